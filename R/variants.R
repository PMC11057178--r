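#' @keywords internal
.CONTIGS <- c(as.character(1:22), "X", "Y", "MT")

#' Normalize variant identifiers
#'
#' A small variant (SNV or small indel) is identified by the string
#' `CONTIG:POS:REF:ALT` with 1-based, fully closed GRCh38 coordinates, as in
#' VCF. Normalization strips any leading `"chr"` from the contig (mapping
#' `"M"` to `"MT"`) and uppercases the alleles. Two variants are treated as
#' the same prediction/answer if and only if their canonical strings are
#' equal: no indel left-alignment or allele minimalization is attempted,
#' because all parties to an assessment share one canonical call set and
#' silently repairing representations would hide mismatches a real
#' assessment would count as misses. Use the near-miss warning emitted by
#' [score_model()] to spot representation problems instead.
#'
#' @param x Character vector of `CONTIG:POS:REF:ALT` strings.
#' @return Character vector of canonical variant keys. Normalization is
#'   idempotent: applying it to its own output is a no-op.
#' @examples
#' normalize_variant("chr7:97850000:C:T")  # "7:97850000:C:T"
#' normalize_variant("7:97850000:c:t") == normalize_variant("chr7:97850000:C:T")
#' @export
normalize_variant <- function(x) {
  if (!is.character(x)) {
    stop("variant must be a character vector of 'CONTIG:POS:REF:ALT' strings")
  }
  if (length(x) == 0L) {
    return(character(0))
  }
  if (anyNA(x)) {
    stop("variant string is NA")
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1L]
    stop(sprintf(
      "malformed variant '%s': expected 4 colon-separated fields (CONTIG:POS:REF:ALT), got %d",
      x[i], nf[i]
    ))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 4L, byrow = TRUE)
  contig <- toupper(sub("^chr", "", m[, 1L], ignore.case = TRUE))
  contig[contig == "M"] <- "MT"
  bad <- !(contig %in% .CONTIGS)
  if (any(bad)) {
    stop(sprintf(
      "invalid contig in variant '%s': '%s' (allowed: 1-22, X, Y, MT, with or without 'chr')",
      x[which(bad)[1L]], m[which(bad)[1L], 1L]
    ))
  }
  pos <- suppressWarnings(as.integer(m[, 2L]))
  bad <- is.na(pos) | pos < 1L
  if (any(bad)) {
    stop(sprintf(
      "invalid position in variant '%s': '%s' (must be an integer >= 1)",
      x[which(bad)[1L]], m[which(bad)[1L], 2L]
    ))
  }
  ref <- toupper(m[, 3L])
  alt <- toupper(m[, 4L])
  bad <- !grepl("^[ACGT]+$", ref)
  if (any(bad)) {
    stop(sprintf(
      "invalid ref allele in variant '%s': '%s' (must be a non-empty A/C/G/T string)",
      x[which(bad)[1L]], m[which(bad)[1L], 3L]
    ))
  }
  bad <- !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop(sprintf(
      "invalid alt allele in variant '%s': '%s' (must be a non-empty A/C/G/T string)",
      x[which(bad)[1L]], m[which(bad)[1L], 4L]
    ))
  }
  bad <- ref == alt
  if (any(bad)) {
    stop(sprintf(
      "degenerate variant '%s': ref equals alt ('%s')",
      x[which(bad)[1L]], ref[which(bad)[1L]]
    ))
  }
  paste(contig, pos, ref, alt, sep = ":")
}

#' Split canonical variant keys into their fields
#'
#' @param x Character vector of variant strings (normalized on the way in).
#' @return A tibble with columns `key`, `contig`, `pos`, `ref`, `alt`.
#' @examples
#' variant_fields("chrX:1000:A:GT")
#' @export
variant_fields <- function(x) {
  key <- normalize_variant(x)
  if (length(key) == 0L) {
    return(tibble::tibble(
      key = character(0), contig = character(0), pos = integer(0),
      ref = character(0), alt = character(0)
    ))
  }
  m <- matrix(unlist(strsplit(key, ":", fixed = TRUE), use.names = FALSE),
    ncol = 4L, byrow = TRUE
  )
  tibble::tibble(
    key = key, contig = m[, 1L], pos = as.integer(m[, 2L]),
    ref = m[, 3L], alt = m[, 4L]
  )
}

# Normalize a vector element-wise, returning NA (plus the error message as an
# attribute-free side channel) for entries that fail; used by the tolerant
# submission parser, which must never abort on a bad line.
.safe_normalize <- function(x) {
  out <- character(length(x))
  msg <- character(length(x))
  for (i in seq_along(x)) {
    r <- tryCatch(normalize_variant(x[[i]]), error = function(e) e)
    if (inherits(r, "error")) {
      out[i] <- NA_character_
      msg[i] <- conditionMessage(r)
    } else {
      out[i] <- r
    }
  }
  list(key = out, message = msg)
}

# Canonical unordered representation of a 1- or 2-variant prediction.
.variant_set_id <- function(var1, var2) {
  ifelse(
    is.na(var2),
    var1,
    paste(pmin(var1, var2), pmax(var1, var2), sep = "|")
  )
}
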