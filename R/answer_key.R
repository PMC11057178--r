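#' Read an answer key of causal variants per proband
#'
#' The answer key lists, for every proband in a challenge test set, whether
#' the family is solved and, if so, the acceptable causal variant set. Two
#' matching semantics occur in practice and both are supported generically:
#'
#' * `ALL_OF` — every listed variant must be predicted jointly (a
#'   compound-heterozygous answer submitted as one biallelic prediction);
#' * `ANY_OF` — predicting any one member (or the full set) is correct (two
#'   variants in *cis* on one haplotype, either of which may be causal).
#'
#' File dialect (tab-separated, `#`-prefixed header lines ignored):
#' `proband_id  solved{0,1}  match_mode{ALL_OF,ANY_OF,.}  variants  label`
#' where `variants` is a `;`-joined list of `CONTIG:POS:REF:ALT` strings or
#' `"."` for unsolved probands. The `label` column is free-text metadata
#' (gene symbol, inheritance) and is optional.
#'
#' @param path Path to the answer-key TSV.
#' @return A tibble of class `answer_key` with columns `proband_id`,
#'   `solved` (logical), `match_mode`, `variants` (list of canonical variant
#'   keys) and `label`, plus attributes `n_solved` and `n_unsolved`.
#' @seealso [write_answer_key()], [score_model()]
#' @export
load_answer_key <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("answer key file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(.new_answer_key(tibble::tibble(
      proband_id = character(0), solved = logical(0),
      match_mode = character(0), variants = list(), label = character(0)
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L | nf > 5L)) {
    i <- which(nf < 4L | nf > 5L)[1L]
    stop(sprintf(
      "answer key line %d: expected 4 or 5 tab-separated fields, got %d",
      i, nf[i]
    ))
  }
  get <- function(k) vapply(fields, function(f) {
    if (length(f) >= k) trimws(f[[k]]) else ""
  }, character(1))
  proband_id <- get(1L)
  solved_raw <- get(2L)
  match_mode <- get(3L)
  variants_raw <- get(4L)
  label <- get(5L)

  if (anyDuplicated(proband_id)) {
    stop(sprintf(
      "duplicate proband_id in answer key: %s",
      proband_id[duplicated(proband_id)][1L]
    ))
  }
  if (!all(solved_raw %in% c("0", "1"))) {
    stop(sprintf(
      "answer key: solved must be 0 or 1 (proband %s has '%s')",
      proband_id[!solved_raw %in% c("0", "1")][1L],
      solved_raw[!solved_raw %in% c("0", "1")][1L]
    ))
  }
  solved <- solved_raw == "1"
  ok_mode <- match_mode %in% c("ALL_OF", "ANY_OF") | (!solved & match_mode == ".")
  if (!all(ok_mode)) {
    stop(sprintf(
      "answer key: unknown match_mode '%s' for proband %s (allowed: ALL_OF, ANY_OF)",
      match_mode[!ok_mode][1L], proband_id[!ok_mode][1L]
    ))
  }
  variants <- lapply(seq_along(variants_raw), function(i) {
    v <- variants_raw[i]
    if (v %in% c("", ".")) {
      return(character(0))
    }
    sort(normalize_variant(strsplit(v, ";", fixed = TRUE)[[1L]]))
  })
  nv <- lengths(variants)
  if (any(solved & nv == 0L)) {
    stop(sprintf(
      "answer key: solved proband %s has no causal variants",
      proband_id[solved & nv == 0L][1L]
    ))
  }
  if (any(!solved & nv > 0L)) {
    stop(sprintf(
      "answer key: unsolved proband %s lists causal variants",
      proband_id[!solved & nv > 0L][1L]
    ))
  }
  if (any(nv > 2L)) {
    stop(sprintf(
      "answer key: proband %s lists %d variants (at most 2 supported)",
      proband_id[nv > 2L][1L], max(nv)
    ))
  }
  .new_answer_key(tibble::tibble(
    proband_id = proband_id, solved = solved, match_mode = match_mode,
    variants = variants, label = label
  ))
}

.new_answer_key <- function(df) {
  stopifnot(is.data.frame(df))
  attr(df, "n_solved") <- sum(df$solved)
  attr(df, "n_unsolved") <- sum(!df$solved)
  class(df) <- c("answer_key", class(df))
  df
}

#' @export
print.answer_key <- function(x, ...) {
  cat(sprintf(
    "<answer_key> %d probands: %d solved, %d unsolved\n",
    nrow(x), attr(x, "n_solved"), attr(x, "n_unsolved")
  ))
  NextMethod()
  invisible(x)
}

#' Write an answer key to its TSV dialect
#'
#' Inverse of [load_answer_key()]; `load_answer_key(write_answer_key(key, f))`
#' reproduces an equal key.
#'
#' @param key An `answer_key` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_answer_key <- function(key, path) {
  stopifnot(inherits(key, "answer_key") || is.data.frame(key))
  vr <- vapply(key$variants, function(v) {
    if (length(v) == 0L) "." else paste(v, collapse = ";")
  }, character(1))
  lines <- c(
    "# proband_id\tsolved\tmatch_mode\tvariants\tlabel",
    sprintf(
      "%s\t%d\t%s\t%s\t%s",
      key$proband_id, as.integer(key$solved), key$match_mode, vr, key$label
    )
  )
  writeLines(lines, path)
  invisible(path)
}

# Solved subset, in key order; errors if the key has no solved entries.
.solved_entries <- function(key) {
  s <- key[key$solved, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop("answer key contains no solved probands; metrics are undefined")
  }
  s
}
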