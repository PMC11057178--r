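#' Read family structure and proband phenotype terms
#'
#' Families are described by a standard 6-column PED file (family id,
#' individual id, father id, mother id, sex, affected status with 2 =
#' affected) holding one row per *sequenced* individual, and an optional
#' two-column TSV mapping individual ids to comma-separated HPO term ids.
#'
#' The proband is identified as the first-listed affected non-founder
#' (an individual with at least one parent id set); if the family has no
#' non-founders, the single affected founder is the proband (a proband-only
#' family). A family with no affected individual, or with several affected
#' founders and no parental structure to disambiguate them, is an error.
#' Additional affected non-founders are affected siblings.
#'
#' Pedigree completeness is derived purely from which relatives have rows:
#' `proband_only` (no parent sequenced), `duo` (one parent), `trio` (both
#' parents), `quad` (both parents plus at least one sibling).
#'
#' @param ped_path Path to the PED file.
#' @param hpo_path Optional path to the proband-HPO TSV
#'   (`individual_id<TAB>HP:NNNNNNN[,HP:NNNNNNN...]`). Probands without a row
#'   get an empty term set, with a warning.
#' @return A tibble with one row per family: `family_id`, `proband_id`,
#'   `completeness`, `hpo_terms` (list of character vectors) and `members`
#'   (list of tibbles with `individual_id`, `relation`, `affected`).
#' @export
load_families <- function(ped_path, hpo_path = NULL) {
  if (!file.exists(ped_path)) {
    stop(sprintf("PED file not found: %s", ped_path))
  }
  ped <- utils::read.table(
    ped_path,
    header = FALSE, sep = "", comment.char = "#",
    col.names = c(
      "family_id", "individual_id", "father_id", "mother_id", "sex", "affected"
    ),
    colClasses = "character", stringsAsFactors = FALSE
  )
  if (ncol(ped) != 6L) {
    stop("PED file must have 6 columns: family, individual, father, mother, sex, affected")
  }
  ped$affected_lgl <- ped$affected == "2"

  hpo_map <- list()
  if (!is.null(hpo_path)) {
    if (!file.exists(hpo_path)) {
      stop(sprintf("HPO file not found: %s", hpo_path))
    }
    hl <- readLines(hpo_path, warn = FALSE)
    hl <- hl[nzchar(trimws(hl)) & !startsWith(trimws(hl), "#")]
    for (line in hl) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(f) >= 2L) {
        hpo_map[[trimws(f[1L])]] <- trimws(strsplit(f[2L], ",", fixed = TRUE)[[1L]])
      } else if (length(f) == 1L) {
        hpo_map[[trimws(f[1L])]] <- character(0)
      }
    }
  }

  fams <- split(ped, ped$family_id)
  rows <- lapply(fams, function(fp) .family_info(fp, hpo_map, !is.null(hpo_path)))
  out <- do.call(rbind, rows)
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out <- tibble::as_tibble(out)
  out$hpo_terms <- unclass(out$hpo_terms)
  out$members <- unclass(out$members)
  out
}

.family_info <- function(fp, hpo_map, have_hpo) {
  is_child <- fp$father_id != "0" | fp$mother_id != "0"
  affected_children <- which(is_child & fp$affected_lgl)
  if (length(affected_children) > 0L) {
    proband_i <- affected_children[1L]
  } else {
    aff <- which(fp$affected_lgl)
    if (length(aff) == 0L) {
      stop(sprintf("family %s has no affected individual", fp$family_id[1L]))
    }
    if (length(aff) > 1L) {
      stop(sprintf(
        "family %s has %d affected founders and no parental structure; cannot identify a single proband",
        fp$family_id[1L], length(aff)
      ))
    }
    proband_i <- aff
  }
  pid <- fp$individual_id[proband_i]
  father <- fp$father_id[proband_i]
  mother <- fp$mother_id[proband_i]
  father_here <- father != "0" && father %in% fp$individual_id
  mother_here <- mother != "0" && mother %in% fp$individual_id

  relation <- rep(NA_character_, nrow(fp))
  relation[proband_i] <- "proband"
  relation[fp$individual_id == father & father_here] <- "father"
  relation[fp$individual_id == mother & mother_here] <- "mother"
  # siblings: other children sharing at least one named parent with the proband
  shares_parent <- is_child & (
    (fp$father_id == father & father != "0") |
      (fp$mother_id == mother & mother != "0")
  )
  relation[is.na(relation) & shares_parent] <- "sibling"
  if (anyNA(relation)) {
    warning(sprintf(
      "family %s: individual(s) %s are neither the proband, a parent, nor a sibling; ignored",
      fp$family_id[1L],
      paste(fp$individual_id[is.na(relation)], collapse = ", ")
    ))
  }
  keep <- !is.na(relation)

  n_parents <- sum(relation %in% c("father", "mother"), na.rm = TRUE)
  n_sibs <- sum(relation == "sibling", na.rm = TRUE)
  completeness <- if (n_parents == 0L) {
    "proband_only"
  } else if (n_parents == 1L) {
    "duo"
  } else if (n_sibs >= 1L) {
    "quad"
  } else {
    "trio"
  }

  terms <- hpo_map[[pid]]
  if (is.null(terms)) {
    if (have_hpo) {
      warning(sprintf("proband %s has no HPO terms in the HPO file", pid))
    }
    terms <- character(0)
  }

  data.frame(
    family_id = fp$family_id[1L],
    proband_id = pid,
    completeness = completeness,
    hpo_terms = I(list(terms)),
    members = I(list(tibble::tibble(
      individual_id = fp$individual_id[keep],
      relation = relation[keep],
      affected = fp$affected_lgl[keep]
    ))),
    stringsAsFactors = FALSE
  )
}

#' Pedigree completeness classes
#'
#' @return Character vector of the four completeness classes, in increasing
#'   order of available familial information.
#' @export
completeness_levels <- function() {
  c("proband_only", "duo", "trio", "quad")
}
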