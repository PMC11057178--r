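#' Does a single prediction match an answer-key entry?
#'
#' Implements the strict matching rules used in assessment:
#'
#' * `ALL_OF` entry (e.g. a compound-heterozygous answer): the prediction's
#'   variant set must equal the required set exactly, as an unordered set. A
#'   single-variant prediction of one allele does not match, and a correct
#'   causal variant paired with a non-required partner in a proposed
#'   biallelic prediction is considered incorrect.
#' * `ANY_OF` entry (a cis-pair equivalence group): a single-variant
#'   prediction of any member matches, as does a pair equal to the full set.
#'   A member paired with an outside variant does not match.
#'
#' With `partial_credit = TRUE` (off by default, for exploratory use only) a
#' single-variant prediction of one allele of an `ALL_OF` pair also counts;
#' the wrong-partner rule is never relaxed.
#'
#' @param variants Character vector of 1 or 2 variant strings (normalized on
#'   the way in).
#' @param entry One answer-key entry: a one-row subset of an `answer_key`
#'   tibble (or a list with `solved`, `match_mode`, `variants`). Must be
#'   solved.
#' @param partial_credit Logical; see above.
#' @return `TRUE` or `FALSE`.
#' @export
match_prediction <- function(variants, entry, partial_credit = FALSE) {
  e <- .as_entry(entry)
  if (!isTRUE(e$solved)) {
    stop("match_prediction is only defined for solved answer-key entries")
  }
  vs <- sort(unique(normalize_variant(variants)))
  if (length(vs) < 1L || length(vs) > 2L) {
    stop("a prediction consists of 1 or 2 distinct variants")
  }
  req <- sort(e$variants)
  if (e$match_mode == "ANY_OF") {
    return((length(vs) == 1L && vs %in% req) || identical(vs, req))
  }
  if (identical(vs, req)) {
    return(TRUE)
  }
  if (partial_credit && length(vs) == 1L && length(req) == 2L && vs %in% req) {
    return(TRUE)
  }
  FALSE
}

.as_entry <- function(entry) {
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1L)
    list(
      proband_id = entry$proband_id[[1L]],
      solved = entry$solved[[1L]],
      match_mode = entry$match_mode[[1L]],
      variants = entry$variants[[1L]]
    )
  } else {
    entry
  }
}

# Vectorized match flags for the predictions of one proband against one
# solved entry. Relies on var1/var2 being canonical and pair-sorted, as
# new_submission() guarantees.
.match_flags <- function(preds, e, partial_credit = FALSE) {
  req <- sort(e$variants)
  req_id <- paste(req, collapse = "|")
  single <- is.na(preds$var2)
  if (e$match_mode == "ANY_OF") {
    (single & preds$var1 %in% req) | preds$vset == req_id
  } else {
    hit <- preds$vset == req_id
    if (partial_credit && length(req) == 2L) {
      hit <- hit | (single & preds$var1 %in% req)
    }
    hit
  }
}

#' Resolve a cis-pair equivalence group within one proband's predictions
#'
#' For an `ANY_OF` entry, every prediction matching any member of the group
#' refers to the same underlying answer. The highest-ranked (lowest rank
#' number) matching prediction is retained as the match and every other
#' matching prediction is removed from the proband's list before any metric
#' is computed. Non-matching predictions keep their original ranks — the
#' retained match is by construction the best-ranked one, so its scoring
#' band is unaffected, and renumbering would silently move unrelated
#' predictions across bands.
#'
#' @param predictions Tibble of one proband's predictions (columns as in
#'   `model_submission$predictions`).
#' @param entry The `ANY_OF` answer-key entry (see [match_prediction()]).
#' @return A list with `predictions` (filtered tibble) and `outcome`, a
#'   one-row tibble with `proband_id`, `matched`, `match_rank` and
#'   `removed_ranks` (list column).
#' @export
resolve_equivalence <- function(predictions, entry) {
  e <- .as_entry(entry)
  if (!identical(e$match_mode, "ANY_OF")) {
    stop("resolve_equivalence applies only to ANY_OF answer-key entries")
  }
  hits <- which(.match_flags(predictions, e))
  if (length(hits) == 0L) {
    outcome <- tibble::tibble(
      proband_id = e$proband_id, matched = FALSE, match_rank = NA_integer_,
      removed_ranks = list(integer(0))
    )
    return(list(predictions = predictions, outcome = outcome))
  }
  best <- hits[which.min(predictions$rank[hits])]
  removed <- setdiff(hits, best)
  outcome <- tibble::tibble(
    proband_id = e$proband_id, matched = TRUE,
    match_rank = as.integer(predictions$rank[best]),
    removed_ranks = list(as.integer(predictions$rank[removed]))
  )
  keep <- setdiff(seq_len(nrow(predictions)), removed)
  list(predictions = predictions[keep, , drop = FALSE], outcome = outcome)
}

#' Score one model against the answer key
#'
#' For each solved answer-key entry, finds the rank of the first (lowest
#' rank) prediction that matches under the rules of [match_prediction()],
#' after resolving `ANY_OF` equivalence groups with [resolve_equivalence()].
#' At most one match is counted per entry; probands with no predictions are
#' misses. Predictions for probands absent from the key trigger a warning
#' and are ignored. When an entry is missed but the model predicted a
#' variant at the right contig within 10 bp of a required variant, a
#' near-miss warning lists the positions (a guard against representation
#' mismatches, since matching is exact by design).
#'
#' @param sub A cleaned `model_submission`.
#' @param key An `answer_key`.
#' @param partial_credit Passed to the matching rules (see
#'   [match_prediction()]).
#' @param near_miss_warn Emit the near-miss warning (default `TRUE`).
#' @return A tibble of class `match_outcomes` with one row per solved entry:
#'   `proband_id`, `matched`, `match_rank`, `matched_vset`, `removed_ranks`.
#' @export
score_model <- function(sub, key, partial_credit = FALSE, near_miss_warn = TRUE) {
  stopifnot(inherits(sub, "model_submission"))
  solved <- .solved_entries(key)
  extra <- setdiff(unique(sub$predictions$proband_id), key$proband_id)
  if (length(extra)) {
    warning(sprintf(
      "submission contains proband(s) absent from the answer key (ignored): %s",
      paste(extra, collapse = ", ")
    ))
  }
  preds_by_proband <- split(sub$predictions, sub$predictions$proband_id)

  rows <- vector("list", nrow(solved))
  near_misses <- character(0)
  for (i in seq_len(nrow(solved))) {
    e <- .as_entry(solved[i, , drop = FALSE])
    pp <- preds_by_proband[[e$proband_id]]
    if (is.null(pp) || nrow(pp) == 0L) {
      rows[[i]] <- tibble::tibble(
        proband_id = e$proband_id, matched = FALSE, match_rank = NA_integer_,
        matched_vset = NA_character_, removed_ranks = list(integer(0))
      )
      next
    }
    removed <- integer(0)
    if (e$match_mode == "ANY_OF") {
      res <- resolve_equivalence(pp, e)
      pp <- res$predictions
      removed <- res$outcome$removed_ranks[[1L]]
    }
    hit <- which(.match_flags(pp, e, partial_credit))
    if (length(hit)) {
      first <- hit[which.min(pp$rank[hit])]
      rows[[i]] <- tibble::tibble(
        proband_id = e$proband_id, matched = TRUE,
        match_rank = as.integer(pp$rank[first]),
        matched_vset = pp$vset[first], removed_ranks = list(removed)
      )
    } else {
      rows[[i]] <- tibble::tibble(
        proband_id = e$proband_id, matched = FALSE, match_rank = NA_integer_,
        matched_vset = NA_character_, removed_ranks = list(removed)
      )
      if (near_miss_warn) {
        nm <- .near_misses(pp, e$variants)
        if (length(nm)) {
          near_misses <- c(near_misses, sprintf("%s: %s", e$proband_id, nm))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (length(near_misses)) {
    warning(sprintf(
      "possible variant-representation near misses (same contig, position within 10 bp of a required variant):\n  %s",
      paste(near_misses, collapse = "\n  ")
    ))
  }
  attr(out, "n_solved") <- nrow(solved)
  class(out) <- c("match_outcomes", class(out))
  out
}

.near_misses <- function(pp, required) {
  pv <- variant_fields(stats::na.omit(c(pp$var1, pp$var2)))
  rv <- variant_fields(required)
  hits <- character(0)
  for (j in seq_len(nrow(rv))) {
    close <- pv$contig == rv$contig[j] & abs(pv$pos - rv$pos[j]) <= 10L &
      pv$key != rv$key[j]
    if (any(close)) {
      hits <- c(hits, sprintf(
        "predicted %s vs required %s",
        paste(unique(pv$key[close]), collapse = ","), rv$key[j]
      ))
    }
  }
  hits
}

# Records of all solved probands with ANY_OF equivalence resolved and the
# (at most one per entry) matching record flagged. The backbone of the
# precision/recall machinery: TP at threshold t = flagged records with
# epcr >= t, calls at t = all records with epcr >= t.
.solved_records <- function(sub, key, partial_credit = FALSE) {
  solved <- .solved_entries(key)
  preds_by_proband <- split(sub$predictions, sub$predictions$proband_id)
  pieces <- vector("list", nrow(solved))
  for (i in seq_len(nrow(solved))) {
    e <- .as_entry(solved[i, , drop = FALSE])
    pp <- preds_by_proband[[e$proband_id]]
    if (is.null(pp) || nrow(pp) == 0L) next
    if (e$match_mode == "ANY_OF") {
      pp <- resolve_equivalence(pp, e)$predictions
    }
    hit <- which(.match_flags(pp, e, partial_credit))
    is_causal <- rep(FALSE, nrow(pp))
    if (length(hit)) {
      is_causal[hit[which.min(pp$rank[hit])]] <- TRUE
    }
    pieces[[i]] <- tibble::tibble(
      proband_id = pp$proband_id, rank = pp$rank, epcr = pp$epcr,
      vset = pp$vset, is_causal = is_causal
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces)) {
    do.call(rbind, pieces)
  } else {
    tibble::tibble(
      proband_id = character(0), rank = integer(0), epcr = numeric(0),
      vset = character(0), is_causal = logical(0)
    )
  }
}
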