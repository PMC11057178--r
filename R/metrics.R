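#' Rank-band point schedule
#'
#' Weighted point allocation rewarding highly ranked causal variants: a hit
#' within the top five earns 100 points, top 10 earns 50, top 20 earns 25,
#' top 50 earns 10, top 100 earns 5, and anything beyond (or a miss) earns
#' 0. The steep decay mirrors clinical practice, where only a handful of
#' top-ranked variants receive full curation.
#'
#' @param max_rank,points Parallel vectors defining the bands: `max_rank`
#'   strictly increasing (inclusive upper bounds), `points` strictly
#'   decreasing.
#' @param miss_points Points for a rank beyond the last band or a miss.
#' @return A list of class `rank_points_schedule`.
#' @export
rank_points_schedule <- function(max_rank = c(5L, 10L, 20L, 50L, 100L),
                                 points = c(100, 50, 25, 10, 5),
                                 miss_points = 0) {
  stopifnot(
    length(max_rank) == length(points), length(max_rank) >= 1L,
    all(diff(max_rank) > 0), all(diff(points) < 0), all(max_rank >= 1L)
  )
  structure(
    list(max_rank = as.integer(max_rank), points = points, miss_points = miss_points),
    class = "rank_points_schedule"
  )
}

#' Convert a match rank into points
#'
#' @param rank Integer vector of match ranks; `NA` encodes a miss.
#' @param schedule A [rank_points_schedule()].
#' @return Numeric vector of points.
#' @examples
#' rank_to_points(c(3, 12, NA)) # 100, 25, 0
#' @export
rank_to_points <- function(rank, schedule = rank_points_schedule()) {
  stopifnot(inherits(schedule, "rank_points_schedule"))
  rank <- as.integer(rank)
  if (any(!is.na(rank) & rank < 1L)) {
    stop("ranks must be >= 1 (use NA for a miss)")
  }
  out <- rep(schedule$miss_points, length(rank))
  ok <- !is.na(rank)
  # band index: first band whose inclusive upper bound >= rank
  cuts <- c(1L, schedule$max_rank + 1L)
  idx <- findInterval(rank[ok], cuts)
  in_band <- idx <= length(schedule$points)
  out[ok][in_band] <- schedule$points[idx[in_band]]
  out
}

.outcome_ranks <- function(outcomes) {
  if (inherits(outcomes, "match_outcomes") || is.data.frame(outcomes)) {
    outcomes$match_rank
  } else {
    as.integer(outcomes)
  }
}

#' Mean rank points over the solved probands
#'
#' Arithmetic mean of [rank_to_points()] over all solved answer-key entries.
#' The denominator is the number of solved entries — probands a model
#' skipped count as misses, not as excluded observations.
#'
#' @param outcomes A `match_outcomes` tibble from [score_model()], or an
#'   integer vector of match ranks with `NA` for misses (one element per
#'   solved entry).
#' @param schedule A [rank_points_schedule()].
#' @return A single number in \[0, max points\].
#' @export
mean_rank_points <- function(outcomes, schedule = rank_points_schedule()) {
  ranks <- .outcome_ranks(outcomes)
  if (length(ranks) == 0L) {
    stop("mean_rank_points is undefined for zero solved entries")
  }
  mean(rank_to_points(ranks, schedule))
}

#' Cumulative rank-band counts for one model
#'
#' Counts of solved entries whose causal variant(s) were found at rank 1 and
#' within the cumulative cutoffs 5, 10, 20, 50 and 100; non-decreasing from
#' left to right.
#'
#' @inheritParams mean_rank_points
#' @return Named integer vector `rank_1`, `rank_1_5`, ..., `rank_1_100`.
#' @export
rank_band_counts <- function(outcomes) {
  r <- .outcome_ranks(outcomes)
  cuts <- c(1L, 5L, 10L, 20L, 50L, 100L)
  out <- vapply(cuts, function(k) sum(!is.na(r) & r <= k), integer(1))
  names(out) <- c("rank_1", paste0("rank_1_", cuts[-1L]))
  out
}

#' Precision, recall and F-measure at one EPCR threshold
#'
#' The call set at threshold `t` is every prediction for a solved proband
#' with EPCR >= `t` (after `ANY_OF` equivalence resolution). A true positive
#' is a solved entry whose matching prediction is in the call set (at most
#' one per entry). Precision is TP over the call-set size (0 for an empty
#' call set), recall is TP over the number of solved entries, and F is their
#' harmonic mean (0 when both are 0). Predictions for unsolved probands
#' enter neither numerator nor denominator.
#'
#' @param sub A cleaned `model_submission`.
#' @param key An `answer_key`.
#' @param threshold EPCR threshold in \[0, 1\].
#' @param partial_credit See [match_prediction()].
#' @return Named numeric vector `precision`, `recall`, `f`.
#' @export
precision_recall_at <- function(sub, key, threshold, partial_credit = FALSE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  rec <- .solved_records(sub, key, partial_credit)
  n_solved <- nrow(.solved_entries(key))
  called <- rec$epcr >= threshold
  tp <- sum(rec$is_causal & called)
  n_calls <- sum(called)
  precision <- if (n_calls == 0L) 0 else tp / n_calls
  recall <- tp / n_solved
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f = f)
}

# F over the descending unique-threshold sweep, from raw record vectors.
# Uses F = 2*TP / (calls + n_entries), the closed form of 2PR/(P+R).
# Returns list(thresholds, tp, calls, f) with thresholds sorted decreasing.
.fmax_curve <- function(epcr, is_causal, n_entries) {
  thr <- sort(unique(epcr), decreasing = TRUE)
  grp <- match(epcr, thr)
  calls <- cumsum(tabulate(grp, nbins = length(thr)))
  tp <- cumsum(tabulate(grp[is_causal], nbins = length(thr)))
  list(
    thresholds = thr, tp = tp, calls = calls,
    f = 2 * tp / (calls + n_entries)
  )
}

#' Sweep all EPCR thresholds and locate the maximum F-measure
#'
#' Evaluates [precision_recall_at()] at every unique EPCR value among the
#' model's solved-proband predictions (F is piecewise constant between
#' them, so this sweep is exhaustive) and reports the maximum. When several
#' thresholds tie, the largest is reported — the most conservative call set.
#' The mean and SD of calls per proband at the winning threshold are taken
#' over all solved probands, counting 0 for probands without calls.
#'
#' @inheritParams precision_recall_at
#' @return A list of class `fmax_result`: `fmax`, `threshold`,
#'   `mean_calls`, `sd_calls`, and `curve`, a tibble of
#'   (`threshold`, `precision`, `recall`, `f`). A model with no predictions
#'   for solved probands yields `NA` fields rather than an error.
#' @export
fmax_sweep <- function(sub, key, partial_credit = FALSE) {
  rec <- .solved_records(sub, key, partial_credit)
  solved <- .solved_entries(key)
  n_solved <- nrow(solved)
  if (nrow(rec) == 0L) {
    return(structure(
      list(
        fmax = NA_real_, threshold = NA_real_,
        mean_calls = NA_real_, sd_calls = NA_real_,
        curve = tibble::tibble(
          threshold = numeric(0), precision = numeric(0),
          recall = numeric(0), f = numeric(0)
        )
      ),
      class = "fmax_result"
    ))
  }
  cv <- .fmax_curve(rec$epcr, rec$is_causal, n_solved)
  best <- which.max(cv$f) # thresholds descend, so ties resolve to the largest
  thr_star <- cv$thresholds[best]
  calls_per <- vapply(
    solved$proband_id,
    function(p) sum(rec$proband_id == p & rec$epcr >= thr_star),
    numeric(1)
  )
  structure(
    list(
      fmax = cv$f[best],
      threshold = thr_star,
      mean_calls = mean(calls_per),
      sd_calls = stats::sd(calls_per),
      curve = tibble::tibble(
        threshold = cv$thresholds,
        precision = ifelse(cv$calls == 0, 0, cv$tp / cv$calls),
        recall = cv$tp / n_solved,
        f = cv$f
      )
    ),
    class = "fmax_result"
  )
}

#' @export
print.fmax_result <- function(x, ...) {
  if (is.na(x$fmax)) {
    cat("<fmax_result> NA (no predictions over solved probands)\n")
  } else {
    cat(sprintf(
      "<fmax_result> F-max %.3f at EPCR threshold %g (%.2f +/- %.2f calls/proband)\n",
      x$fmax, x$threshold, x$mean_calls, x$sd_calls
    ))
  }
  invisible(x)
}

#' Bootstrap standard error of a per-proband statistic
#'
#' Resamples the solved probands with replacement `B` times, recomputes the
#' statistic on each multiset, and returns the standard deviation of the
#' replicates (denominator B - 1). Both assessment metrics qualify: mean
#' rank points is a mean of per-proband points, and F-max is re-swept on the
#' resampled records per replicate.
#'
#' @param statistic Function of a multiset of proband ids (a character
#'   vector possibly with repeats) returning one number.
#' @param ids The solved proband ids to resample.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional seed for reproducibility; the caller's RNG state is
#'   left untouched when supplied.
#' @return The bootstrap standard error (one number).
#' @export
bootstrap_se <- function(statistic, ids, B = 1000L, seed = NULL) {
  stopifnot(is.function(statistic), length(ids) >= 1L)
  if (B < 2L) {
    stop("bootstrap_se needs at least 2 replicates")
  }
  run <- function() {
    reps <- vapply(
      seq_len(B),
      function(b) statistic(sample(ids, length(ids), replace = TRUE)),
      numeric(1)
    )
    stats::sd(reps)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Per-entry detection counts across models
#'
#' For each solved answer-key entry, how many models placed the causal
#' variant(s) at rank 1 and within the cumulative bands 5, 10, 20, 50, 100.
#'
#' @param outcomes_list List (one element per model) of `match_outcomes`
#'   tibbles from [score_model()], all scored against the same key.
#' @return Tibble with one row per solved entry: `proband_id`, `n_rank_1`,
#'   `n_rank_1_5`, ..., `n_rank_1_100`.
#' @export
detection_counts <- function(outcomes_list) {
  stopifnot(length(outcomes_list) >= 1L)
  probands <- outcomes_list[[1L]]$proband_id
  cuts <- c(1L, 5L, 10L, 20L, 50L, 100L)
  counts <- matrix(0L, nrow = length(probands), ncol = length(cuts))
  for (o in outcomes_list) {
    stopifnot(identical(o$proband_id, probands))
    r <- o$match_rank
    for (j in seq_along(cuts)) {
      counts[, j] <- counts[, j] + as.integer(!is.na(r) & r <= cuts[j])
    }
  }
  out <- tibble::as_tibble(as.data.frame(counts))
  names(out) <- c("n_rank_1", paste0("n_rank_1_", cuts[-1L]))
  tibble::tibble(proband_id = probands, out)
}

#' Concordance of two models' top-k predictions
#'
#' For every proband where at least one of the two models submitted
#' predictions, the Jaccard index of the two top-`k` variant-set collections
#' is computed (a biallelic prediction is one element); the model-pair
#' concordance is the mean over those probands. Symmetric, bounded by
#' \[0, 1\], and 1 for a nonempty submission against itself.
#'
#' @param sub_a,sub_b Cleaned `model_submission`s.
#' @param k Depth of the compared lists (default 5).
#' @return One number, or `NA` if both submissions are empty.
#' @export
concordance <- function(sub_a, sub_b, k = 5L) {
  pa <- sub_a$predictions
  pb <- sub_b$predictions
  probands <- union(unique(pa$proband_id), unique(pb$proband_id))
  if (length(probands) == 0L) {
    return(NA_real_)
  }
  top <- function(p, id) {
    v <- p$vset[p$proband_id == id]
    utils::head(v, k)
  }
  jac <- vapply(probands, function(id) {
    a <- top(pa, id)
    b <- top(pb, id)
    u <- union(a, b)
    length(intersect(a, b)) / length(u)
  }, numeric(1))
  mean(jac)
}

#' Pairwise concordance matrix over a set of models
#'
#' @param subs Named list of cleaned `model_submission`s.
#' @param k Depth of the compared lists.
#' @return A symmetric numeric matrix.
#' @export
concordance_matrix <- function(subs, k = 5L) {
  n <- length(subs)
  nm <- names(subs)
  if (is.null(nm)) {
    nm <- paste0("model_", seq_len(n))
  }
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- concordance(subs[[i]], subs[[j]], k = k)
    }
  }
  m
}

#' Mean rank points stratified by pedigree completeness
#'
#' Splits the solved entries into families with incomplete familial data
#' (proband-only or duo) versus complete data (trio or quad) and computes
#' the mean-rank-points metric separately in each stratum. Segregation
#' evidence is what parental genomes buy a model, so this contrast measures
#' its value.
#'
#' @param outcomes `match_outcomes` from [score_model()].
#' @param families Family table from [load_families()] (or any data frame
#'   with `proband_id` and `completeness`).
#' @param schedule A [rank_points_schedule()].
#' @return Named numeric vector `c(incomplete =, complete =)`; a stratum
#'   with no entries is `NA`.
#' @export
stratified_mean_rank_points <- function(outcomes, families,
                                        schedule = rank_points_schedule()) {
  idx <- match(outcomes$proband_id, families$proband_id)
  if (anyNA(idx)) {
    stop(sprintf(
      "no family information for proband(s): %s",
      paste(outcomes$proband_id[is.na(idx)], collapse = ", ")
    ))
  }
  comp <- families$completeness[idx]
  incomplete <- comp %in% c("proband_only", "duo")
  score <- function(sel) {
    if (!any(sel)) NA_real_ else mean(rank_to_points(outcomes$match_rank[sel], schedule))
  }
  c(incomplete = score(incomplete), complete = score(!incomplete))
}

#' Paired two-sided Student's t-test
#'
#' Tests whether paired per-model scores differ, e.g. each model's
#' complete-pedigree score against its incomplete-pedigree score. Delegates
#' to [stats::t.test()] with explicit handling of the degenerate cases: all
#' differences zero gives t = 0, p = 1; constant nonzero differences give an
#' infinite t with p = 0, flagged as degenerate.
#'
#' @param x,y Equal-length numeric vectors; the test is on `d = y - x`.
#' @return List with `statistic` (t), `p.value` (two-sided), `df`,
#'   `mean_diff`, and `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) {
    stop("paired_t_test does not accept missing values")
  }
  n <- length(x)
  if (n < 2L) {
    stop("paired_t_test needs at least 2 pairs")
  }
  d <- y - x
  if (all(d == 0)) {
    return(list(statistic = 0, p.value = 1, df = n - 1L, mean_diff = 0,
                degenerate = TRUE))
  }
  if (stats::sd(d) == 0) {
    return(list(
      statistic = sign(mean(d)) * Inf, p.value = 0, df = n - 1L,
      mean_diff = mean(d), degenerate = TRUE
    ))
  }
  tt <- stats::t.test(y, x, paired = TRUE, alternative = "two.sided")
  list(
    statistic = unname(tt$statistic), p.value = tt$p.value,
    df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE
  )
}
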