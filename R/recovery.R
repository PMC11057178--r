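#' A ladder of ten graded skill profiles
#'
#' Ten skill profiles whose band distributions are stochastically ordered
#' (each profile's cumulative band mass dominates the next one's), with
#' analytic expected mean rank points descending from roughly 97 to 5.
#' Used by [recovery_experiment()] to check that the assessment pipeline
#' recovers a known skill ordering.
#'
#' @param n_preds Predictions per proband for every profile.
#' @return Named list of [skill_profile()]s, best first.
#' @export
skill_ladder <- function(n_preds = 100L) {
  probs <- list(
    c(0.95, 0.03, 0.01, 0.005, 0.005, 0),
    c(0.80, 0.10, 0.05, 0.03, 0.01, 0.01),
    c(0.65, 0.15, 0.08, 0.05, 0.03, 0.04),
    c(0.50, 0.20, 0.10, 0.08, 0.05, 0.07),
    c(0.40, 0.20, 0.12, 0.10, 0.08, 0.10),
    c(0.30, 0.18, 0.15, 0.12, 0.10, 0.15),
    c(0.20, 0.15, 0.15, 0.15, 0.15, 0.20),
    c(0.12, 0.12, 0.12, 0.15, 0.20, 0.29),
    c(0.05, 0.08, 0.10, 0.12, 0.15, 0.50),
    c(0.01, 0.02, 0.05, 0.10, 0.12, 0.70)
  )
  out <- lapply(probs, skill_profile, n_preds = n_preds)
  names(out) <- sprintf("skill_%02d", seq_along(out))
  out
}

#' End-to-end skill-recovery experiment
#'
#' Generates `n_replicates` independent synthetic challenges and, for each,
#' simulates one submission per skill profile, assesses them, and records
#' the mean-rank-points score. Within a replicate all skills share one
#' generator seed, so they face identical per-proband band-draw uniforms (a
#' paired, common-random-numbers design; see [generate_model_submission()]).
#' Because the ladder's band distributions are stochastically ordered, a
#' correctly functioning pipeline can then never invert the expected
#' ordering within a replicate — any inversion indicates a matching or
#' scoring defect — while across replicates each model's mean score is an
#' unbiased estimate of its analytic expectation.
#'
#' @param n_replicates Number of independent challenges.
#' @param skills List of [skill_profile()]s (default [skill_ladder()]),
#'   ordered by decreasing [expected_mean_rank_points()].
#' @param cfg_fun Function `seed -> challenge_config`, defaulting to the
#'   standard 14-solved / 16-unsolved test-set configuration.
#' @param seed Master seed.
#' @return List with `scores` (replicates x skills matrix), `expected`,
#'   `mean_scores`, `mc_se` (per-skill Monte-Carlo SE of the mean score),
#'   `z` (standardized deviation of mean score from expectation),
#'   `ordering_recovery_rate` (fraction of replicates with zero pairwise
#'   inversions of the expected ordering; ties count as consistent).
#' @export
recovery_experiment <- function(n_replicates = 100L,
                                skills = skill_ladder(),
                                cfg_fun = function(seed) {
                                  challenge_config(seed = seed)
                                },
                                seed = 1L) {
  stopifnot(n_replicates >= 2L, length(skills) >= 2L)
  expected <- vapply(skills, expected_mean_rank_points, numeric(1))
  scores <- matrix(
    NA_real_, n_replicates, length(skills),
    dimnames = list(NULL, names(skills))
  )
  for (r in seq_len(n_replicates)) {
    ch <- generate_challenge(cfg_fun(seed + r))
    model_seed <- seed + 100000L + r # shared across skills within a replicate
    for (s in seq_along(skills)) {
      sub <- generate_model_submission(ch, skills[[s]], seed = model_seed)
      o <- score_model(sub, ch$answer_key, near_miss_warn = FALSE)
      scores[r, s] <- mean_rank_points(o)
    }
  }
  mean_scores <- colMeans(scores)
  mc_se <- apply(scores, 2L, stats::sd) / sqrt(n_replicates)
  inversion_free <- vapply(seq_len(n_replicates), function(r) {
    v <- scores[r, ]
    ok <- TRUE
    for (i in seq_len(length(v) - 1L)) {
      for (j in (i + 1L):length(v)) {
        better <- if (expected[i] >= expected[j]) i else j
        worse <- if (better == i) j else i
        if (v[better] < v[worse]) ok <- FALSE
      }
    }
    ok
  }, logical(1))
  list(
    scores = scores,
    expected = expected,
    mean_scores = mean_scores,
    mc_se = mc_se,
    z = (mean_scores - expected) / mc_se,
    ordering_recovery_rate = mean(inversion_free)
  )
}
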