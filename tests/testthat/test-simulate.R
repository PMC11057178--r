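test_that("challenge generation honors counts, special entries, and determinism", {
  cfg <- challenge_config(n_solved = 14, n_unsolved = 16,
                          include_cis_pair = TRUE, seed = 101)
  ch <- generate_challenge(cfg)
  key <- ch$answer_key
  expect_equal(nrow(key), 30L)
  expect_equal(attr(key, "n_solved"), 14L)
  expect_equal(attr(key, "n_unsolved"), 16L)
  expect_equal(sum(key$match_mode == "ANY_OF"), 1L)
  cis <- key$variants[[which(key$match_mode == "ANY_OF")]]
  expect_length(cis, 2L)
  cf <- variant_fields(cis)
  expect_equal(cf$contig[1], cf$contig[2])
  expect_equal(abs(diff(cf$pos)), 6L)
  # decoy pool: large and disjoint from every causal variant
  expect_gte(length(ch$decoys), 10000L)
  expect_length(intersect(ch$decoys, unlist(key$variants)), 0L)
  # same seed twice: identical objects and byte-identical files
  ch2 <- generate_challenge(cfg)
  expect_equal(ch$answer_key, ch2$answer_key)
  expect_equal(ch$ped, ch2$ped)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_challenge(ch, d1)
  write_challenge(ch2, d2)
  for (f in c("families.ped", "hpo.tsv", "answer_key.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a pure compound-het config yields a single two-variant ALL_OF entry", {
  cfg <- challenge_config(
    n_solved = 1, n_unsolved = 0,
    inheritance_mix = c(ar_comphet = 1),
    include_cis_pair = FALSE, seed = 5
  )
  key <- generate_challenge(cfg)$answer_key
  expect_equal(nrow(key), 1L)
  expect_equal(key$match_mode, "ALL_OF")
  expect_length(key$variants[[1]], 2L)
})

test_that("written challenges reload consistently through the standard readers", {
  ch <- generate_challenge(challenge_config(seed = 77))
  d <- withr::local_tempdir()
  write_challenge(ch, d)
  key <- load_answer_key(file.path(d, "answer_key.tsv"))
  expect_equal(key$proband_id, ch$answer_key$proband_id)
  expect_equal(key$variants, ch$answer_key$variants)
  fam <- load_families(file.path(d, "families.ped"), file.path(d, "hpo.tsv"))
  m <- match(ch$families$proband_id, fam$proband_id)
  expect_false(anyNA(m))
  expect_equal(fam$completeness[m], ch$families$completeness)
  expect_equal(fam$hpo_terms[m], ch$families$hpo_terms)
  expect_true(all(fam$completeness %in% completeness_levels()))
})

test_that("expected mean rank points is the band-probability dot product", {
  expect_equal(expected_mean_rank_points(skill_profile(c(1, 0, 0, 0, 0, 0))), 100)
  expect_equal(expected_mean_rank_points(skill_profile(c(0, 1, 0, 0, 0, 0))), 50)
  expect_equal(
    expected_mean_rank_points(skill_profile(c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1))),
    37.5
  )
  expect_error(skill_profile(c(0.5, 0.5, 0.1, 0, 0, 0)), "sum to 1")
  expect_error(skill_profile(rep(1 / 6, 6), epcr_causal = c(0, 1)), "epcr_causal")
})

test_that("degenerate skills hit their analytic extremes exactly", {
  ch <- generate_challenge(challenge_config(seed = 9))
  top <- generate_model_submission(
    ch, skill_profile(c(1, 0, 0, 0, 0, 0)), seed = 1
  )
  o <- score_model(top, ch$answer_key, near_miss_warn = FALSE)
  expect_true(all(o$matched))
  expect_true(all(o$match_rank <= 5))
  expect_equal(mean_rank_points(o), 100)
  bottom <- generate_model_submission(
    ch, skill_profile(c(0, 0, 0, 0, 0, 1)), seed = 1
  )
  ob <- score_model(bottom, ch$answer_key, near_miss_warn = FALSE)
  expect_false(any(ob$matched))
  expect_equal(mean_rank_points(ob), 0)
})

test_that("a mixed skill recovers its expectation over many solved probands", {
  # E[score] = 50 for a half-top-five, half-miss skill; with n solved
  # probands the Monte-Carlo SE of the mean is 50/sqrt(n)
  n <- 250L
  ch <- generate_challenge(challenge_config(
    n_solved = n, n_unsolved = 0, include_cis_pair = FALSE, seed = 31
  ))
  sk <- skill_profile(c(0.5, 0, 0, 0, 0, 0.5), n_preds = 20L)
  s <- generate_model_submission(ch, sk, seed = 13)
  o <- score_model(s, ch$answer_key, near_miss_warn = FALSE)
  se <- 50 / sqrt(n)
  expect_lt(abs(mean_rank_points(o) - 50), 3 * se)
})

test_that("generated submissions pass validation with zero errors", {
  ch <- generate_challenge(challenge_config(seed = 3))
  s <- generate_model_submission(
    ch, skill_profile(c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02)), seed = 8
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_submission(s, f)
  out <- validate_submission(f)
  expect_equal(nrow(out$report$errors), 0L)
  expect_equal(nrow(out$report$warnings), 0L) # EPCRs sorted by construction
  expect_equal(sum(out$report$counts$dropped), 0L)
  # miscalibrated generation trips the monotonicity warning path
  s2 <- generate_model_submission(
    ch, skill_profile(c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02)),
    seed = 8, miscalibrated = TRUE
  )
  out2 <- clean_submission(s2)
  expect_true(any(out2$report$warnings$code == "EPCR_NOT_MONOTONIC"))
})

test_that("unreachable bands are rejected up front", {
  ch <- generate_challenge(challenge_config(seed = 2))
  sk <- skill_profile(c(0.5, 0, 0, 0, 0.5, 0), n_preds = 40L) # band 51-100 unreachable
  expect_error(generate_model_submission(ch, sk, seed = 1), "unreachable")
})

test_that("stochastically better skills never score worse under shared band draws", {
  ch <- generate_challenge(challenge_config(seed = 21))
  skA <- skill_profile(c(0.8, 0.1, 0.05, 0.02, 0.02, 0.01))
  skB <- skill_profile(c(0.3, 0.2, 0.15, 0.1, 0.1, 0.15))
  for (seed in 1:8) {
    oa <- score_model(generate_model_submission(ch, skA, seed = seed),
                      ch$answer_key, near_miss_warn = FALSE)
    ob <- score_model(generate_model_submission(ch, skB, seed = seed),
                      ch$answer_key, near_miss_warn = FALSE)
    expect_gte(mean_rank_points(oa), mean_rank_points(ob))
  }
})

test_that("a wider causal/decoy EPCR gap does not lower the median F-max", {
  ch <- generate_challenge(challenge_config(seed = 55))
  fmax_med <- function(causal, decoy) {
    vals <- vapply(1:6, function(seed) {
      s <- generate_model_submission(
        ch,
        skill_profile(c(0.7, 0.15, 0.1, 0.04, 0, 0.01),
                      epcr_causal = causal, epcr_decoy = decoy,
                      n_preds = 50L),
        seed = seed
      )
      fmax_sweep(s, ch$answer_key)$fmax
    }, numeric(1))
    stats::median(vals)
  }
  no_gap <- fmax_med(c(2, 2), c(2, 2))
  wide_gap <- fmax_med(c(20, 2), c(2, 20))
  expect_gte(wide_gap, no_gap)
})

test_that("recovery error shrinks as the solved cohort grows", {
  sk <- skill_profile(c(0.4, 0.2, 0.15, 0.1, 0.05, 0.1))
  mae <- function(n_solved, reps) {
    errs <- vapply(seq_len(reps), function(r) {
      ch <- generate_challenge(challenge_config(
        n_solved = n_solved, n_unsolved = 0,
        include_cis_pair = FALSE, seed = 400 + r
      ))
      o <- score_model(generate_model_submission(ch, sk, seed = 900 + r),
                       ch$answer_key, near_miss_warn = FALSE)
      abs(mean_rank_points(o) - expected_mean_rank_points(sk))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(mae(80L, 12L), mae(10L, 12L))
})
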