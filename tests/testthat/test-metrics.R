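test_that("the point schedule maps ranks to band points", {
  expect_equal(rank_to_points(3), 100)
  expect_equal(rank_to_points(5), 100)
  expect_equal(rank_to_points(6), 50)
  expect_equal(rank_to_points(12), 25)
  expect_equal(rank_to_points(c(20, 21, 50, 51, 100)), c(25, 10, 10, 5, 5))
  expect_equal(rank_to_points(c(101, NA)), c(0, 0))
  expect_error(rank_to_points(0), ">= 1")
  expect_error(rank_points_schedule(max_rank = c(5, 5), points = c(100, 50)), "diff")
})

test_that("mean rank points reproduces hand-computed scores over 14 probands", {
  # 13 hits in the top five, one miss
  expect_equal(mean_rank_points(c(rep(1L, 13), NA)), 1300 / 14)
  expect_equal(round(mean_rank_points(c(rep(3L, 13), NA)), 1), 92.9)
  # all 14 at rank one: the maximum
  expect_equal(mean_rank_points(rep(1L, 14)), 100)
  # disjoint band occupancy: 5 in 1-5, 1 in 6-10, 2 in 11-20, 4 in 21-50,
  # 1 in 51-100, 1 miss
  ranks <- c(1L, 2L, 3L, 4L, 5L, 7L, 11L, 19L, 21L, 30L, 40L, 50L, 99L, NA)
  expect_equal(mean_rank_points(ranks), (500 + 50 + 50 + 40 + 5) / 14)
  expect_equal(round(mean_rank_points(ranks), 1), 46.1)
  expect_error(mean_rank_points(integer(0)), "zero solved")
})

test_that("mean rank points is monotone in rank and flat within bands", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      ranks <- sample(c(1:120, NA), 14, replace = TRUE)
      base <- mean_rank_points(ranks)
      i <- sample.int(14, 1)
      improved <- ranks
      improved[i] <- if (is.na(ranks[i])) 100L else max(1L, ranks[i] - sample.int(5, 1))
      expect_gte(mean_rank_points(improved), base)
    }
  })
  # invariance within a band
  expect_equal(mean_rank_points(c(1L, 6L, 11L)), mean_rank_points(c(5L, 10L, 20L)))
})

test_that("cumulative band counts enumerate correctly and never decrease", {
  expect_equal(
    unname(rank_band_counts(c(1L, 1L, 7L, 15L, NA))),
    c(2L, 2L, 3L, 4L, 4L, 4L)
  )
  expect_equal(unname(rank_band_counts(rep(NA_integer_, 5))), rep(0L, 6))
  expect_equal(unname(rank_band_counts(rep(1L, 14))), rep(14L, 6))
  withr::with_seed(7, {
    for (rep in 1:20) {
      r <- sample(c(1:150, rep(NA, 20)), 14, replace = TRUE)
      r[!is.na(r) & r > 100] <- NA
      expect_true(all(diff(rank_band_counts(r)) >= 0))
    }
  })
})

test_that("precision and recall at a threshold follow the worked example", {
  sub <- worked_example_sub()
  key <- tiny_key()
  pr <- precision_recall_at(sub, key, 0.6)
  expect_equal(unname(pr), c(0.5, 1, 2 / 3))
  pr <- precision_recall_at(sub, key, 0.7)
  expect_equal(unname(pr), c(1 / 3, 0.5, 0.4))
  # perfect model at its own threshold
  perfect <- make_sub(c("A", "B"), c("1:100:A:G", "2:200:C:T"), epcr = c(1, 1))
  expect_equal(unname(precision_recall_at(perfect, key, 1)), c(1, 1, 1))
  # empty call set
  expect_equal(unname(precision_recall_at(sub, key, 0.95)), c(0, 0, 0))
})

test_that("the F-max sweep finds the maximum and breaks ties toward the largest threshold", {
  sub <- worked_example_sub()
  key <- tiny_key()
  fx <- fmax_sweep(sub, key)
  expect_equal(fx$fmax, 2 / 3)
  # F = 2/3 at both 0.9 and 0.6; the larger (more conservative) one wins
  expect_equal(fx$threshold, 0.9)
  expect_equal(fx$mean_calls, 0.5)
  expect_equal(fx$sd_calls, stats::sd(c(1, 0)))
  expect_equal(nrow(fx$curve), 4L)
  expect_true(all(fx$curve$f >= 0 & fx$curve$f <= 1))
  expect_true(all(fx$curve$precision >= 0 & fx$curve$precision <= 1))
  expect_true(all(fx$curve$recall >= 0 & fx$curve$recall <= 1))

  perfect <- make_sub(c("A", "B"), c("1:100:A:G", "2:200:C:T"), epcr = c(1, 1))
  fp <- fmax_sweep(perfect, key)
  expect_equal(fp$fmax, 1)
  expect_equal(fp$mean_calls, 1)
  expect_equal(fp$sd_calls, 0)

  none <- make_sub(c("A", "B"), c("9:9:A:G", "8:8:C:T"), epcr = c(0.9, 0.8))
  expect_equal(fmax_sweep(none, key)$fmax, 0)

  empty <- new_submission(tibble::tibble(
    proband_id = character(0), var1 = character(0),
    var2 = character(0), epcr = numeric(0)
  ))
  fe <- fmax_sweep(empty, key)
  expect_true(is.na(fe$fmax))
  expect_true(is.na(fe$threshold))
})

test_that("recall at the minimum EPCR equals the anywhere-matched fraction", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      case <- random_case()
      o <- score_model(case$sub, case$key, near_miss_warn = FALSE)
      pr <- precision_recall_at(case$sub, case$key, min(case$sub$predictions$epcr))
      expect_equal(unname(pr["recall"]), sum(o$matched) / nrow(o))
    }
  })
})

test_that("bootstrap SE is zero for constant points, deterministic under a seed", {
  pts <- rep(100, 14)
  stat <- function(ids) mean(pts[as.integer(factor(ids, levels = paste0("P", 1:14)))])
  ids <- paste0("P", 1:14)
  expect_equal(bootstrap_se(stat, ids, B = 200, seed = 1), 0)
  v <- c(rep(100, 13), 0)
  names(v) <- ids
  stat2 <- function(s) mean(v[s])
  a <- bootstrap_se(stat2, ids, B = 500, seed = 99)
  b <- bootstrap_se(stat2, ids, B = 500, seed = 99)
  expect_identical(a, b)
  expect_error(bootstrap_se(stat2, ids, B = 1), "replicates")
})

test_that("detection counts tally models per cumulative band", {
  key <- make_key("A", TRUE, "ALL_OF", list("1:100:A:G"))
  mk <- function(rank) {
    o <- tibble::tibble(
      proband_id = "A", matched = !is.na(rank),
      match_rank = rank, matched_vset = NA_character_,
      removed_ranks = list(integer(0))
    )
    o
  }
  dc <- detection_counts(list(mk(1L), mk(7L), mk(NA_integer_)))
  expect_equal(
    unname(unlist(dc[1, -1])),
    c(1L, 1L, 2L, 2L, 2L, 2L)
  )
  dc0 <- detection_counts(list(mk(NA_integer_), mk(NA_integer_)))
  expect_equal(unname(unlist(dc0[1, -1])), rep(0L, 6))
  dc1 <- detection_counts(list(mk(1L), mk(1L), mk(1L)))
  expect_equal(unname(unlist(dc1[1, -1])), rep(3L, 6))
})

test_that("concordance is the mean per-proband Jaccard of top-k sets", {
  a <- make_sub(rep("P1", 5), sprintf("1:%d:A:G", 1:5), epcr = seq(0.9, 0.5, -0.1))
  expect_equal(concordance(a, a), 1)
  b <- make_sub(rep("P1", 5), sprintf("2:%d:C:T", 1:5), epcr = seq(0.9, 0.5, -0.1))
  expect_equal(concordance(a, b), 0)
  expect_equal(concordance(a, b), concordance(b, a))
  # top-5 sets sharing 2 of 8 distinct records
  c_vars <- c(sprintf("1:%d:A:G", 1:2), sprintf("3:%d:G:A", 1:3))
  cc <- make_sub(rep("P1", 5), c_vars, epcr = seq(0.9, 0.5, -0.1))
  expect_equal(concordance(a, cc), 2 / 8)
  # k limits the comparison depth
  a10 <- make_sub(rep("P1", 10), sprintf("1:%d:A:G", 1:10), epcr = seq(0.95, 0.5, -0.05))
  expect_equal(concordance(a10, a10, k = 5), 1)
  empty <- new_submission(tibble::tibble(
    proband_id = character(0), var1 = character(0),
    var2 = character(0), epcr = numeric(0)
  ))
  expect_true(is.na(concordance(empty, empty)))
  expect_equal(concordance(a, empty), 0)
  m <- concordance_matrix(list(a = a, b = b, c = cc))
  expect_true(isSymmetric(m))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("stratified scores split by pedigree completeness", {
  fam <- tibble::tibble(
    proband_id = c("A", "B", "C", "D", "E"),
    completeness = c("proband_only", "duo", "trio", "quad", "trio")
  )
  o <- tibble::tibble(
    proband_id = c("A", "B", "C", "D", "E"),
    matched = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    match_rank = c(1L, NA, 2L, 3L, 8L)
  )
  s <- stratified_mean_rank_points(o, fam)
  expect_equal(unname(s), c(mean(c(100, 0)), mean(c(100, 100, 50))))
  # all solved families complete: incomplete stratum undefined
  s2 <- stratified_mean_rank_points(o[3:5, ], fam)
  expect_true(is.na(s2[["incomplete"]]))
  expect_error(stratified_mean_rank_points(
    tibble::tibble(proband_id = "ZZ", matched = TRUE, match_rank = 1L), fam
  ), "family information")
})

test_that("the paired t-test matches the textbook formula and handles degeneracy", {
  r <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$p.value, 2 * stats::pt(-r$statistic, df = 2), tolerance = 1e-10)
  expect_equal(round(r$p.value, 4), 0.0742)
  # sign flip negates t, preserves p
  r2 <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p.value, r$p.value)
  # identical vectors
  r3 <- paired_t_test(c(5, 6), c(5, 6))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p.value, 1)
  # constant nonzero difference
  r4 <- paired_t_test(c(0, 0), c(2, 2))
  expect_true(is.infinite(r4$statistic) && r4$statistic > 0)
  expect_equal(r4$p.value, 0)
  expect_true(r4$degenerate)
  expect_error(paired_t_test(1, 2), "at least 2")
})
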