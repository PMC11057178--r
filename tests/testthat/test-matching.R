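ck_pair <- function() {
  make_key("P5", TRUE, "ALL_OF", list(c("7:500:C:T", "7:900:G:A")))
}

cis_key <- function() {
  make_key("P27", TRUE, "ANY_OF", list(c("10:100:A:G", "10:106:C:T")))
}

test_that("biallelic matching is unordered and rejects wrong partners", {
  key <- ck_pair()
  entry <- key[1, ]
  expect_true(match_prediction(c("7:900:G:A", "7:500:C:T"), entry))
  expect_true(match_prediction(c("7:500:C:T", "7:900:G:A"), entry))
  # correct causal variant paired with a non-causal partner is incorrect
  expect_false(match_prediction(c("7:500:C:T", "1:1:A:G"), entry))
  # a single allele of a compound-het answer does not match...
  expect_false(match_prediction("7:500:C:T", entry))
  # ...unless partial credit is explicitly enabled
  expect_true(match_prediction("7:500:C:T", entry, partial_credit = TRUE))
  expect_false(match_prediction(c("7:500:C:T", "1:1:A:G"), entry,
                                partial_credit = TRUE))
  expect_error(
    match_prediction("1:1:A:G", make_key("U", FALSE, ".", list(character(0)))[1, ]),
    "solved"
  )
})

test_that("either member of a cis equivalence group matches", {
  entry <- cis_key()[1, ]
  expect_true(match_prediction("10:100:A:G", entry))
  expect_true(match_prediction("10:106:C:T", entry))
  expect_true(match_prediction(c("10:100:A:G", "10:106:C:T"), entry))
  expect_false(match_prediction("10:999:A:G", entry))
  expect_false(match_prediction(c("10:100:A:G", "3:3:A:C"), entry))
})

test_that("equivalence resolution keeps the best-ranked member and removes the rest", {
  key <- cis_key()
  # v_a at rank 4, v_b at rank 9 among decoys
  vars <- sprintf("1:%d:A:G", 1:10)
  vars[4] <- "10:100:A:G"
  vars[9] <- "10:106:C:T"
  sub <- make_sub(rep("P27", 10), vars, epcr = seq(1, 0.1, length.out = 10))
  res <- resolve_equivalence(sub$predictions, key[1, ])
  expect_true(res$outcome$matched)
  expect_equal(res$outcome$match_rank, 4L)
  expect_equal(res$outcome$removed_ranks[[1]], 9L)
  expect_equal(nrow(res$predictions), 9L)
  # surviving records keep their original ranks (no renumbering)
  expect_equal(res$predictions$rank, setdiff(1:10, 9L))

  # single candidate deep in the list: retained, nothing removed
  vars2 <- sprintf("1:%d:A:G", 1:50)
  vars2[50] <- "10:106:C:T"
  sub2 <- make_sub(rep("P27", 50), vars2, epcr = seq(1, 0.1, length.out = 50))
  res2 <- resolve_equivalence(sub2$predictions, key[1, ])
  expect_equal(res2$outcome$match_rank, 50L)
  expect_equal(res2$outcome$removed_ranks[[1]], integer(0))

  # neither member present
  sub3 <- make_sub("P27", "1:1:A:G", epcr = 0.5)
  res3 <- resolve_equivalence(sub3$predictions, key[1, ])
  expect_false(res3$outcome$matched)
  expect_error(resolve_equivalence(sub3$predictions, ck_pair()[1, ]), "ANY_OF")
})

test_that("deleting the retained member promotes the other group member", {
  key <- cis_key()
  vars <- sprintf("1:%d:A:G", 1:10)
  vars[4] <- "10:100:A:G"
  vars[9] <- "10:106:C:T"
  sub <- make_sub(rep("P27", 10), vars, epcr = seq(1, 0.1, length.out = 10))
  o1 <- score_model(sub, key)
  expect_equal(o1$match_rank, 4L)
  # drop the rank-4 record and re-rank: the other member now matches
  kept <- sub$predictions[-4, c("proband_id", "var1", "var2", "epcr")]
  sub2 <- new_submission(kept)
  o2 <- score_model(sub2, key)
  expect_equal(o2$match_rank, 8L) # was rank 9; one record above it removed
})

test_that("score_model takes the first match and misses probands without predictions", {
  key <- make_key(
    c("A", "B", "C"), rep(TRUE, 3), rep("ALL_OF", 3),
    list("1:100:A:G", "2:200:C:T", "3:300:G:A")
  )
  sub <- make_sub(
    proband_id = c("A", "A", "A", "B"),
    var1 = c("9:9:A:G", "1:100:A:G", "1:100:A:G", "8:8:C:T"),
    epcr = c(0.9, 0.8, 0.7, 0.6)
  )
  sub <- clean_submission(sub)$submission # dedup removes the second copy
  o <- score_model(sub, key)
  expect_equal(o$proband_id, c("A", "B", "C"))
  expect_equal(o$matched, c(TRUE, FALSE, FALSE))
  expect_equal(o$match_rank, c(2L, NA_integer_, NA_integer_))
  expect_equal(attr(o, "n_solved"), 3L)
})

test_that("an empty submission scores zero matches everywhere", {
  key <- tiny_key()
  sub <- new_submission(tibble::tibble(
    proband_id = character(0), var1 = character(0),
    var2 = character(0), epcr = numeric(0)
  ))
  o <- score_model(sub, key)
  expect_equal(nrow(o), 2L)
  expect_false(any(o$matched))
  expect_equal(mean_rank_points(o), 0)
})

test_that("records below the first match never change the outcome", {
  key <- tiny_key()
  base <- make_sub(
    c("A", "A"), c("9:9:A:G", "1:100:A:G"), epcr = c(0.9, 0.8)
  )
  o1 <- score_model(base, key)
  extended <- make_sub(
    c("A", "A", "A", "A"),
    c("9:9:A:G", "1:100:A:G", "5:5:C:T", "6:6:G:A"),
    epcr = c(0.9, 0.8, 0.7, 0.6)
  )
  o2 <- score_model(extended, key)
  expect_equal(o1$match_rank, o2$match_rank)
  expect_equal(o1$matched, o2$matched)
})

test_that("probands outside the key warn, and near misses are flagged", {
  key <- tiny_key()
  sub <- make_sub(c("A", "ZZ"), c("1:100:A:G", "1:1:A:G"), epcr = c(0.9, 0.9))
  expect_warning(score_model(sub, key), "absent from the answer key")
  # same contig, 3 bp away from the required variant: representation alarm
  near <- make_sub("A", "1:103:A:G", epcr = 0.9)
  expect_warning(score_model(near, key), "near misses")
  expect_no_warning(score_model(near, key, near_miss_warn = FALSE))
})
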