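# Shared fixture builders: everything is constructed in code at test time.

# Build an answer key through its file dialect (exercising the round trip
# implicitly everywhere).
make_key <- function(proband_id, solved, match_mode, variants, label = "") {
  df <- tibble::tibble(
    proband_id = proband_id, solved = solved, match_mode = match_mode,
    variants = variants,
    label = rep_len(label, length(proband_id))
  )
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_answer_key(df, f)
  load_answer_key(f)
}

# A two-proband key with single-variant answers.
tiny_key <- function() {
  make_key(
    proband_id = c("A", "B"),
    solved = c(TRUE, TRUE),
    match_mode = c("ALL_OF", "ALL_OF"),
    variants = list("1:100:A:G", "2:200:C:T")
  )
}

# Submission from a compact spec: data frame with proband_id, var1,
# optional var2, epcr; rank = row order per proband.
make_sub <- function(proband_id, var1, var2 = NA_character_, epcr,
                     team_id = "t", model_id = 1L) {
  new_submission(
    tibble::tibble(
      proband_id = proband_id, var1 = var1,
      var2 = rep_len(var2, length(proband_id)), epcr = epcr
    ),
    team_id = team_id, model_id = model_id
  )
}

# The two-proband worked example used for the F-measure machinery:
# A: causal (1:100:A:G) at 0.9 then a decoy at 0.8;
# B: a decoy at 0.7 then causal (2:200:C:T) at 0.6.
worked_example_sub <- function() {
  make_sub(
    proband_id = c("A", "A", "B", "B"),
    var1 = c("1:100:A:G", "9:999:G:A", "8:888:T:C", "2:200:C:T"),
    epcr = c(0.9, 0.8, 0.7, 0.6)
  )
}

# Write PED lines to a temp file and return its path.
write_ped <- function(lines) {
  f <- withr::local_tempfile(fileext = ".ped", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_hpo <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Brute-force F-measure over a dense threshold grid, written independently
# of the package's unique-threshold sweep: plain loops re-deriving, from the
# definitions, which record (if any) is each solved entry's match, then
# maximizing F over an evenly spaced grid. F is piecewise constant between
# unique EPCR values, so a fine enough grid attains the true maximum.
brute_force_fmax <- function(sub, key, n_grid = 10000L) {
  solved <- key[key$solved, , drop = FALSE]
  n <- nrow(solved)
  rec_epcr <- numeric(0)
  rec_causal <- logical(0)
  for (i in seq_len(n)) {
    pid <- solved$proband_id[i]
    req <- sort(solved$variants[[i]])
    mode <- solved$match_mode[i]
    p <- sub$predictions[sub$predictions$proband_id == pid, , drop = FALSE]
    if (nrow(p) == 0L) next
    hit <- logical(nrow(p))
    for (j in seq_len(nrow(p))) {
      vs <- sort(stats::na.omit(c(p$var1[j], p$var2[j])))
      hit[j] <- if (mode == "ANY_OF") {
        (length(vs) == 1L && vs %in% req) || identical(vs, req)
      } else {
        identical(vs, req)
      }
    }
    if (mode == "ANY_OF" && sum(hit) > 1L) {
      # equivalence group: keep the best-ranked member, drop the rest
      drop <- which(hit)[-1L]
      p <- p[-drop, , drop = FALSE]
      hit <- hit[-drop]
    }
    causal <- logical(nrow(p))
    if (any(hit)) causal[which(hit)[1L]] <- TRUE # first match only
    rec_epcr <- c(rec_epcr, p$epcr)
    rec_causal <- c(rec_causal, causal)
  }
  best_f <- 0
  best_t <- NA_real_
  for (t in seq(0, 1, length.out = n_grid)) {
    tp <- sum(rec_causal & rec_epcr >= t)
    n_calls <- sum(rec_epcr >= t)
    precision <- if (n_calls == 0L) 0 else tp / n_calls
    recall <- tp / n
    f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    if (f > best_f) {
      best_f <- f
      best_t <- t
    }
  }
  list(fmax = best_f, threshold = best_t)
}

# Random small submission + key pairs for oracle comparisons.
random_case <- function(n_probands = 3L, max_records = 6L) {
  pids <- paste0("P", seq_len(n_probands))
  causal <- sprintf("%d:%d:A:G", seq_len(n_probands), 1000L + seq_len(n_probands))
  key <- make_key(
    proband_id = pids, solved = rep(TRUE, n_probands),
    match_mode = rep("ALL_OF", n_probands), variants = as.list(causal)
  )
  rows <- list()
  for (i in seq_len(n_probands)) {
    m <- sample.int(max_records, 1L)
    vars <- sprintf("%d:%d:C:T", i, sample.int(9000, m))
    if (stats::runif(1) < 0.7) {
      vars[sample.int(m, 1L)] <- causal[i]
    }
    rows[[i]] <- tibble::tibble(
      proband_id = pids[i], var1 = vars, var2 = NA_character_,
      epcr = round(stats::runif(m), 2)
    )
  }
  sub <- new_submission(do.call(rbind, rows))
  list(sub = sub, key = key)
}
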