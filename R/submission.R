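#' Construct a model submission from a prediction table
#'
#' A model submission is the ranked list of causal-variant predictions one
#' model makes for each proband. Each prediction is one variant, or an
#' unordered pair of variants proposed as compound heterozygous, with an
#' estimated probability of causal relationship (EPCR) in \[0, 1\]. Rank is
#' the 1-based position within the proband's list in submission order: file
#' order is authoritative, EPCR is not re-sorted (an EPCR/rank disagreement
#' is a calibration warning, not something to repair, since re-sorting would
#' silently move predictions across scoring bands).
#'
#' @param predictions A data frame with columns `proband_id`, `var1`, `var2`
#'   (`NA` for single-variant predictions) and `epcr`. Variants must already
#'   be canonical (see [normalize_variant()]). Row order within each proband
#'   defines rank.
#' @param team_id,model_id Identifiers carried into reports.
#' @return An object of class `model_submission`: a list with `team_id`,
#'   `model_id` and a `predictions` tibble gaining `rank` and `vset` (the
#'   canonical unordered variant-set id) columns.
#' @export
new_submission <- function(predictions, team_id = NA_character_, model_id = NA_integer_) {
  stopifnot(is.data.frame(predictions))
  req <- c("proband_id", "var1", "var2", "epcr")
  missing_cols <- setdiff(req, names(predictions))
  if (length(missing_cols)) {
    stop(sprintf("predictions lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  p <- tibble::as_tibble(predictions[req])
  p$proband_id <- as.character(p$proband_id)
  p$epcr <- as.numeric(p$epcr)
  if (nrow(p) > 0L) {
    if (anyNA(p$epcr) || any(p$epcr < 0 | p$epcr > 1)) {
      stop("epcr values must all lie in [0, 1]")
    }
    pair <- !is.na(p$var2)
    if (any(pair & p$var1 == p$var2)) {
      stop("a biallelic prediction must name two distinct variants")
    }
    # store pairs in canonical (sorted) order so the pair is an unordered set
    v1 <- ifelse(pair, pmin(p$var1, p$var2), p$var1)
    v2 <- ifelse(pair, pmax(p$var1, p$var2), NA_character_)
    p$var1 <- v1
    p$var2 <- v2
    p$rank <- stats::ave(seq_len(nrow(p)), p$proband_id, FUN = seq_along)
    p$vset <- .variant_set_id(p$var1, p$var2)
  } else {
    p$rank <- integer(0)
    p$vset <- character(0)
  }
  structure(
    list(
      team_id = as.character(team_id),
      model_id = model_id,
      predictions = p
    ),
    class = "model_submission"
  )
}

#' @export
print.model_submission <- function(x, ...) {
  cat(sprintf(
    "<model_submission> team %s, model %s: %d predictions for %d probands\n",
    x$team_id, format(x$model_id), nrow(x$predictions),
    length(unique(x$predictions$proband_id))
  ))
  invisible(x)
}

.new_validation_report <- function(errors, warnings, n_read, n_kept, dropped_by_code) {
  stopifnot(n_read == n_kept + sum(dropped_by_code))
  structure(
    list(
      errors = errors, warnings = warnings,
      counts = list(read = n_read, kept = n_kept, dropped = dropped_by_code)
    ),
    class = "validation_report"
  )
}

.empty_report_rows <- function() {
  tibble::tibble(line = integer(0), code = character(0), message = character(0))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> read %d, kept %d, dropped %d; %d error(s), %d warning(s)\n",
    x$counts$read, x$counts$kept, sum(x$counts$dropped),
    nrow(x$errors), nrow(x$warnings)
  ))
  if (sum(x$counts$dropped) > 0) {
    d <- x$counts$dropped
    for (code in names(d)) if (d[[code]] > 0) cat(sprintf("  %s: %d\n", code, d[[code]]))
  }
  invisible(x)
}

#' Parse a submission file
#'
#' Reads the tab-delimited submission dialect:
#' `proband_id<TAB>variant1<TAB>variant2<TAB>epcr`, one prediction per line,
#' `variant2 = "."` for single-variant predictions, optional `#`-prefixed
#' header lines, per-proband rank given by order of appearance. Malformed
#' lines are dropped and reported with a diagnostic code, never fatal; only
#' an unreadable file aborts. Drop codes: `FIELD_COUNT` (not 4 fields),
#' `BAD_VARIANT` (unparsable variant), `PAIR_IDENTICAL` (both variants of a
#' pair equal), `BAD_EPCR` (missing/non-numeric EPCR), `EPCR_RANGE` (EPCR
#' outside \[0, 1\]).
#'
#' @param path Path to the submission TSV.
#' @param team_id,model_id Identifiers attached to the parsed submission
#'   (defaults derive the team id from the file name).
#' @return A list with elements `submission` ([new_submission()] object) and
#'   `report` (a `validation_report`).
#' @seealso [clean_submission()], [validate_submission()]
#' @export
parse_submission <- function(path, team_id = NULL,
                             model_id = NA_integer_) {
  if (!file.exists(path)) {
    stop(sprintf("submission file not found: %s", path))
  }
  if (is.null(team_id)) {
    team_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep_line <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep_line)
  lines <- lines[keep_line]

  errors <- list()
  drop_codes <- character(0)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- trimws(f)
    if (length(f) != 4L || any(f[c(1L, 2L, 4L)] == "")) {
      errors[[length(errors) + 1L]] <- list(
        line = line_no[i], code = "FIELD_COUNT",
        message = sprintf("expected 4 tab-separated fields, got %d", length(f))
      )
      drop_codes <- c(drop_codes, "FIELD_COUNT")
      next
    }
    v1 <- .safe_normalize(f[2L])
    if (is.na(v1$key)) {
      errors[[length(errors) + 1L]] <- list(
        line = line_no[i], code = "BAD_VARIANT", message = v1$message
      )
      drop_codes <- c(drop_codes, "BAD_VARIANT")
      next
    }
    v2key <- NA_character_
    if (!f[3L] %in% c(".", "")) {
      v2 <- .safe_normalize(f[3L])
      if (is.na(v2$key)) {
        errors[[length(errors) + 1L]] <- list(
          line = line_no[i], code = "BAD_VARIANT", message = v2$message
        )
        drop_codes <- c(drop_codes, "BAD_VARIANT")
        next
      }
      v2key <- v2$key
      if (identical(v1$key, v2key)) {
        errors[[length(errors) + 1L]] <- list(
          line = line_no[i], code = "PAIR_IDENTICAL",
          message = "biallelic prediction lists the same variant twice"
        )
        drop_codes <- c(drop_codes, "PAIR_IDENTICAL")
        next
      }
    }
    epcr <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(epcr)) {
      errors[[length(errors) + 1L]] <- list(
        line = line_no[i], code = "BAD_EPCR",
        message = sprintf("EPCR '%s' is not a number", f[4L])
      )
      drop_codes <- c(drop_codes, "BAD_EPCR")
      next
    }
    if (epcr < 0 || epcr > 1) {
      errors[[length(errors) + 1L]] <- list(
        line = line_no[i], code = "EPCR_RANGE",
        message = sprintf("EPCR %g outside [0, 1]", epcr)
      )
      drop_codes <- c(drop_codes, "EPCR_RANGE")
      next
    }
    out[[i]] <- list(proband_id = f[1L], var1 = v1$key, var2 = v2key, epcr = epcr)
  }
  kept <- !vapply(out, is.null, logical(1))
  preds <- if (any(kept)) {
    k <- out[kept]
    tibble::tibble(
      proband_id = vapply(k, `[[`, character(1), "proband_id"),
      var1 = vapply(k, `[[`, character(1), "var1"),
      var2 = vapply(k, `[[`, character(1), "var2"),
      epcr = vapply(k, `[[`, numeric(1), "epcr")
    )
  } else {
    tibble::tibble(
      proband_id = character(0), var1 = character(0),
      var2 = character(0), epcr = numeric(0)
    )
  }
  err_df <- if (length(errors)) {
    tibble::tibble(
      line = vapply(errors, `[[`, numeric(1), "line"),
      code = vapply(errors, `[[`, character(1), "code"),
      message = vapply(errors, `[[`, character(1), "message")
    )
  } else {
    .empty_report_rows()
  }
  report <- .new_validation_report(
    errors = err_df, warnings = .empty_report_rows(),
    n_read = length(lines), n_kept = sum(kept),
    dropped_by_code = if (length(drop_codes)) table(drop_codes) else integer(0)
  )
  list(
    submission = new_submission(preds, team_id = team_id, model_id = model_id),
    report = report
  )
}

#' Clean a parsed submission
#'
#' Applies the assessment-side cleaning rules: within each proband,
#' predictions whose variant set duplicates an earlier (better-ranked)
#' prediction are removed (`DUPLICATE`), predictions beyond position 100 are
#' truncated (`OVER_LIMIT`), and ranks are recomputed to be consecutive.
#' EPCR monotonicity (non-increasing with rank) is checked and violations
#' are reported as warnings only — rank order is authoritative. Cleaning is
#' total and idempotent and never reorders surviving predictions.
#'
#' @param sub A `model_submission`.
#' @param max_rank Maximum predictions retained per proband (default 100).
#' @return A list with elements `submission` (cleaned) and `report`.
#' @export
clean_submission <- function(sub, max_rank = 100L) {
  stopifnot(inherits(sub, "model_submission"))
  p <- sub$predictions
  n_read <- nrow(p)
  if (n_read == 0L) {
    return(list(
      submission = sub,
      report = .new_validation_report(
        .empty_report_rows(), .empty_report_rows(), 0L, 0L, integer(0)
      )
    ))
  }
  dup <- as.logical(stats::ave(
    seq_len(nrow(p)),
    p$proband_id,
    FUN = function(i) duplicated(p$vset[i])
  ))
  kept1 <- p[!dup, , drop = FALSE]
  pos_after_dedup <- stats::ave(
    seq_len(nrow(kept1)), kept1$proband_id, FUN = seq_along
  )
  over <- pos_after_dedup > max_rank
  kept <- kept1[!over, , drop = FALSE]
  kept$rank <- as.integer(stats::ave(
    seq_len(nrow(kept)), kept$proband_id, FUN = seq_along
  ))

  warn_rows <- list()
  for (pid in unique(kept$proband_id)) {
    e <- kept$epcr[kept$proband_id == pid]
    if (length(e) > 1L && any(diff(e) > 0)) {
      warn_rows[[length(warn_rows) + 1L]] <- list(
        line = NA_integer_, code = "EPCR_NOT_MONOTONIC",
        message = sprintf(
          "proband %s: EPCR increases with rank at position(s) %s",
          pid, paste(which(diff(e) > 0) + 1L, collapse = ",")
        )
      )
    }
  }
  warn_df <- if (length(warn_rows)) {
    tibble::tibble(
      line = vapply(warn_rows, `[[`, integer(1), "line"),
      code = vapply(warn_rows, `[[`, character(1), "code"),
      message = vapply(warn_rows, `[[`, character(1), "message")
    )
  } else {
    .empty_report_rows()
  }

  dropped <- c(DUPLICATE = sum(dup), OVER_LIMIT = sum(over))
  dropped <- dropped[dropped > 0]
  report <- .new_validation_report(
    errors = .empty_report_rows(), warnings = warn_df,
    n_read = n_read, n_kept = nrow(kept), dropped_by_code = dropped
  )
  cleaned <- new_submission(
    kept[c("proband_id", "var1", "var2", "epcr")],
    team_id = sub$team_id, model_id = sub$model_id
  )
  list(submission = cleaned, report = report)
}

#' Parse and clean a submission file, returning the combined report
#'
#' Convenience wrapper used by the `validate` command-line entry point: runs
#' [parse_submission()] then [clean_submission()] and merges their reports.
#'
#' @inheritParams parse_submission
#' @return A list with `submission` (cleaned) and `report` (merged
#'   `validation_report`).
#' @export
validate_submission <- function(path, team_id = NULL, model_id = NA_integer_) {
  parsed <- parse_submission(path, team_id = team_id, model_id = model_id)
  cleaned <- clean_submission(parsed$submission)
  pr <- parsed$report
  cr <- cleaned$report
  dropped <- c(pr$counts$dropped, cr$counts$dropped)
  report <- .new_validation_report(
    errors = rbind(pr$errors, cr$errors),
    warnings = rbind(pr$warnings, cr$warnings),
    n_read = pr$counts$read,
    n_kept = cr$counts$kept,
    dropped_by_code = dropped
  )
  list(submission = cleaned$submission, report = report)
}

#' Write a submission in the challenge TSV dialect
#'
#' Inverse of [parse_submission()] (up to header comments); parsing the
#' written file reproduces an equal submission.
#'
#' @param sub A `model_submission`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(sub, path) {
  stopifnot(inherits(sub, "model_submission"))
  p <- sub$predictions
  lines <- c(
    "# proband_id\tvariant1\tvariant2\tepcr",
    sprintf(
      "%s\t%s\t%s\t%s",
      p$proband_id, p$var1,
      ifelse(is.na(p$var2), ".", p$var2),
      sprintf("%.17g", p$epcr)
    )
  )
  writeLines(lines, path)
  invisible(path)
}
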