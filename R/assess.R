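#' Assess a set of model submissions against an answer key
#'
#' Runs the full pipeline for every submission — parse (if given paths),
#' clean, match against the answer key, compute the rank-weighted
#' mean-points metric and the maximum F-measure with bootstrap standard
#' errors — and assembles the cohort-level summaries: per-entry detection
#' counts, the pairwise top-k concordance matrix, and (when family
#' information is supplied) per-model scores stratified by pedigree
#' completeness with a paired t-test contrasting complete against
#' incomplete pedigrees across models.
#'
#' Individual unreadable submissions are reported and skipped; only an
#' unreadable answer key is fatal. All bootstrap randomness derives from
#' `seed`.
#'
#' @param answer_key An `answer_key` object or path to an answer-key TSV.
#' @param submissions A named list of `model_submission`s, a character
#'   vector of submission file paths, or a directory containing `*.tsv`
#'   submissions (one model per file).
#' @param families Optional: a family table from [load_families()], or a
#'   list/vector of `c(ped_path, hpo_path)`; enables the stratified
#'   analysis.
#' @param B Bootstrap replicates per metric (default 1000).
#' @param k Depth of the concordance comparison (default 5).
#' @param seed Master seed for all bootstrap resampling.
#' @param partial_credit See [match_prediction()].
#' @return An object of class `assessment_run`: list with `reports` (one
#'   row per model, ordered by descending mean rank points, ties broken by
#'   descending F-max, with dual rankings from [rank_models()]),
#'   `detection` (per-entry model counts), `concordance` (matrix),
#'   `stratified` (per-model stratum scores), `paired_test`, `outcomes`
#'   (per-model `match_outcomes`), `fcurves` and `config`.
#' @export
assess <- function(answer_key, submissions, families = NULL,
                   B = 1000L, k = 5L, seed = 1L, partial_credit = FALSE) {
  key <- if (is.character(answer_key)) load_answer_key(answer_key) else answer_key
  stopifnot(inherits(key, "answer_key"))
  fam <- NULL
  if (!is.null(families)) {
    fam <- if (is.data.frame(families)) {
      families
    } else {
      load_families(families[[1L]], if (length(families) > 1L) families[[2L]] else NULL)
    }
  }

  subs <- .collect_submissions(submissions)
  if (length(subs) == 0L) {
    stop("no submissions to assess")
  }

  solved <- .solved_entries(key)
  n_solved <- nrow(solved)
  cleaned <- lapply(subs, function(s) clean_submission(s)$submission)
  outcomes <- list()
  strat <- list()
  rows <- vector("list", length(subs))
  fcurves <- list()
  for (i in seq_along(subs)) {
    sub <- cleaned[[i]]
    o <- score_model(sub, key, partial_credit = partial_credit,
                     near_miss_warn = FALSE)
    outcomes[[names(subs)[i]]] <- o
    points <- rank_to_points(o$match_rank)
    names(points) <- o$proband_id
    mrp <- mean(points)
    mrp_se <- bootstrap_se(
      function(ids) mean(points[ids]),
      ids = o$proband_id, B = B, seed = seed + i
    )
    fx <- fmax_sweep(sub, key, partial_credit = partial_credit)
    rec <- .solved_records(sub, key, partial_credit)
    fx_se <- if (is.na(fx$fmax)) {
      NA_real_
    } else {
      rec_by <- split(rec[c("epcr", "is_causal")], rec$proband_id)
      bootstrap_se(
        function(ids) {
          pieces <- rec_by[ids]
          pieces <- pieces[!vapply(pieces, is.null, logical(1))]
          if (length(pieces) == 0L) return(0)
          e <- unlist(lapply(pieces, `[[`, "epcr"), use.names = FALSE)
          cz <- unlist(lapply(pieces, `[[`, "is_causal"), use.names = FALSE)
          max(.fmax_curve(e, cz, n_solved)$f)
        },
        ids = o$proband_id, B = B, seed = seed + 100000L + i
      )
    }
    bands <- rank_band_counts(o)
    rows[[i]] <- tibble::tibble(
      model = names(subs)[i],
      team_id = sub$team_id,
      model_id = sub$model_id,
      n_rank_1 = bands[["rank_1"]],
      n_rank_1_5 = bands[["rank_1_5"]],
      n_rank_1_10 = bands[["rank_1_10"]],
      n_rank_1_20 = bands[["rank_1_20"]],
      n_rank_1_50 = bands[["rank_1_50"]],
      n_rank_1_100 = bands[["rank_1_100"]],
      mean_rank_points = mrp,
      mean_rank_points_se = mrp_se,
      fmax = fx$fmax,
      fmax_se = fx_se,
      fmax_threshold = fx$threshold,
      mean_calls = fx$mean_calls,
      sd_calls = fx$sd_calls
    )
    fcurves[[names(subs)[i]]] <- fx$curve
    if (!is.null(fam)) {
      strat[[names(subs)[i]]] <- stratified_mean_rank_points(o, fam)
    }
  }
  reports <- do.call(rbind, rows)
  ord <- order(-reports$mean_rank_points,
               -ifelse(is.na(reports$fmax), -Inf, reports$fmax))
  reports <- reports[ord, , drop = FALSE]
  reports <- rank_models(reports)

  detection <- detection_counts(outcomes)
  conc <- concordance_matrix(cleaned, k = k)

  stratified <- NULL
  paired <- NULL
  if (!is.null(fam) && length(strat)) {
    stratified <- tibble::tibble(
      model = names(strat),
      incomplete = vapply(strat, `[[`, numeric(1), "incomplete"),
      complete = vapply(strat, `[[`, numeric(1), "complete")
    )
    usable <- !is.na(stratified$incomplete) & !is.na(stratified$complete)
    if (sum(usable) >= 2L) {
      paired <- paired_t_test(stratified$incomplete[usable],
                              stratified$complete[usable])
    }
  }

  structure(
    list(
      config = list(
        B = as.integer(B), k = as.integer(k), seed = as.integer(seed),
        partial_credit = partial_credit, n_solved = n_solved,
        n_models = length(subs)
      ),
      reports = reports, detection = detection, concordance = conc,
      stratified = stratified, paired_test = paired,
      outcomes = outcomes, fcurves = fcurves
    ),
    class = "assessment_run"
  )
}

.collect_submissions <- function(submissions) {
  if (inherits(submissions, "model_submission")) {
    submissions <- list(submissions)
  }
  if (is.character(submissions)) {
    if (length(submissions) == 1L && dir.exists(submissions)) {
      paths <- sort(list.files(submissions, pattern = "\\.tsv$", full.names = TRUE))
      paths <- paths[!basename(paths) %in% c("answer_key.tsv", "hpo.tsv")]
    } else {
      paths <- submissions
    }
    if (length(paths) == 0L) {
      stop("no submission files found")
    }
    subs <- list()
    for (p in paths) {
      parsed <- tryCatch(parse_submission(p), error = function(e) e)
      if (inherits(parsed, "error")) {
        warning(sprintf("skipping unreadable submission %s: %s",
                        p, conditionMessage(parsed)))
        next
      }
      subs[[sub("\\.tsv$", "", basename(p))]] <- parsed$submission
    }
    return(subs)
  }
  stopifnot(is.list(submissions),
            all(vapply(submissions, inherits, logical(1), "model_submission")))
  if (is.null(names(submissions)) || any(!nzchar(names(submissions)))) {
    names(submissions) <- sprintf("model_%02d", seq_along(submissions))
  }
  submissions
}

#' Dual model rankings by the two assessment metrics
#'
#' Ranks models independently by mean rank points and by F-max, using
#' competition ("1224") ranking so equal metric values share an identical,
#' visible rank. Models without an F-max (empty submissions) rank after all
#' scored models.
#'
#' @param reports The per-model report tibble from [assess()] (any data
#'   frame with `mean_rank_points` and `fmax` columns).
#' @return `reports` with `rank_by_points` and `rank_by_fmax` columns.
#' @export
rank_models <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  comp_rank <- function(v) {
    w <- ifelse(is.na(v), -Inf, v)
    vapply(w, function(z) 1L + sum(w > z), integer(1))
  }
  reports$rank_by_points <- comp_rank(reports$mean_rank_points)
  reports$rank_by_fmax <- comp_rank(reports$fmax)
  reports
}

#' @export
print.assessment_run <- function(x, ...) {
  cat(sprintf(
    "<assessment_run> %d models against %d solved probands (B = %d bootstrap replicates)\n",
    x$config$n_models, x$config$n_solved, x$config$B
  ))
  r <- x$reports
  cat(sprintf(
    "  top model: %s (mean rank points %.1f +/- %.1f, F-max %s)\n",
    r$model[1L], r$mean_rank_points[1L], r$mean_rank_points_se[1L],
    ifelse(is.na(r$fmax[1L]), "NA", sprintf("%.2f +/- %.2f", r$fmax[1L], r$fmax_se[1L]))
  ))
  if (!is.null(x$paired_test)) {
    cat(sprintf(
      "  complete vs incomplete pedigrees: paired t = %.3f, p = %.2g\n",
      x$paired_test$statistic, x$paired_test$p.value
    ))
  }
  invisible(x)
}

#' Write assessment outputs to a directory
#'
#' Emits `models_report.tsv` (one row per model, metrics rounded to one
#' decimal as in published report tables; full precision stays in the R
#' object), `detection_counts.tsv` (one row per solved entry),
#' `concordance.tsv`, `stratified.tsv` (when computed), `fcurves.json`
#' (full precision-recall curves) and `run.json` (config snapshot).
#'
#' @param run An `assessment_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assessment <- function(run, dir) {
  stopifnot(inherits(run, "assessment_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- run$reports
  out <- data.frame(
    model = r$model, team_id = r$team_id, model_id = r$model_id,
    rank_1 = r$n_rank_1, rank_1_5 = r$n_rank_1_5, rank_1_10 = r$n_rank_1_10,
    rank_1_20 = r$n_rank_1_20, rank_1_50 = r$n_rank_1_50,
    rank_1_100 = r$n_rank_1_100,
    mean_rank_points = round(r$mean_rank_points, 1),
    mean_rank_points_se = round(r$mean_rank_points_se, 1),
    fmax = round(r$fmax, 2),
    fmax_se = round(r$fmax_se, 2),
    fmax_threshold = r$fmax_threshold,
    mean_calls = round(r$mean_calls, 2),
    sd_calls = round(r$sd_calls, 2),
    rank_by_points = r$rank_by_points,
    rank_by_fmax = r$rank_by_fmax
  )
  utils::write.table(out, file.path(dir, "models_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(as.data.frame(run$detection),
    file.path(dir, "detection_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(model = rownames(run$concordance),
               round(run$concordance, 4), check.names = FALSE),
    file.path(dir, "concordance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(run$stratified)) {
    st <- run$stratified
    st$incomplete <- round(st$incomplete, 1)
    st$complete <- round(st$complete, 1)
    utils::write.table(as.data.frame(st), file.path(dir, "stratified.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  jsonlite::write_json(
    lapply(run$fcurves, function(cv) as.list(as.data.frame(cv))),
    file.path(dir, "fcurves.json"),
    digits = NA
  )
  cfg <- run$config
  if (!is.null(run$paired_test)) {
    cfg$paired_test <- run$paired_test[c("statistic", "p.value", "df")]
  }
  jsonlite::write_json(cfg, file.path(dir, "run.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
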