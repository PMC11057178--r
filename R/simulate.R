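#' Skill profile of a simulated prediction model
#'
#' A synthetic model is described by where it tends to place the causal
#' variant and how well calibrated its EPCR scores are:
#'
#' * `band_probs` — probability of the causal variant landing in each rank
#'   band (1-5, 6-10, 11-20, 21-50, 51-100) or being missed entirely; must
#'   sum to 1.
#' * `epcr_causal`, `epcr_decoy` — Beta(shape1, shape2) parameters for the
#'   EPCR of the causal prediction and of decoy predictions. A larger gap
#'   between the two means separates causal from decoy scores and drives
#'   F-max upward.
#' * `n_preds` — list length per proband. The defaults emulate a cohort of
#'   submissions spanning strong to weak performers; real challenge
#'   submissions ranged from 0 to 100 predictions per proband with a median
#'   of 100, hence the default of 100.
#'
#' @param band_probs Numeric vector of 6 probabilities (five bands + miss).
#' @param epcr_causal,epcr_decoy Length-2 positive numerics: Beta shape1,
#'   shape2.
#' @param n_preds Predictions per proband (1-100).
#' @return A list of class `skill_profile`.
#' @export
skill_profile <- function(band_probs = c(0.6, 0.15, 0.1, 0.05, 0.05, 0.05),
                          epcr_causal = c(8, 2),
                          epcr_decoy = c(2, 8),
                          n_preds = 100L) {
  band_probs <- as.numeric(band_probs)
  if (length(band_probs) != 6L || any(band_probs < 0)) {
    stop("band_probs must be 6 non-negative probabilities (bands 1-5, 6-10, 11-20, 21-50, 51-100, miss)")
  }
  if (abs(sum(band_probs) - 1) > 1e-9) {
    stop("band_probs must sum to 1 (within 1e-9)")
  }
  stopifnot(
    length(epcr_causal) == 2L, all(epcr_causal > 0),
    length(epcr_decoy) == 2L, all(epcr_decoy > 0),
    n_preds >= 1L, n_preds <= 100L
  )
  structure(
    list(
      band_probs = band_probs,
      epcr_causal = as.numeric(epcr_causal),
      epcr_decoy = as.numeric(epcr_decoy),
      n_preds = as.integer(n_preds)
    ),
    class = "skill_profile"
  )
}

.BAND_BOUNDS <- cbind(lower = c(1L, 6L, 11L, 21L, 51L), upper = c(5L, 10L, 20L, 50L, 100L))

#' Expected mean rank points of a skill profile
#'
#' Closed-form expectation of the rank-points metric under a skill profile:
#' the dot product of the band probabilities with the band point values
#' (points are constant within a band, so the within-band rank placement is
#' irrelevant). This is the analytic oracle the end-to-end recovery tests
#' compare assessed scores against.
#'
#' @param skill A [skill_profile()].
#' @param schedule A [rank_points_schedule()].
#' @return One number.
#' @export
expected_mean_rank_points <- function(skill, schedule = rank_points_schedule()) {
  stopifnot(inherits(skill, "skill_profile"))
  sum(skill$band_probs * c(schedule$points, schedule$miss_points))
}

#' Configuration of a synthetic challenge
#'
#' Defaults mirror a rare-disease challenge test set: 30 families of which
#' 14 are solved and 16 unsolved; pedigree completeness mixing 2
#' proband-only, 3 duo, 23 trio and 2 quad families; solved diagnoses
#' spanning de novo dominant, compound-heterozygous recessive, homozygous
#' recessive, X-linked recessive and sex-limited dominant inheritance
#' (weights 10/14, 1/14, 1/14, 1/14, 1/14); and one cis-pair answer whose
#' two variants are equally acceptable.
#'
#' @param n_solved,n_unsolved Family counts (`n_solved >= 1`).
#' @param completeness_mix Named weights over `proband_only`, `duo`, `trio`,
#'   `quad` (normalized internally).
#' @param inheritance_mix Named weights over `de_novo`, `ar_comphet`,
#'   `ar_hom`, `xlr`, `dom_sex_limited` (normalized internally).
#' @param include_cis_pair Include one ANY_OF cis-pair answer (default
#'   `TRUE`).
#' @param n_decoys Size of the decoy variant pool (>= 10000).
#' @param seed Seed making the whole challenge deterministic.
#' @return A list of class `challenge_config`.
#' @export
challenge_config <- function(n_solved = 14L, n_unsolved = 16L,
                             completeness_mix = c(
                               proband_only = 2, duo = 3, trio = 23, quad = 2
                             ),
                             inheritance_mix = c(
                               de_novo = 10, ar_comphet = 1, ar_hom = 1,
                               xlr = 1, dom_sex_limited = 1
                             ),
                             include_cis_pair = TRUE,
                             n_decoys = 10000L,
                             seed = 1L) {
  stopifnot(n_solved >= 1L, n_unsolved >= 0L, n_decoys >= 10000L)
  norm_mix <- function(m, allowed, what) {
    if (is.null(names(m)) || !all(names(m) %in% allowed) || any(m < 0) || sum(m) <= 0) {
      stop(sprintf("%s must be non-negative weights named among: %s",
                   what, paste(allowed, collapse = ", ")))
    }
    full <- stats::setNames(numeric(length(allowed)), allowed)
    full[names(m)] <- m
    full / sum(full)
  }
  structure(
    list(
      n_solved = as.integer(n_solved),
      n_unsolved = as.integer(n_unsolved),
      completeness_mix = norm_mix(completeness_mix, completeness_levels(),
                                  "completeness_mix"),
      inheritance_mix = norm_mix(
        inheritance_mix,
        c("de_novo", "ar_comphet", "ar_hom", "xlr", "dom_sex_limited"),
        "inheritance_mix"
      ),
      include_cis_pair = isTRUE(include_cis_pair),
      n_decoys = as.integer(n_decoys),
      seed = as.integer(seed)
    ),
    class = "challenge_config"
  )
}

.HPO_VOCAB <- c(
  "HP:0001250", "HP:0001263", "HP:0001252", "HP:0000252", "HP:0001249",
  "HP:0000365", "HP:0000505", "HP:0002194", "HP:0001344", "HP:0002376",
  "HP:0001290", "HP:0000717", "HP:0001508", "HP:0002133", "HP:0000486",
  "HP:0002059", "HP:0008947", "HP:0001518", "HP:0000750", "HP:0011968"
)

.random_variants <- function(n, contigs = c(as.character(1:22), "X"),
                             max_pos = 250000000L) {
  contig <- sample(contigs, n, replace = TRUE)
  pos <- sample.int(max_pos, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  paste(contig, pos, ref, alt, sep = ":")
}

#' Generate a complete synthetic challenge
#'
#' Produces families (pedigrees plus proband HPO terms), an answer key, and
#' a decoy variant pool, deterministically under the config seed. Solved
#' entries receive one causal variant, an `ALL_OF` pair for
#' compound-heterozygous recessive inheritance (two variants in the same
#' region of one contig), or — for the designated cis-pair family — an
#' `ANY_OF` pair of two variants 6 bp apart. Decoy variants are sampled
#' uniformly over contigs 1-22 and X and are disjoint from all causal
#' variants; allele-frequency spectra and gene context are deliberately not
#' modeled because no assessment metric consumes them.
#'
#' @param cfg A [challenge_config()].
#' @return A list of class `challenge`: `config`, `families` (as from
#'   [load_families()]), `answer_key`, `decoys` (character vector), `ped`
#'   and `hpo` tibbles ready for [write_challenge()].
#' @export
generate_challenge <- function(cfg = challenge_config()) {
  stopifnot(inherits(cfg, "challenge_config"))
  withr::with_seed(cfg$seed, .generate_challenge_impl(cfg))
}

.generate_challenge_impl <- function(cfg) {
  n <- cfg$n_solved + cfg$n_unsolved
  fam_id <- sprintf("F%03d", seq_len(n))
  proband_id <- sprintf("P%03d", seq_len(n))
  solved <- sample(rep(c(TRUE, FALSE), c(cfg$n_solved, cfg$n_unsolved)))
  completeness <- sample(
    completeness_levels(), n, replace = TRUE, prob = cfg$completeness_mix
  )
  inheritance <- rep(NA_character_, n)
  inheritance[solved] <- sample(
    names(cfg$inheritance_mix), cfg$n_solved, replace = TRUE,
    prob = cfg$inheritance_mix
  )
  cis_idx <- NA_integer_
  if (cfg$include_cis_pair) {
    cand <- which(solved & inheritance == "dom_sex_limited")
    cis_idx <- if (length(cand)) cand[1L] else which(solved)[1L]
    inheritance[cis_idx] <- "dom_sex_limited"
  }

  # causal variants first, then a decoy pool disjoint from them
  n_causal_slots <- sum(solved & inheritance %in% c("ar_comphet")) * 2L +
    sum(solved & !inheritance %in% c("ar_comphet"))
  if (cfg$include_cis_pair) n_causal_slots <- n_causal_slots + 1L
  causal_pool_x <- normalize_variant(.random_variants(n_causal_slots, contigs = "X"))
  causal_pool_auto <- normalize_variant(.random_variants(n_causal_slots * 2L))
  decoys <- unique(normalize_variant(.random_variants(ceiling(cfg$n_decoys * 1.05))))

  xi <- 0L
  ai <- 0L
  next_x <- function() {
    xi <<- xi + 1L
    causal_pool_x[xi]
  }
  next_auto <- function() {
    ai <<- ai + 1L
    causal_pool_auto[ai]
  }

  variants <- vector("list", n)
  match_mode <- rep(".", n)
  sex <- sample(c("1", "2"), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (!solved[i]) {
      variants[[i]] <- character(0)
      next
    }
    mode_i <- inheritance[i]
    if (identical(i, cis_idx)) {
      # two variants in cis, 6 bp apart, either acceptable
      v1 <- variant_fields(next_auto())
      v2 <- sprintf("%s:%d:%s:%s", v1$contig, v1$pos + 6L,
                    sample(c("A", "C", "G", "T"), 1L),
                    sample(c("A", "C", "G", "T"), 1L))
      while (inherits(try(normalize_variant(v2), silent = TRUE), "try-error")) {
        v2 <- sprintf("%s:%d:%s:%s", v1$contig, v1$pos + 6L,
                      sample(c("A", "C", "G", "T"), 1L),
                      sample(c("A", "C", "G", "T"), 1L))
      }
      variants[[i]] <- sort(c(v1$key, normalize_variant(v2)))
      match_mode[i] <- "ANY_OF"
      sex[i] <- "2" # sex-limited expression in females
    } else if (mode_i == "ar_comphet") {
      # two hits in the same gene region: same contig, within 100 kb
      v1 <- variant_fields(next_auto())
      v2 <- sprintf(
        "%s:%d:%s:%s", v1$contig, max(1L, v1$pos - sample.int(100000L, 1L)),
        "G", "A"
      )
      variants[[i]] <- sort(c(v1$key, normalize_variant(v2)))
      match_mode[i] <- "ALL_OF"
    } else if (mode_i == "xlr") {
      variants[[i]] <- next_x()
      match_mode[i] <- "ALL_OF"
      sex[i] <- "1" # hemizygous male proband
    } else {
      variants[[i]] <- next_auto()
      match_mode[i] <- "ALL_OF"
      if (mode_i == "dom_sex_limited") sex[i] <- "2"
    }
  }
  causal <- unique(unlist(variants))
  decoys <- setdiff(decoys, causal)
  if (length(decoys) < cfg$n_decoys) {
    stop("decoy pool generation fell short; increase n_decoys")
  }
  decoys <- decoys[seq_len(cfg$n_decoys)]

  key <- .new_answer_key(tibble::tibble(
    proband_id = proband_id, solved = solved, match_mode = match_mode,
    variants = variants,
    label = ifelse(solved, inheritance, "")
  ))

  # pedigrees: rows only for sequenced members, parent ids always named
  ped_rows <- vector("list", n)
  hpo_rows <- vector("list", n)
  fam_rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fam_id[i]
    p <- proband_id[i]
    fa <- paste0(f, "_FAT")
    mo <- paste0(f, "_MOT")
    sib <- paste0(f, "_SIB")
    comp <- completeness[i]
    rows <- list(c(f, p, fa, mo, sex[i], "2"))
    members <- tibble::tibble(
      individual_id = p, relation = "proband", affected = TRUE
    )
    if (comp %in% c("trio", "quad")) {
      rows <- c(rows, list(c(f, fa, "0", "0", "1", "1"), c(f, mo, "0", "0", "2", "1")))
      members <- rbind(
        members,
        tibble::tibble(
          individual_id = c(fa, mo), relation = c("father", "mother"),
          affected = FALSE
        )
      )
    } else if (comp == "duo") {
      which_parent <- sample(c("father", "mother"), 1L)
      if (which_parent == "father") {
        rows <- c(rows, list(c(f, fa, "0", "0", "1", "1")))
        members <- rbind(members, tibble::tibble(
          individual_id = fa, relation = "father", affected = FALSE
        ))
      } else {
        rows <- c(rows, list(c(f, mo, "0", "0", "2", "1")))
        members <- rbind(members, tibble::tibble(
          individual_id = mo, relation = "mother", affected = FALSE
        ))
      }
    }
    if (comp == "quad") {
      rows <- c(rows, list(c(f, sib, fa, mo, sample(c("1", "2"), 1L), "2")))
      members <- rbind(members, tibble::tibble(
        individual_id = sib, relation = "sibling", affected = TRUE
      ))
    }
    ped_rows[[i]] <- do.call(rbind, rows)
    terms <- sort(sample(.HPO_VOCAB, sample(2:6, 1L)))
    hpo_rows[[i]] <- c(p, paste(terms, collapse = ","))
    fam_rows[[i]] <- tibble::tibble(
      family_id = f, proband_id = p, completeness = comp,
      hpo_terms = list(terms), members = list(members)
    )
  }
  ped <- as.data.frame(do.call(rbind, ped_rows), stringsAsFactors = FALSE)
  names(ped) <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "affected")
  hpo_m <- do.call(rbind, hpo_rows)
  hpo <- tibble::tibble(individual_id = hpo_m[, 1L], hpo_terms = hpo_m[, 2L])
  families <- do.call(rbind, fam_rows)

  structure(
    list(
      config = cfg, families = families, answer_key = key,
      decoys = decoys, ped = tibble::as_tibble(ped), hpo = hpo
    ),
    class = "challenge"
  )
}

#' @export
print.challenge <- function(x, ...) {
  cat(sprintf(
    "<challenge> %d families (%d solved, %d unsolved), %d decoy variants, seed %d\n",
    nrow(x$families), attr(x$answer_key, "n_solved"),
    attr(x$answer_key, "n_unsolved"), length(x$decoys), x$config$seed
  ))
  invisible(x)
}

#' Simulate one model's submission for a synthetic challenge
#'
#' For each solved proband an outcome band is drawn from the skill's
#' `band_probs` (these uniforms are the generator's first RNG block, drawn
#' for all solved probands up front, so two skills simulated under the same
#' seed face identical band draws — a paired design that lets skill
#' profiles be compared without between-model sampling noise). If the
#' outcome is not a miss, the causal prediction — the full required pair
#' for an `ALL_OF` answer, one member (plus, half the time, the other
#' member lower down, exercising equivalence-group resolution) for an
#' `ANY_OF` answer — is placed at a uniform-random rank within the band
#' among decoy predictions. Unsolved probands receive decoys only.
#'
#' The causal EPCR is drawn from the skill's causal Beta law; decoy EPCRs
#' are drawn from the decoy Beta law conditioned to respect the causal
#' prediction's rank (inverse-CDF sampling above/below the causal EPCR) and
#' sorted, so rank order and EPCR order agree by construction. With
#' `miscalibrated = TRUE` EPCRs are left i.i.d. and unsorted, which
#' exercises the EPCR-monotonicity warning path in [clean_submission()].
#'
#' @param challenge A [generate_challenge()] result.
#' @param skill A [skill_profile()].
#' @param seed Optional seed (models sharing a seed share band draws).
#' @param team_id,model_id Identifiers for reports.
#' @param miscalibrated Disable EPCR sorting (default `FALSE`).
#' @return A `model_submission` that passes [validate_submission()]-style
#'   cleaning unchanged.
#' @export
generate_model_submission <- function(challenge, skill, seed = NULL,
                                      team_id = "sim", model_id = 1L,
                                      miscalibrated = FALSE) {
  stopifnot(inherits(challenge, "challenge"), inherits(skill, "skill_profile"))
  run <- function() {
    .generate_submission_impl(challenge, skill, team_id, model_id, miscalibrated)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.generate_submission_impl <- function(challenge, skill, team_id, model_id,
                                      miscalibrated) {
  key <- challenge$answer_key
  solved <- key[key$solved, , drop = FALSE]
  n_preds <- skill$n_preds
  active <- which(skill$band_probs[1:5] > 0)
  if (length(active) && any(.BAND_BOUNDS[active, "lower"] > n_preds)) {
    stop(sprintf(
      "band %d is unreachable with n_preds = %d", max(active), n_preds
    ))
  }
  # first RNG block: band draws for all solved probands (common random
  # numbers across skills under a shared seed)
  u <- stats::runif(nrow(solved))
  band <- findInterval(u, cumsum(skill$band_probs)) + 1L # 1..5 band, 6 = miss

  a_c <- skill$epcr_causal[1L]
  b_c <- skill$epcr_causal[2L]
  a_d <- skill$epcr_decoy[1L]
  b_d <- skill$epcr_decoy[2L]
  rbeta_trunc <- function(m, lo, hi) {
    if (m == 0L) return(numeric(0))
    plo <- stats::pbeta(lo, a_d, b_d)
    phi <- stats::pbeta(hi, a_d, b_d)
    stats::qbeta(stats::runif(m, plo, phi), a_d, b_d)
  }

  v1_l <- vector("list", nrow(key))
  v2_l <- vector("list", nrow(key))
  e_l <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    pid <- key$proband_id[i]
    si <- if (key$solved[i]) match(pid, solved$proband_id) else NA_integer_
    b <- if (key$solved[i]) band[si] else 6L
    if (b > 5L) {
      # miss or unsolved proband: decoys only
      e <- stats::rbeta(n_preds, a_d, b_d)
      if (!miscalibrated) e <- sort(e, decreasing = TRUE)
      v1_l[[i]] <- sample(challenge$decoys, n_preds)
      v2_l[[i]] <- rep(NA_character_, n_preds)
      e_l[[i]] <- e
      next
    }
    req <- key$variants[[i]]
    mode <- key$match_mode[i]
    lb <- .BAND_BOUNDS[b, "lower"]
    ub <- min(.BAND_BOUNDS[b, "upper"], n_preds)
    r <- lb + sample.int(ub - lb + 1L, 1L) - 1L
    var1 <- rep(NA_character_, n_preds)
    var2 <- rep(NA_character_, n_preds)
    if (mode == "ALL_OF" && length(req) == 2L) {
      var1[r] <- req[1L]
      var2[r] <- req[2L]
    } else if (mode == "ANY_OF") {
      pick <- sample(req, 1L)
      var1[r] <- pick
      if (length(req) == 2L && r < n_preds && stats::runif(1L) < 0.5) {
        other <- setdiff(req, pick)
        r2 <- r + sample.int(n_preds - r, 1L)
        var1[r2] <- other
      }
    } else {
      var1[r] <- req[1L]
    }
    open <- which(is.na(var1))
    var1[open] <- sample(challenge$decoys, length(open))
    e_c <- stats::rbeta(1L, a_c, b_c)
    if (miscalibrated) {
      e <- stats::rbeta(n_preds, a_d, b_d)
      e[r] <- e_c
    } else {
      e <- numeric(n_preds)
      e[r] <- e_c
      above <- seq_len(r - 1L)
      below <- if (r < n_preds) (r + 1L):n_preds else integer(0)
      e[above] <- sort(rbeta_trunc(length(above), e_c, 1), decreasing = TRUE)
      e[below] <- sort(rbeta_trunc(length(below), 0, e_c), decreasing = TRUE)
    }
    v1_l[[i]] <- var1
    v2_l[[i]] <- var2
    e_l[[i]] <- e
  }
  preds <- tibble::tibble(
    proband_id = rep(key$proband_id, lengths(v1_l)),
    var1 = unlist(v1_l, use.names = FALSE),
    var2 = unlist(v2_l, use.names = FALSE),
    epcr = unlist(e_l, use.names = FALSE)
  )
  new_submission(preds, team_id = team_id, model_id = model_id)
}

#' Write a synthetic challenge to a directory
#'
#' Emits `families.ped`, `hpo.tsv`, `answer_key.tsv` and a `manifest.json`
#' recording every generation parameter and the seed, so a challenge
#' directory is self-describing and reproducible.
#'
#' @param challenge A [generate_challenge()] result.
#' @param dir Output directory (created if needed).
#' @param submissions Optional named list of `model_submission`s written as
#'   `<name>.tsv` alongside the challenge files.
#' @return `dir`, invisibly.
#' @export
write_challenge <- function(challenge, dir, submissions = NULL) {
  stopifnot(inherits(challenge, "challenge"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- challenge$ped
  writeLines(
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s",
      ped$family_id, ped$individual_id, ped$father_id, ped$mother_id,
      ped$sex, ped$affected
    ),
    file.path(dir, "families.ped")
  )
  writeLines(
    sprintf("%s\t%s", challenge$hpo$individual_id, challenge$hpo$hpo_terms),
    file.path(dir, "hpo.tsv")
  )
  write_answer_key(challenge$answer_key, file.path(dir, "answer_key.tsv"))
  manifest <- list(
    n_solved = challenge$config$n_solved,
    n_unsolved = challenge$config$n_unsolved,
    completeness_mix = as.list(challenge$config$completeness_mix),
    inheritance_mix = as.list(challenge$config$inheritance_mix),
    include_cis_pair = challenge$config$include_cis_pair,
    n_decoys = challenge$config$n_decoys,
    seed = challenge$config$seed,
    submissions = if (is.null(submissions)) list() else as.list(names(submissions))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  if (!is.null(submissions)) {
    for (nm in names(submissions)) {
      write_submission(submissions[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  invisible(dir)
}
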