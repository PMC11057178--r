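# varbench

Assessment tools for **ranked causal-variant prioritization models** in
rare-disease cohorts — the assessor's side of a community benchmark in
which models submit, per proband, up to 100 ranked variant predictions
(single variants or proposed compound-heterozygous pairs), each with an
estimated probability of causal relationship (EPCR) in [0, 1], and are
scored against an answer key of solved families.

For whom: anyone organizing or replicating such a benchmark, or validating
a prioritization tool against a cohort with known causal variants.

## The metrics

For each of the *n* solved families, let *r* be the rank of the first
prediction matching the answer (matching rules below). Two headline
metrics are computed per model:

* **Mean rank points** — a band-weighted award,

  | rank | 1–5 | 6–10 | 11–20 | 21–50 | 51–100 | miss |
  |------|-----|------|-------|-------|--------|------|
  | points | 100 | 50 | 25 | 10 | 5 | 0 |

  averaged over all *n* solved entries (skipped probands are misses).

* **F-max** — at EPCR threshold *t*, calls = predictions for solved
  probands with EPCR ≥ *t*, TP = solved entries whose matching prediction
  is called (≤ 1 per entry); precision = TP/calls, recall = TP/*n*,
  F = 2PR/(P+R). F-max is the maximum over all unique submitted EPCR
  values; ties resolve to the largest (most conservative) threshold.

Both metrics get a bootstrap standard error from resampling the solved
probands with replacement (B = 1000). Matching is strict: a compound-het
answer requires the exact unordered pair (a correct variant with a wrong
partner is incorrect), and a cis-pair answer accepts either member, with
all other predictions of the group removed before scoring.

## Worked example

Simulate a 30-family challenge (14 solved, 16 unsolved) and three models
of graded skill, then assess them:

```r
library(varbench)
ch <- generate_challenge(challenge_config(seed = 42))
subs <- list(
  strong   = generate_model_submission(ch, skill_profile(c(0.8, 0.1, 0.05, 0.02, 0.02, 0.01)),
                                       seed = 101, team_id = "alpha"),
  middling = generate_model_submission(ch, skill_profile(c(0.4, 0.2, 0.15, 0.1, 0.05, 0.1)),
                                       seed = 102, team_id = "beta"),
  weak     = generate_model_submission(ch, skill_profile(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.5)),
                                       seed = 103, team_id = "gamma")
)
run <- assess(ch$answer_key, subs, families = ch$families, B = 1000, seed = 7)
run
#> <assessment_run> 3 models against 14 solved probands (B = 1000 bootstrap replicates)
#>   top model: strong (mean rank points 91.1 +/- 5.9, F-max 0.33 +/- 0.06)
#>   complete vs incomplete pedigrees: paired t = 3.427, p = 0.076
run$reports[, c("model", "n_rank_1", "n_rank_1_5", "mean_rank_points",
                "mean_rank_points_se", "fmax", "rank_by_points")]
#>      model n_rank_1 n_rank_1_5 mean_rank_points mean_rank_points_se  fmax rank_by_points
#> 1   strong        2         12             91.1                 5.9 0.325              1
#> 2 middling        0          2             39.6                 8.5 0.105              2
#> 3     weak        1          3             33.6                10.3 0.105              3
```

Reading the rows: the "strong" model found the causal variant(s) in 12 of
14 solved families within the top five (2 at rank one), worth 91.1 mean
rank points ± 5.9 (bootstrap SE); its best F-measure over EPCR thresholds
is 0.325. `run$detection` counts models per solved entry and band,
`run$concordance` holds the pairwise top-5 Jaccard matrix, and
`write_assessment(run, dir)` writes the report tables as TSV.

Submission files are plain TSV (`proband  variant1  variant2|.  epcr`);
`parse_submission()` / `clean_submission()` read and sanitize them with
per-line diagnostics, never failing on a malformed line. A thin command
line (`inst/cli/varbench`) wraps the same functions as `assess`,
`validate` and `simulate` subcommands.

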