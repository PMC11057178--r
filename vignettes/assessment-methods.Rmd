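---
title: "Assessing ranked causal-variant prioritization models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ranked causal-variant prioritization models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varbench)
```

## The assessment problem

In a variant-prioritization benchmark, each participating model receives
genome-wide variant calls and HPO phenotype terms for a cohort of
rare-disease families and returns, per proband, a ranked list of up to 100
predictions. A prediction is either a single variant or a proposed
compound-heterozygous pair (two variants submitted jointly on one line), and
carries an estimated probability of causal relationship (EPCR) in $[0, 1]$.
An answer key, established by expert analysis and clinical confirmation,
records the causal variant set for each *solved* family; *unsolved*
families are included so that models cannot tell which probands count, but
only solved families enter the metrics.

`varbench` implements the assessor's side of such a challenge: reading and
cleaning submissions, matching predictions to the key under the rules
below, computing the two headline metrics with bootstrap standard errors,
and producing the secondary summaries (per-entry detection counts, top-k
concordance between models, and scores stratified by pedigree
completeness). Because real cohorts of this kind are under controlled
access, the package also ships a synthetic challenge generator, which is
first-class, tested code: every pipeline stage can be exercised end to end
on data with known ground truth.

## Matching rules

Variant identity is exact string identity of `CONTIG:POS:REF:ALT` after
normalization (strip `chr`, uppercase alleles). No left-alignment or allele
minimalization is attempted: all parties share one canonical call set, and
silently repairing representations would hide mismatches a real assessment
would count as misses. As a guard, `score_model()` warns when a missed
entry has a predicted variant on the right contig within 10 bp of a
required variant.

Two special answer-key semantics generalize the cases that arise in
practice:

* **`ALL_OF`** (compound heterozygous): the prediction must be the exact
  unordered pair. A single allele does not match, and a correct causal
  variant paired with a non-causal partner in a proposed biallelic
  prediction is scored as incorrect. The strict reading is the default; a
  `partial_credit` flag (off by default, for exploratory use) lets a
  single-allele hit count, because whether the original assessments
  credited such hits is not documented.
* **`ANY_OF`** (cis pair): when two variants lie on one haplotype and
  either may be causal, a prediction of either member is correct. All
  predictions matching any group member refer to the same answer, so the
  best-ranked one is retained and the rest are deleted before any metric
  is computed. Surviving predictions keep their original ranks: the
  retained match is by construction the best-ranked, so its band is
  unaffected, and renumbering would move unrelated predictions across
  scoring bands.

Within each proband, rank is file order. EPCR is *not* used to re-sort:
submissions are ranked by causal likelihood by their authors, and
re-sorting on EPCR would invisibly change band membership. An EPCR that
increases with rank is surfaced as a calibration warning
(`EPCR_NOT_MONOTONIC`), never repaired.

## Metrics

**Mean rank points.** A hit within the top 5 earns 100 points, top 10
earns 50, top 20 earns 25, top 50 earns 10, top 100 earns 5, and a miss 0.
The model's score is the arithmetic mean over all $n$ solved entries
($n = 14$ in the reference configuration). The denominator is fixed at the
number of solved entries — a proband the model skipped is a miss, not an
excluded observation; this convention reproduces every recomputable
published score from its band counts. The steep decay mirrors clinical
review capacity: only a handful of top-ranked variants get full ACMG/AMP
curation.

```{r}
mean_rank_points(c(rep(1L, 13), NA))   # 13 top-five hits, one miss, n = 14
```

**F-max.** At an EPCR threshold $t$, the call set is every prediction for
a solved proband with EPCR $\ge t$; a true positive is a solved entry
whose matching prediction is in the call set (at most one per entry).
Precision is $TP/\text{calls}$, recall is $TP/n$, and
$F = 2PR/(P+R) = 2\,TP/(\text{calls} + n)$. $F$ is piecewise constant
between unique EPCR values, so sweeping the unique values is exhaustive;
the tests verify this against a brute-force dense-grid oracle. Ties are
broken toward the **largest** threshold — the smallest, most conservative
call set, which is the clinically safer operating point; the convention is
isolated in `fmax_sweep()`. Predictions for unsolved probands enter
neither numerator nor denominator. Alongside F-max the sweep reports the
winning threshold and the mean ± SD of calls per proband at that
threshold (probands without calls contribute 0).

**Bootstrap standard errors.** For both metrics, the solved probands are
resampled with replacement $B = 1000$ times and the metric recomputed per
replicate; the SE is the standard deviation of the replicates (denominator
$B-1$). F-max is re-swept within each replicate. For the mean of
per-proband points the bootstrap SE converges to
$\sqrt{\widehat{\sigma}^2_{\text{pop}}/n}$, which the tests check at
$B = 10^5$.

**Secondary summaries.** Detection counts report, per solved entry, how
many models placed the causal variant(s) in each cumulative band. Pairwise
concordance is the mean per-proband Jaccard index of the top-5 variant-set
collections (a biallelic prediction is one element); the formula for the
published concordance figure is not documented, so this choice is isolated
in `concordance()` where an overlap coefficient or pooled Jaccard could be
swapped in. The stratified analysis contrasts mean rank points on
incomplete pedigrees (proband-only, duo) against complete ones (trio,
quad) and applies a paired two-sided Student's t-test across models
(delegating to `stats::t.test()`, with degenerate cases — all differences
zero, or constant nonzero differences — handled explicitly).

Model rankings use competition ("1224") ranking so tied metric values
share a visible rank, matching how tied models appear in published report
tables.

## The synthetic challenge generator

`generate_challenge()` emulates the *structure* of a real test set, not
its biology. Defaults are the reference cohort: 30 families, 14 solved and
16 unsolved; completeness weights 2 proband-only : 3 duo : 23 trio : 2
quad; solved inheritance weights 10 de novo : 1 compound-het recessive : 1
homozygous recessive : 1 X-linked recessive : 1 sex-limited dominant; and
one cis-pair `ANY_OF` answer whose two variants sit 6 bp apart. Decoy
variants (a pool of at least $10^4$, disjoint from all causal variants)
are uniform over contigs 1–22 and X with positions in $[1, 2.5\times10^8]$
and random SNV alleles. Allele-frequency spectra, gene context, and
genotype likelihoods are deliberately not modeled: no assessment metric
consumes them, and adding them would only make the fixture slower without
sharpening any test. HPO terms are sampled from a small fixed vocabulary
and carried through the readers but unused by the metrics — phenotype
matching is the predictors' job, not the assessor's.

A simulated model is a `skill_profile()`: band probabilities for where the
causal prediction lands (or a miss), Beta laws for causal and decoy EPCRs,
and a list length (default 100, the median observed in real submissions).
The causal EPCR is drawn from its Beta law; decoy EPCRs are drawn from the
decoy law *conditioned* (by inverse-CDF truncation) to lie above or below
the causal EPCR according to their rank, then sorted. File order, rank and
EPCR are therefore mutually consistent by construction, and a
`miscalibrated` flag disables the sorting to exercise the monotonicity
warning path.

```{r}
sk <- skill_profile(c(0.6, 0.15, 0.1, 0.05, 0.05, 0.05))
expected_mean_rank_points(sk)
```

### Validating the pipeline end to end

`recovery_experiment()` generates many independent challenges, simulates
one submission per profile of a ten-step `skill_ladder()`, and assesses
them. Two design choices matter here:

* Within a replicate, all skills share the generator seed, and the
  generator draws the per-proband band uniforms as its first RNG block.
  All models therefore face identical band draws — a paired,
  common-random-numbers design, the standard variance-reduction technique
  for comparing simulated policies. With 14 solved probands and ten models
  spaced ~10 expected points apart, independent randomness would swap
  adjacent models in roughly a quarter of replicates no matter how correct
  the pipeline is; pairing removes that between-model noise so that
  ordering errors can only come from defects in matching or scoring.
* The ladder's band distributions are stochastically ordered (each
  profile's cumulative band mass dominates the next), so under the paired
  design the expected ordering can never be inverted by a correct
  pipeline, while across replicates each model's mean score remains an
  unbiased estimate of its analytic expectation
  (`expected_mean_rank_points()`).

The validation suite runs 100 replicates of the 14-solved/16-unsolved
configuration with ten models of 100 predictions each, checks every
model's mean assessed score against its expectation at 3 Monte-Carlo
standard errors, and requires the expected ordering to be recovered (no
pairwise inversion) in at least 95% of replicates. Bootstrap convergence
is checked at $B = 10^3$ (tolerance 0.5 points) and $B = 10^5$ (tolerance
0.1); the F-max sweep is compared to a $10^4$-point dense-grid oracle on
100 randomized small submissions.

What passing these tests does *not* show: performance on real data with
shared artifacts between models, realistic EPCR distributions, or
representation mismatches between a model's variant normalizer and the
challenge VCF — the strict matcher plus the near-miss warning is the
package's answer to the last of these, but only real submissions can
trigger it meaningfully. Published F-max values, their SEs, the observed
concordance distribution, and the stratified t-test p-value all depend on
the original (unpublished) EPCR values and cannot be recomputed at desk
scale; the property checks above are what stands in for them.

## Numerical and degenerate-input conventions

* Skill band probabilities must sum to 1 within $10^{-9}$; mixes given as
  counts are normalized.
* An empty submission yields 0 mean rank points and an `NA` F-max result
  (not an error), mirroring how a withdrawn team appears in a report.
* A model calling nothing above a threshold has precision 0 (not NaN);
  $P + R = 0$ gives $F = 0$.
* `bootstrap_se()` requires $B \ge 2$; given a seed it leaves the caller's
  RNG state untouched (`withr::with_seed`).
* Cleaning is total and idempotent: duplicates within a proband keep the
  best-ranked copy, lists are truncated at 100, and ranks are renumbered
  consecutively afterwards.
* All randomness in `assess()` derives from one master seed recorded in
  the run config; re-running writes byte-identical reports.

## Limitations

The generator does not simulate reads, genotype quality, allele
frequencies, or any specific prediction method; its skill profiles are a
device for testing the assessor, not a model of predictor behavior.
Matching is variant-level only — gene-level credit, fuzzy representation
matching, and HPO semantic similarity are out of scope. Only SNVs and
small indels on GRCh38 contigs 1–22, X, Y, MT are representable.
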