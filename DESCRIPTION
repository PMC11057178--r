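Package: varbench
Title: Assessment of Ranked Causal-Variant Prioritization Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarking tools for variant prioritization models in
    rare-disease cohorts. Parses and validates ranked per-proband variant
    submissions carrying estimated probabilities of causal relationship
    (EPCR), matches predictions against an answer key with
    compound-heterozygous (all-of) and cis-equivalence (any-of) semantics,
    and scores each model by rank-weighted mean points and the maximum
    F-measure over EPCR thresholds, with bootstrap standard errors obtained
    by resampling solved probands. Includes detection-count, concordance and
    pedigree-completeness stratified summaries, and a synthetic challenge
    generator (families, answer keys, skill-parameterized model submissions)
    so the full pipeline can be exercised and validated without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
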