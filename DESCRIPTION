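Package: dtmr
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("dtmr", "maintainers", email = "dtmr@example.org", role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization using GWAS
    summary statistics: reading and validating summary-statistics tables,
    cis-window instrument selection with tri-biomarker concordance
    filtering and LD clumping, exposure/outcome harmonization with
    palindromic-SNP handling, two-sample causal estimation (Wald ratio,
    fixed-effects inverse-variance weighting, weighted median, MR-Egger),
    Cochran's Q heterogeneity testing, approximate-Bayes-factor
    colocalization over the five standard hypotheses, a synthetic
    summary-statistics simulator with known ground truth, and a pipeline
    that orchestrates a full proxied-inhibition study from one YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
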