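Package: pqtlmr
Title: Proteome-Wide Mendelian Randomization and Colocalization from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for drug-target prioritization from plasma-protein
    quantitative trait loci (cis-pQTLs): instrument selection with a
    cis-window, genome-wide-significance and weak-instrument filters plus
    greedy LD clumping; two-sample Mendelian randomization estimators
    (Wald ratio, fixed-effect inverse-variance weighting, MR-Egger) with
    Cochran's Q heterogeneity and Benjamini-Hochberg FDR prioritization;
    Bayesian colocalization over the five sharing hypotheses from
    Wakefield approximate Bayes factors; reverse-direction and
    lifestyle-exposure MR modes; and a fully seeded generator of synthetic
    GWAS summary statistics with known regional LD and causal structure,
    so every pipeline stage can be validated without access to
    individual-level or restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
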