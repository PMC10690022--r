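Package: nmdx
Title: Diagnostic Genomics Toolkit for Neuromuscular Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of genomic diagnosis in multinational
    neuromuscular disease (NMD) cohorts. Provides a synthetic-cohort
    generator with planted ground-truth diagnoses; variant prioritization
    using inheritance-specific minor-allele-frequency filters and
    phenotype/gene-panel matching; an ACMG evidence-combining engine with
    solved / possibly-solved / unsolved outcome rules and variant-novelty
    determination; a dystrophin (DMD) structural-variant engine implementing
    the reading-frame rule, severity prediction, intron-breakpoint hotspot
    summaries and single-exon-skipping amenability; and cohort-level
    statistics including an exact Fisher test for r x c contingency tables
    implemented from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
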