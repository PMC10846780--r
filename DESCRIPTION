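Package: tmbflow
Title: Tumor Mutation Burden Estimation from Tumor-Only Exome Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tumor mutation burden (TMB) from tumor-only
    whole-exome small-variant call sets using staged filtration: quality
    and coding-consequence filtration, three-level germline elimination
    (population allele frequency, variant allele fraction bands, and a
    healthy-donor baseline panel), and per-sample TMB scoring. Includes
    matched tumor-normal subtraction as a validation workflow, a
    four-metric sequencing-QC scoring and gating scheme, cohort-level
    statistics (percentile distributions, bootstrap ninth-decile
    estimation, Kruskal-Wallis cohort comparison), and a synthetic
    matched-cohort generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
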