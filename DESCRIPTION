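Package: hpamethyl
Title: Targeted DNA-Methylation Analysis of HPA-Axis Genes After Paediatric Critical Illness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A targeted epigenome-wide association workflow for comparing
    buccal-mucosa DNA methylation between former paediatric-intensive-care
    patients and healthy children: sample and probe quality control on
    beta-value matrices, technical-variation adjustment via principal
    components of array control probes, empirical-Bayes moderated per-CpG
    linear models with Benjamini-Hochberg false-discovery control,
    kernel-smoothed detection of differentially methylated regions,
    sex/age interaction and glucocorticoid-subgroup contrasts, and a
    repeated cross-validation plus Fisher's-method assessment of the
    robustness of methylation-outcome associations. Includes a synthetic
    cohort simulator with batch effects expressed in technical control
    probes, and a packaged reference table of differentially methylated
    positions for regression testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
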