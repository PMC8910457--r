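Package: palconcord
Title: Pathway Activation Level Scoring and Transcriptome-Proteome
    Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes pathway activation levels (PAL) from bulk expression
    profiles by aggregating role-weighted, significance-gated log
    case-to-normal ratios over annotated gene sets, and quantifies the
    concordance between paired transcriptomic and proteomic profiles at
    the gene and pathway levels. Includes median-of-ratios size-factor
    normalization and read-count quality gating for RNA-seq input, exact
    Wilcoxon signed-rank comparison of paired correlation distributions,
    pathway ranking tables, sign-concordance summaries, and a synthetic
    paired-omics generator with known latent pathway activities and
    closed-form expected correlations for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
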