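Package: cometscreen
Title: Simulation, Quantification and Genotoxicity Calling for Microwell-Array
    Comet Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput comet assays run on micropatterned
    agarose microwell arrays. Provides a mechanistic damage/repair-trapping
    model that maps exposure scenarios (agent, dose, genotype, CYP450
    metabolic capacity, repair-synthesis inhibitors) to single-strand-break
    burdens and percent tail DNA; a synthetic fluorescence-field generator
    with per-comet ground truth; lattice registration and per-comet
    segmentation yielding percent tail DNA and tail moment; a gamma-radiation
    standard curve converting changes in percent tail DNA into strand breaks
    per cell; and replicate-well statistics (Dunnett many-to-one comparisons,
    two-way ANOVA with Bonferroni contrasts, paired t-tests) feeding a
    genotoxicity screen caller with an optional cell-viability threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    multcomp,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
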