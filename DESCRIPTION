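Package: repamp
Title: Technical-Replicate Reproducibility Analysis for Amplicon OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reproducibility of amplicon (e.g. 16S
    rRNA gene) sequencing from technical replicates. Implements OTU overlap
    statistics between and among technical replicates (unweighted and
    sequence-abundance weighted), singleton and unique-OTU filtering rules,
    rarefaction without replacement with an analytic expected-richness
    oracle, overlap-versus-depth saturation profiling, alpha and beta
    diversity summaries across a nested location/treatment/replicate design,
    and a null-model PERMDISP-style test of whether technical replicates
    differ more than random sequence sampling predicts. Includes a
    synthetic-data generator that emulates the sampling structure of a
    replicated soil amplicon experiment, with multinomial or
    Dirichlet-multinomial replicate noise and depth-scaling spurious OTUs.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
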