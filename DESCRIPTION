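Package: polykaryo
Title: Molecular Karyotyping and Apomixis Mapping in Polysomic Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of F1 pseudo-testcross populations in
    polysomic polyploids such as hexaploid brachiaria grasses. Provides a
    forward simulator of bivalent polysomic meiosis (random or preferential
    pairing, compensated aneuploidy, GBS-like read counts), read-threshold
    genotype calling with parental imputation from selfed contaminants,
    single- versus double-dose marker classification, molecular karyotyping by
    all-pairs Fisher exact tests with coupling/repulsion tiering and LOD-based
    homolog grouping, closed-form single-dose by double-dose coupling linkage
    models with maximum-likelihood recombination estimation, subgenome
    uniformity tests, and cosegregation scanning for a dominant apospory
    locus. Tidyverse-native: data frames in, tibbles out, with broom-style
    tidiers and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
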