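Package: ufsim
Title: Simulation of Unnecessarily Failed Unrelated Stem-Cell-Donor Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds virtual unrelated stem-cell-donor registries from five-locus
    HLA haplotype frequencies and simulates matching-probability-guided donor
    searches with a limited budget of typing requests. Quantifies the share of
    unnecessarily failed searches (UFS) -- searches that end without identifying
    a donor although a fully HLA-matched donor is registered -- as a function of
    registry size, typing-profile composition, search strategy, typing-request
    budget and haplotype diversity. Includes an EM estimator for haplotype
    frequencies from unphased (possibly partially typed) phenotypes,
    Hardy-Weinberg effect-size diagnostics at broad-antigen resolution, and a
    synthetic haplotype-frequency generator for fully reproducible studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
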