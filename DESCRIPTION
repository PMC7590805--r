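Package: kaspdiv
Title: Diversity, Differentiation and Selection Scans for KASP Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic analysis of biallelic KASP (kompetitive
    allele-specific PCR) genotype panels stratified by agro-ecological zone,
    breeding-era group and release decade. Computes allele and carrier
    frequencies, nucleotide diversity (pi), Nei's Gst (Fst) with island-model
    gene flow (Nm), Nei (1972) genetic identity and distance,
    neighbor-joining trees, principal component analysis of allele dosages,
    empirical top-5 percent selective-sweep scans (Fst and pi-ratio), allele
    surveys with fixed-variant and rare-allele counts, and pairwise
    differentiation grids. Includes a Balding-Nichols panel simulator with
    injected selection shifts so that every statistic can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
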