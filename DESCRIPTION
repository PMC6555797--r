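Package: segdrive
Title: Gamete Killer-Protector Genetics: Segregation Distortion, Drive, and
    Haplotype Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models single-locus gamete killer-protector systems of the kind
    underlying interspecific rice hybrid sterility. Predicts gamete viability,
    hybrid pollen and spikelet fertility, and progeny segregation for arbitrary
    multi-locus crosses under a sporophytic killer / gametophytic protector
    model; tests observed genotype-class counts against model expectations with
    chi-square goodness-of-fit and transmission-ratio statistics; estimates the
    gamete abortion probability by maximum likelihood; simulates deterministic
    and Wright-Fisher allele-frequency drive across generations; and classifies
    locus haplotype structures from SNP-panel states and breadth-of-coverage
    presence/absence calls. Includes a synthetic-data generator for progeny
    count tables, per-base depth profiles, and accession panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
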