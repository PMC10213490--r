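Package: rarepatterns
Title: Sample-Size-Corrected Geographic Distribution Patterns of Rare and
    Common Genetic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rarefaction-based correction for comparing rare and common
    genetic variation across populations with unequal sample sizes. Computes
    exact hypergeometric probabilities that an allelic type is unobserved,
    rare, or common (or in an arbitrary frequency window) in a subsample of
    fixed size g drawn without replacement from each population; combines
    per-population class probabilities into multi-population geographic
    distribution patterns (e.g. RUUUU) and their (|U|,|R|,|C|) summary
    triples; and scans genomes in nonoverlapping windows with per-window
    pattern-group probabilities and rank tracks. Includes extraction of
    per-population minor-allele counts from VCF, a synthetic panel
    generator with controlled frequency structure, and an
    exhaustive-enumeration oracle for validating the closed forms.
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
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
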