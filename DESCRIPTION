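Package: ddcbetools
Title: Target Design and Off-Target Analysis for DddA-Derived Cytosine Base
    Editors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing DddA-derived cytosine base editors (DdCBEs)
    against organellar genomes and for quantifying their editing outcomes from
    deep sequencing. Enumerates 5'-TC deamination targets on circular or
    linear genomes, finds paired (dimeric DdCBE) and single (monomeric mDdCBE)
    TALE placements under thymidine-end, length and spacer constraints, and
    summarises which motifs each architecture can reach. Calls per-position
    C-to-T / G-to-A conversion rates from aligned reads, applies SNV and
    on-target exclusion filters to produce genome-wide off-target summaries,
    and profiles editing frequencies relative to TALE binding sites to recover
    the monomeric editing window. A deterministic simulator generates genomes
    with planted designs and aligned read sets with programmed substitution
    fractions so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
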