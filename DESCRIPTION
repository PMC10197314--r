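Package: circseam
Title: Back-Splice Junction Primer Design for Circular RNA Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs circle-specific PCR primer sets for circular RNAs
    (circRNAs) called by common back-splice junction predictors. Parses
    coordinate files from CIRI2, find_circ, CIRCexplorer2, DCC,
    circRNA_finder, KNIFE, mapsplice and plain BED into a canonical table,
    extracts junction-spanning templates from a reference genome (local
    FASTA or cached NCBI assembly), enumerates and ranks primer pairs whose
    amplicon crosses the back-splice junction using an internal
    nearest-neighbor melting-temperature engine, screens candidates for
    hairpins and self-dimers, checks locus-windowed linear-genome
    specificity, and recommends thermocycling conditions. Includes a
    deterministic synthetic-fixture generator emitting planted circRNA
    truth sets in every supported predictor dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
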