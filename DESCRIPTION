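Package: selms
Title: Decoding Barcode-Free Self-Encoded Small-Molecule Libraries from Tandem MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for affinity-selection mass spectrometry with self-encoded
    combinatorial small-molecule libraries, where screening hits are identified
    by their own MS/MS fragmentation instead of an attached barcode. Enumerates
    combinatorial libraries from building-block tables with exact monoisotopic
    masses, predicts fragment ions from a scaffold-aware fragment-type grammar,
    filters and annotates centroided LC-MS/MS runs (mzML) against the enumerated
    library, subtracts bead-only control background, and computes per-building-block
    hypergeometric enrichment statistics for hit calling. Includes a ground-truthed
    synthetic-spectra simulator for end-to-end evaluation of recall and false
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    mzR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
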