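Package: ntcnmr
Title: Interpreting 31P NMR Parameters of B-DNA via Dinucleotide
    Conformer (NtC) Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies DNA backbone torsion snapshots into NtC
    dinucleotide conformer classes by minimal circular distance in
    torsion space, computes per-phosphate conformer populations and
    class-conditional torsion probability distributions, averages
    per-class 31P chemical shieldings and 3J(P,H3') couplings by
    population weighting or probability averaging, references chemical
    shifts to an internal phosphate standard, fits grouped BI'/BII'
    conformer populations to experimental observables, and analyses
    temperature series of shifts and populations. Includes a synthetic
    trajectory and parameter-table generator emulating a B-DNA
    dodecamer so the full pipeline is testable without molecular
    dynamics data.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
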