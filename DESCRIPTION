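Package: vdjlens
Title: Lymphocyte Fractions, Class Switching and Repertoire Diversity from
    WGS Read Depth over V(D)J Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates circulating and infiltrating T cell and B cell
    fractions from whole-genome sequencing read depth over the TCRA, TCRB,
    TCRG and IGH loci. Somatic V(D)J recombination deletes the DNA between
    the rearranged V and J segments, producing a depth dip proportional to
    lymphocyte content; the dip is modelled as a monotone segment-step
    deletion curve fitted by weighted isotonic regression, yielding the cell
    fraction and V/J segment usage with bootstrap uncertainty. Includes
    immunoglobulin class-switch decomposition over IGH constant genes, a
    germline IGH copy-number variant caller, Shannon and Jensen-Shannon
    segment-usage diversity, tumour purity and local copy-number adjustment,
    a coverage simulator for validation, and a command-line interface.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml,
    Rsamtools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
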