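Package: openpept
Title: Open Protein Identification with a Mass-Sorted Nonspecific Peptide Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for open (enzyme- and modification-unrestricted) peptide
    identification from tandem mass spectra. Proteins from a FASTA database are
    digested in silico (specific, semispecific or nonspecific), enumerated
    peptides are stored in a mass-sorted fixed-width index with constant-time
    first-position lookup, and spectra are identified by precursor-mass range
    retrieval. Open searching resolves an unexplained precursor mass difference
    against an inverted index of post-translational modifications sorted by
    delta mass, assigning a modification identity and site. The database and
    the spectra can be partitioned (balancing amino-acid counts, mass-sorting
    spectra) for multi-worker search whose merged result is identical to the
    monolithic one. A synthetic-data generator plants peptides and
    modifications in simulated databases and spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
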