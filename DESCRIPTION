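Package: crcevo
Title: Multiregion Evolutionary Analysis of Colitis-Associated Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of colitis-associated
    colorectal cancer from multiregion sequencing data. Builds maximum-parsimony
    phylogenies from mutation presence/absence with bootstrap support and
    homoplasy index, classifies mutations into field, truncal, shared-subclonal
    and private compartments, deconvolves 96-channel trinucleotide mutation
    catalogues into non-negative signature exposures, quantifies copy-number
    burden (percent genome altered including copy-neutral LOH), calls arm-level
    events and compares their cohort frequencies, and reconstructs copy-number
    parsimony trees from 500-kbp binned profiles to detect punctuated bursts of
    chromosomal alteration at the dysplasia transition. Includes a synthetic
    multiregion cohort generator with known clone trees so every stage can be
    validated against ground truth, and self-contained implementations of the
    exact statistical tests the analysis relies on (Fisher's exact test,
    Mann-Whitney U, Kruskal-Wallis, Benjamini-Hochberg).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
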