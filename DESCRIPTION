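Package: moeinfer
Title: Mode-of-Evolution Inference for Cancers with a Residual Polyp of Origin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based inference of the mode of evolution (stepwise,
    parallel, neutral, or eruptive) of a cancer from paired somatic SNV
    allele-frequency distributions and copy-number aberration profiles of
    the cancer and its contiguous precursor polyp. Implements the
    shared/private SNV partition, kernel-density clustering and gap
    detection of allele-frequency distributions, purity estimation, an
    independent-origin flag based on driver allele frequencies, a
    five-rule majority-vote classifier, a per-chromosome Jaccard
    similarity metric for copy-number profiles with a recurrence test and
    UPGMA clustering, 96-channel trinucleotide mutation spectra, and a
    seeded clonal-evolution simulator producing archetypal cases for all
    four modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    BiocGenerics,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
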