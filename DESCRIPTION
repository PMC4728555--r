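Package: crispreff
Title: Sequence and Structure Features Associated with CRISPR/Cas9 Cleavage Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating sgRNA sequence features to binary
    on-target cleavage outcomes measured by enzyme-mismatch (Surveyor)
    assays. Provides position-wise nucleotide composition tests with minP
    permutation family-wise correction, GC-content window features, an RNA
    secondary-structure feature engine (partition-function base-pair
    probabilities, minimum free energy, windowed seed accessibility,
    guide-tracrRNA interaction), dummy-coded logistic regression with
    ROC/AUC evaluation under full-data and cross-validated settings,
    genomic-context and open-chromatin association tests, and a synthetic
    dataset generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
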