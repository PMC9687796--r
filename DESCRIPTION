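Package: siamscreen
Title: Hybrid-Enhanced Siamese Similarity Models for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Twin-network (Siamese) similarity scorers for ligand-based virtual
    screening over count fingerprints (ECFC-style nonnegative integer vectors).
    Implements the enhanced Siamese multilayer-perceptron (SMLP) and
    one-dimensional convolutional (SCNN1D) scorers with explicit
    similarity-measure layers (absolute difference, exponential Manhattan,
    continuous Jaccard/Tanimoto, Russel), hybrid models combining the two by
    decision fusion (maximum) or end-to-end feature fusion (sum or maximum),
    a synthetic screening-library generator with calibrated within-class
    similarity, the virtual-screening evaluation protocol (ranking,
    recall at top-n%, stratified k-fold cross-validation), and method-ranking
    statistics (Kendall's coefficient of concordance with tie correction,
    improvement percentage). Networks are trained natively with RMSprop and
    binary cross-entropy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
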