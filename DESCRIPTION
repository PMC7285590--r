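Package: aabench
Title: Benchmarking Amino-Acid Encoding Schemes for Sequence-Based
    Prediction Models
Version: 0.1.0
Authors@R: person("aabench", "developers", role = c("aut", "cre"),
    email = "devel@aabench.org")
Description: Tools for comparing classical amino-acid encodings (one-hot,
    frequency-normalized BLOSUM62, VHSE8 physicochemical descriptors) with
    machine-learnt and random frozen embeddings on two sequence-prediction
    tasks: peptide binding-affinity regression (an HLA class II style task)
    and protein-protein interaction classification from sequence pairs.
    Ships seeded synthetic data generators with motif-driven ground truth,
    the two data-preparation pipelines (tokenization, padding and trimming,
    IC50 normalization, homology filtering, negative balancing), compact
    C++ implementations of the three reference architectures (LSTM,
    CNN-LSTM and a Siamese convolutional network), benchmark grids over
    encoding x dimension x architecture x data fraction, and post-training
    embedding-space analysis (pairwise distances, hierarchical clustering,
    permutation tests of physicochemical group cohesion).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    Biostrings,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
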