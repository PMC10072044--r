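Package: efbdba
Title: Two-Stage Biomarker Selection with an Ensemble Filter and a
    Hybrid Binary Differential Evolution / African Vultures Wrapper
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects small, highly discriminative gene sets from labeled
    expression matrices (samples by features, two classes). Stage one is
    an ensemble filter: an improved fast correlation-based filter (FCBF)
    using Pearson-based class relevance, approximate Markov blanket
    redundancy removal and a Manhattan-distance complementarity rescue,
    intersected with the top features by Fisher score. Stage two searches
    the resulting candidate pool with a hybrid wrapper that fuses an
    improved binary differential evolution (sparsity-inducing mutation,
    adaptive crossover, segmented-adaptive fitness) with a binary African
    vultures optimization step during early generations, scoring subsets
    by stratified cross-validated accuracy of a linear support vector
    machine. Includes microarray-style synthetic data generation,
    preprocessing (duplicate averaging, Tukey outlier fences, KNN
    imputation, z-scoring) and per-feature biomarker statistics (Welch t,
    fold change).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
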