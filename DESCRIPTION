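Package: fragkernel
Title: Fragmentation-Tree Kernels and Multiple Kernel Learning for
    Metabolite Identification from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes fragmentation trees from MS/MS peak lists by mass
    decomposition and maximum colorful subtree extraction, evaluates a
    family of kernels on spectra (probability product kernel) and on
    fragmentation trees (loss, node, path and subtree kernels), combines
    them by multiple kernel learning (uniform, centered-alignment,
    alignment maximization, quadratic-combination and lp-norm weights),
    predicts binary molecular fingerprints with per-property kernel
    support vector machines, and ranks candidate structures from a
    compound database with a Poisson-binomial score.  Includes a seeded
    synthetic-data generator so the full pipeline can be exercised and
    validated without external spectral libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    kernlab,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
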