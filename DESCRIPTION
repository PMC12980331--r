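Package: seomlr
Title: One-Step Multi-View Subspace Clustering for Multi-Omics Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint one-step clustering of multi-omics data (e.g. mRNA, miRNA,
    DNA methylation over shared samples) by sparse self-representation learning
    with relaxed exclusivity across views, a consensus spectral embedding
    regularized by self-weighted base-clustering Laplacians, and spectral
    rotation for a discrete cluster indicator. Includes an ADMM solver for the
    per-view self-representation subproblem, built-in base-clustering providers
    (similarity network fusion, normalized-cuts spectral clustering, k-means),
    a synthetic multi-omics generator with planted subtypes and graded noise,
    clustering-agreement metrics (NMI, ARI), and a noise-robustness benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
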