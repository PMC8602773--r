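Package: hamiltime
Title: Consensus Hamiltonian-Path Pseudotime for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a pseudo developmental time for single-cell
    RNA-seq data by solving asymmetric Hamiltonian path problems over
    cell clusterings of increasing granularity and merging the per-path
    orderings into a consensus pseudotime. Cell-to-cell costs are
    directed Kullback-Leibler divergences between normalized expression
    profiles, so that de-differentiation is penalized. Downstream tools
    cover trajectory topology via a transition-matrix PCA embedding,
    gene dynamics ranking with distance correlation and a maximal
    information coefficient, Gaussian hidden Markov model segmentation
    of genes into on/off states, detection of quiescent (G0-like) cells
    from cell-cycle phase scores, 3D spiral coordinates coupling cycle
    and differentiation time, and ordering-evaluation metrics (change
    index, bubble sort index, Kendall correlation, POS). A synthetic
    trajectory generator supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
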