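Package: gbmd
Title: Canonical Graph-Based Molecular Descriptors and Similarity Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates a canonical, text-form graph descriptor of 2D molecular
    structure: atoms are ordered by the Morgan extended-connectivity algorithm
    with deterministic tie-breaking, a depth-first spanning tree is grown from
    the canonical root, and the molecule is rendered as a back-and-forth
    (Euler-tour) token string over a four-rule grammar covering atoms, bond
    orders, ring closures and disconnected parts. Companion tools score
    molecule pairs by Smith-Waterman local alignment on descriptor tokens or
    by the Tanimoto coefficient on precomputed binary fingerprints, and
    evaluate ligand-based virtual screening runs: ranked retrieval,
    recall at a top-percentage cutoff, per-class averaging over reference
    structures, table statistics (column means, best-in-row counts) and the
    tie-corrected Kendall coefficient of concordance. Seeded generators for
    random labeled molecular graphs and toy activity-class benchmarks make
    the whole pipeline testable without a proprietary compound database.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    ChemmineR,
    igraph,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
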