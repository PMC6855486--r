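Package: degpoly
Title: Polynomial-Based Complexity Measures for Directed Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity descriptors for directed networks built from degree
    polynomials. The out- and in-degree class counts of a simple digraph define
    two polynomials with non-negative integer coefficients; shifting either by
    an admissible constant alpha yields a polynomial with a unique positive
    zero delta in (0,1), which serves as an atomic complexity measure. The
    package constructs the polynomials, selects alpha, isolates the zero by
    bracketed root finding, derives the complexity indices I1-I5 and the edge
    density I7, scores the homogeneity of the zero set across alpha
    candidates, compares digraphs through zero-dominance criteria, and
    provides random generators for Erdos-Renyi and layered hierarchical
    digraph classes together with Spearman correlation analysis of the
    indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
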