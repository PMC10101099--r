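Package: microstab
Title: Stability, Permanence and Invasibility of Longitudinal Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ecological analysis of longitudinal microbiota
    time series: read-depth filtering, rarefaction and per-participant core
    microbiota extraction from OTU count tables; alpha diversity via Hill
    numbers; Bray-Curtis, Hellinger and UniFrac dissimilarities; local
    contributions to beta diversity (LCBD); phylogenetic community structure
    (NRI/NTI) under a richness null model; BVSTEP subset selection; inference
    of per-participant generalized Lotka-Volterra interaction matrices from
    weekly time series by sparse bagged stepwise regression (LIMITS-style);
    and assessment of local stability (Jacobian eigenvalues), global
    stability (permanence via an average-Lyapunov-function linear program)
    and invasibility of the inferred communities. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    boot,
    biomformat,
    data.table,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
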