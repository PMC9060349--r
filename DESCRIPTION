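Package: mranet
Title: Modular Response Analysis for Medium- to Large-Size Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene regulatory networks from systematic single-gene
    perturbation data using modular response analysis (MRA). Computes global
    response matrices from basal and perturbed steady-state expression,
    solves for local interaction strengths either by matrix inversion or by
    a parallelizable blockwise LU formulation that scales to networks of
    around 1,000 genes, and prunes the inferred network with a signed,
    CLR-style background normalization. Ships reimplementations of the
    mutual-information baselines CLR, MRNET and ARACNE for comparison, a
    steady-state network simulator producing ground-truth perturbation
    datasets, and an evaluation harness based on confusion matrices and the
    hypergeometric overlap test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
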