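Package: epiforce
Title: Mechanical Force Inference for Two-Dimensional Epithelial Cell Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relative interfacial tensions and intracellular pressures
    in a two-dimensional epithelial cell sheet from its observed vertex
    geometry, assuming quasi-static force balance at every cell junction
    (the "mechanical inverse"). Includes the force-balance linear system in
    full and reduced (constant-pressure, cortical-tension) parameterizations
    solved by pseudo-inverse or nonnegative least squares, an error-response
    (sensitivity) analysis of the inverse, a tension-driven vertex-model
    simulator on periodic (toroidal) domains used for in-silico validation,
    vertex-noise corruption, and downstream analyses: intercellular traction
    forces, a Young-Laplace cross-check against measured interface
    curvatures, and tension-anisotropy statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
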