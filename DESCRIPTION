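Package: rdlogistic
Title: Hopf Bifurcation Analysis of the Delayed Diffusive Logistic Model
    with Feedback Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the delayed reaction-diffusion logistic growth model
    with an indirect feedback control variable on a one-dimensional habitat
    with no-flux boundaries. Provides closed-form equilibria, dissipativeness
    and permanence predicates, per-spatial-mode characteristic analysis
    (Hopf frequencies, critical delays, mode cutoff, transversality,
    stability classification), center-manifold normal-form coefficients at a
    Hopf point (direction, orbital stability and period trend of the
    bifurcating cycle), and a deterministic fixed-step method-of-lines
    integrator for the full delayed PDE with oscillation diagnostics and
    delay sweeps. Analysis results are returned as tibbles; simulations plot
    with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
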