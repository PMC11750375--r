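Package: bifstokes
Title: Stokes Flow and Conductance of Two-Dimensional Channel Bifurcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves two-dimensional Stokes flow in channel bifurcations by
    rational approximation of the Goursat functions: lightning poles clustered
    at reentrant corners, AAA-derived poles for curved (Bezier) walls, and
    Laurent series with a single-valued log pair for an embedded circular
    particle, with a Vandermonde-with-Arnoldi orthogonalised polynomial basis
    and a weighted least-squares solve.  On top of the solver it computes the
    zero-dimensional network reduction of a bifurcation (conductance triple and
    tensor, Poiseuille and area-preserved references), flow-partition and
    separating-streamline analysis including reverse-flow thresholds, and small
    feedforward neural-network surrogates of conductance as a function of
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
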