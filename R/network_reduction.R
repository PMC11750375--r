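# Reduction of solved Stokes flows to the 0D network quantities: channel
# fluxes, the conductance triple (G0, G1, G2) and 2x2 tensor G mapping outlet
# pressures (P1, P2) to outlet fluxes (Q1, Q2) at grounded inlet pressure,
# plus the Poiseuille and area-preserved reference conductances.

# outward flux through each opening via stream-function differences,
# cross-checked by Gauss-Legendre quadrature of u . n
opening_fluxes <- function(solution, n_gauss = 64) {
  dom <- solution$system$domain
  out <- lapply(dom$openings, function(op) {
    ps <- fields_at(solution, c(op$lo, op$hi))$Psi
    # psi(hi) - psi(lo) is the flux with the right-normal of the lo->hi
    # traversal; orient to the opening's outward normal
    rn <- -1i * (op$hi - op$lo) / op$width
    sgn <- sign(Re(Conj(op$outward) * rn))
    q_psi <- sgn * (ps[2] - ps[1])
    gl <- pracma::gaussLegendre(n_gauss, 0, op$width)
    zg <- op$lo + (op$hi - op$lo) / op$width * gl$x
    f <- fields_at(solution, zg)
    un <- Re(Conj(op$outward) * complex(real = f$U, imaginary = f$V))
    q_quad <- sum(gl$w * un)
    c(q_psi = q_psi, q_quad = q_quad)
  })
  tibble::tibble(
    opening = vapply(dom$openings, `[[`, character(1), "name"),
    flux_out = vapply(out, `[[`, numeric(1), "q_psi"),
    flux_quadrature = vapply(out, `[[`, numeric(1), "q_quad"))
}

#' Channel fluxes of a solved bifurcation flow
#'
#' Computes the inlet flux `Q` (positive into the domain) and the two outlet
#' fluxes `Q1`, `Q2` (positive out) from stream-function differences across
#' the openings, cross-checked against Gauss-Legendre quadrature of the
#' normal velocity.  Errors if mass conservation `Q = Q1 + Q2` is violated
#' beyond tolerance.
#'
#' @param solution A [solve_stokes()] solution on a bifurcation domain.
#' @param tol Relative mass-conservation tolerance.
#' @return A tibble with columns `channel` (`"inlet"`, `"child1"`, `"child2"`),
#'   `flux` (signed as above) and `flux_quadrature` (the quadrature
#'   cross-check, same sign convention).
#' @export
channel_fluxes <- function(solution, tol = 1e-6) {
  stopifnot(solution$system$domain$n_openings == 3L)
  fl <- opening_fluxes(solution)
  q_in <- -fl$flux_out[1]          # inlet positive inward
  q1 <- fl$flux_out[2]
  q2 <- fl$flux_out[3]
  if (abs(q_in - q1 - q2) > tol * max(1, abs(q_in)))
    stop(sprintf("mass conservation violated: Q=%.8g, Q1=%.8g, Q2=%.8g",
                 q_in, q1, q2))
  tibble::tibble(channel = c("inlet", "child1", "child2"),
                 flux = c(q_in, q1, q2),
                 flux_quadrature = c(-fl$flux_quadrature[1],
                                     fl$flux_quadrature[2],
                                     fl$flux_quadrature[3]))
}

# eq-(2.8)-style tensor from a conductance triple
triple_to_tensor <- function(triple) {
  G0 <- triple[1]; G1 <- triple[2]; G2 <- triple[3]
  S <- G0 + G1 + G2
  matrix(c(-G1 * (G2 + G0) / S, G1 * G2 / S,
           G1 * G2 / S, -G2 * (G1 + G0) / S), 2, 2)
}

# triple from a measured 2x2 tensor (used as a robust fallback and check)
tensor_to_triple <- function(G) {
  s12 <- (G[1, 2] + G[2, 1]) / 2
  a1 <- -(G[1, 1] + s12)        # = G0*G1/S
  a2 <- -(G[2, 2] + s12)        # = G0*G2/S
  u0 <- a1 * a2 / s12; u1 <- a1 * s12 / a2; u2 <- a2 * s12 / a1
  r <- sqrt(c(u0, u1, u2))
  r * sum(r)
}

#' Conductance tensor and triple of a bifurcation
#'
#' Solves the Stokes problem twice, with outlet pressure vectors `(1, 0)` and
#' `(0, 1)` at grounded inlet pressure `P0 = 0`, measures the outlet fluxes,
#' and recovers the 2x2 conductance tensor plus the conductance triple
#' `(G0, G1, G2)` and the junction pressures in closed form.  Consistency of
#' the network-model reconstruction of the tensor from the triple is
#' asserted; failure signals an unconverged solver.
#'
#' @param domain A `bif_domain` with three openings.
#' @param options A [solver_options()].
#' @param system Optionally a pre-factorised [stokes_system()].
#' @param keep_solutions Keep the two base solutions (needed by the
#'   flow-partition analysis) in the returned object.
#' @return An object of class `conductance_set`: list with `triple` (named
#'   `G0`, `G1`, `G2`), `tensor`, `junction_pressures`, `fluxes` (per solve),
#'   `residuals`, and optionally `base_solutions` and `system`.
#' @export
conductance_tensor <- function(domain, options = solver_options(),
                               system = NULL, keep_solutions = FALSE) {
  sys <- if (is.null(system)) stokes_system(domain, options) else system
  sol1 <- solve_stokes(domain, c(0, 1, 0), system = sys)
  sol2 <- solve_stokes(domain, c(0, 0, 1), system = sys)
  f1 <- channel_fluxes(sol1)
  f2 <- channel_fluxes(sol2)
  qin1 <- f1$flux[1]; q11 <- f1$flux[2]; q21 <- f1$flux[3]
  qin2 <- f2$flux[1]; q12 <- f2$flux[2]; q22 <- f2$flux[3]
  tensor <- matrix(c(q11, q21, q12, q22), 2, 2)

  r <- qin2 / qin1
  den <- q12 - r * q11
  if (abs(den) > 1e-10 * max(abs(q12), abs(q11), 1e-300)) {
    Pc1 <- q12 / den
    Pc2 <- r * Pc1
    triple <- c(G0 = -qin1 / Pc1, G1 = q12 / Pc2, G2 = q21 / Pc1)
  } else {
    triple <- tensor_to_triple(tensor)
    names(triple) <- c("G0", "G1", "G2")
    S <- sum(triple)
    Pc1 <- triple["G1"] / S; Pc2 <- triple["G2"] / S
  }
  recon <- triple_to_tensor(triple)
  rel <- max(abs(recon - tensor)) / max(abs(tensor))
  if (!is.finite(rel) || rel > 1e-4)
    stop(sprintf("inconsistent conductance reconstruction (rel %.3g): solver unconverged?", rel))
  structure(list(triple = triple, tensor = tensor,
                 junction_pressures = c(Pc1 = unname(Pc1), Pc2 = unname(Pc2)),
                 fluxes = list(solve1 = f1, solve2 = f2),
                 reconstruction_error = rel,
                 n_unknowns = sys$n_unknowns,
                 residuals = c(sol1$residual_report$overall,
                               sol2$residual_report$overall),
                 base_solutions = if (keep_solutions) list(sol1, sol2),
                 system = if (keep_solutions) sys,
                 spec = domain$spec),
            class = "conductance_set")
}

#' @export
print.conductance_set <- function(x, ...) {
  cat(sprintf("<conductance_set> G0=%.4f G1=%.4f G2=%.4f (recon err %.1e)\n",
              x$triple["G0"], x$triple["G1"], x$triple["G2"],
              x$reconstruction_error))
  invisible(x)
}

#' Poiseuille reference conductances
#'
#' The idealised conductances of a bifurcation whose junction is collapsed to
#' a node and whose channels carry fully developed plane Poiseuille flow:
#' `G~0 = 1/(12 L)`, `G~i = Di^3/(12 L)`, with the corresponding network
#' tensor.
#'
#' @param spec A [bif_spec()], or `NULL` if `D1`, `D2`, `L` are given.
#' @param D1,D2,L Geometry parameters (overridden by `spec`).
#' @return List with `triple` (named) and `tensor`.
#' @export
poiseuille_reference <- function(spec = NULL, D1 = NULL, D2 = NULL, L = 2) {
  if (!is.null(spec)) { D1 <- spec$D1; D2 <- spec$D2; L <- spec$L }
  triple <- c(G0 = 1 / (12 * L), G1 = D1^3 / (12 * L), G2 = D2^3 / (12 * L))
  list(triple = triple, tensor = triple_to_tensor(triple))
}

#' Area-preserved reference conductances
#'
#' Replaces each channel by a straight channel of length `L` whose width is
#' scaled to preserve the region area (`D^_i = A_i / L`), and evaluates the
#' Poiseuille conductance of the scaled widths.  Isolates the effect of area
#' change from the effect of non-unidirectional flow.
#'
#' @param domain A `bif_domain`.
#' @return List with `triple` (named `G0`, `G1`, `G2`), `effective_widths`
#'   and `areas`.
#' @export
area_preserved_reference <- function(domain) {
  L <- domain$spec$L
  ar <- region_areas(domain)
  Dh <- ar$area / L
  triple <- Dh^3 / (12 * L)
  names(triple) <- c("G0", "G1", "G2")
  list(triple = triple, tensor = triple_to_tensor(triple),
       effective_widths = stats::setNames(Dh, c("D0", "D1", "D2")),
       areas = stats::setNames(ar$area, ar$region))
}

#' Relative differences between computed and reference conductances
#'
#' @param computed A [conductance_tensor()] result (or a numeric triple).
#' @param reference A reference from [poiseuille_reference()] or
#'   [area_preserved_reference()] (or a numeric triple).
#' @return A tibble with columns `channel`, `G`, `G_ref` and `rel_pct`
#'   (`100 * (G - G_ref) / G_ref`), computed from unrounded values.
#' @export
relative_differences <- function(computed, reference) {
  g <- if (inherits(computed, "conductance_set")) computed$triple else computed
  gr <- if (is.list(reference)) reference$triple else reference
  tibble::tibble(channel = c("parent", "child1", "child2"),
                 G = unname(g), G_ref = unname(gr),
                 rel_pct = 100 * (unname(g) - unname(gr)) / unname(gr))
}

#' Conductance sweep over a grid of geometries
#'
#' Runs [conductance_tensor()] for every row of a parameter grid and returns
#' one tidy row per geometry, including Poiseuille references and relative
#' differences.  Invalid geometries (per [validate_spec()]) are returned with
#' `NA` conductances and the failure reason.
#'
#' @param grid A data frame with columns among `D1`, `D2`, `alpha`, `beta`,
#'   `L`, `X0`, `Y0`, `R` (missing columns get defaults; particle columns all
#'   `NA` means no particle).
#' @param options A [solver_options()].
#' @param wall_kind `"straight"` or `"bezier"`.
#' @return A tibble, one row per grid row.
#' @export
conductance_sweep <- function(grid, options = solver_options(),
                              wall_kind = "straight") {
  grid <- tibble::as_tibble(grid)
  if (!"L" %in% names(grid)) grid$L <- 2
  rows <- purrr::pmap(grid, function(D1, D2, alpha, beta, L, ...) {
    dots <- list(...)
    particle <- NULL
    if (!is.null(dots$R) && is.finite(dots$R))
      particle <- list(X0 = dots$X0, Y0 = dots$Y0, R = dots$R)
    spec <- bif_spec(D1, D2, alpha, beta, L, wall_kind = wall_kind,
                     particle = particle)
    vr <- validate_spec(spec)
    base <- tibble::tibble(D1 = D1, D2 = D2, alpha = alpha, beta = beta, L = L,
                           X0 = particle$X0 %||% NA_real_,
                           Y0 = particle$Y0 %||% NA_real_,
                           R = particle$R %||% NA_real_)
    if (!vr$ok)
      return(dplyr::mutate(base, valid = FALSE,
                           reason = paste(vr$violations, collapse = "; "),
                           G0 = NA_real_, G1 = NA_real_, G2 = NA_real_,
                           G0_pois = NA_real_, G1_pois = NA_real_,
                           G2_pois = NA_real_, relpct_G0 = NA_real_,
                           relpct_G1 = NA_real_, relpct_G2 = NA_real_))
    cs <- conductance_tensor(build_bifurcation(spec), options)
    pr <- poiseuille_reference(spec)
    rd <- relative_differences(cs, pr)
    dplyr::mutate(base, valid = TRUE, reason = "",
                  G0 = cs$triple[["G0"]], G1 = cs$triple[["G1"]],
                  G2 = cs$triple[["G2"]],
                  G0_pois = pr$triple[["G0"]], G1_pois = pr$triple[["G1"]],
                  G2_pois = pr$triple[["G2"]],
                  relpct_G0 = rd$rel_pct[1], relpct_G1 = rd$rel_pct[2],
                  relpct_G2 = rd$rel_pct[3])
  })
  dplyr::bind_rows(rows)
}

#' Murray's law predicate in two dimensions
#'
#' In 2D the optimal-width relation is `D1^2 + D2^2 = D^2` (with unit parent
#' width, `D1^2 + D2^2 = 1`); used only to annotate parameter-space figures.
#'
#' @param D1,D2 Child widths.
#' @param tol Tolerance on `D1^2 + D2^2 - 1`.
#' @return Logical vector.
#' @export
murray_2d <- function(D1, D2, tol = 1e-8) {
  abs(D1^2 + D2^2 - 1) <= tol
}
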