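# Flow-partition and streamline-topology analysis: superposed solutions under
# a unit-inlet-flux constraint, reverse-flow thresholds, and centre /
# separating streamlines.

# build a goursat_solution from a coefficient vector (superposition path)
solution_from_x <- function(sys, x, opening_pressures) {
  structure(list(coeff = coeff_split(sys$basis, x), x = x,
                 system = sys, opening_pressures = opening_pressures,
                 residual_report = list(overall = NA_real_)),
            class = "goursat_solution")
}

#' Flow at prescribed outlet pressure difference and unit inlet flux
#'
#' Finds the outlet pressures `(P1, P2)` with `P1 - P2 = delta_p` and total
#' outlet flux 1 (from the conductance tensor), and superposes the two cached
#' base solutions; no new Stokes solve is performed.
#'
#' @param conductances A [conductance_tensor()] result with
#'   `keep_solutions = TRUE`.
#' @param delta_p The pressure difference `P1 - P2`.
#' @return An object of class `constrained_flow`: list with `delta_p`,
#'   `pressures`, `partition` (named `Q1`, `Q2`, measured from the superposed
#'   field) and `solution`.
#' @export
constrained_flow <- function(conductances, delta_p) {
  stopifnot(inherits(conductances, "conductance_set"),
            !is.null(conductances$base_solutions))
  G <- conductances$tensor
  cs <- colSums(G)
  # [1, -1; cs1, cs2] (P1,P2)' = (delta_p, 1)'
  det <- cs[2] + cs[1]
  if (abs(det) < 1e-14) stop("degenerate conductance tensor")
  P1 <- (delta_p * cs[2] + 1) / det
  P2 <- P1 - delta_p
  sys <- conductances$system
  x <- P1 * conductances$base_solutions[[1]]$x +
    P2 * conductances$base_solutions[[2]]$x
  sol <- solution_from_x(sys, x, c(0, P1, P2))
  fl <- channel_fluxes(sol)
  structure(list(delta_p = delta_p, pressures = c(P1 = P1, P2 = P2),
                 partition = c(Q1 = fl$flux[2], Q2 = fl$flux[3]),
                 solution = sol, conductances = conductances),
            class = "constrained_flow")
}

#' @export
print.constrained_flow <- function(x, ...) {
  cat(sprintf("<constrained_flow> dP=%.4g P=(%.4g, %.4g) Q1=%.4g Q2=%.4g\n",
              x$delta_p, x$pressures[1], x$pressures[2],
              x$partition[1], x$partition[2]))
  invisible(x)
}

#' Reverse-flow threshold of a bifurcation
#'
#' The outlet pressure difference `P1 - P2` at which the flux in child
#' channel 1 vanishes under unit inlet flux, computed in closed form from the
#' conductance tensor (`Q1 = 0` forces `P1/P2 = -G12/G11`) and verified by a
#' sign-change bracket on `Q1(delta_p)`.  Also returns the prediction of the
#' Poiseuille network tensor for the same geometry.
#'
#' @param conductances A [conductance_tensor()] result (base solutions not
#'   required), or a `bif_domain` (the tensor is then computed).
#' @param options Solver options, used only if a domain is given.
#' @return List with `stokes` (threshold from the Stokes tensor),
#'   `poiseuille` (threshold from the eq-style idealised tensor) and
#'   `bracket_check` (|closed form - bracketed root|).
#' @export
reversal_threshold <- function(conductances, options = solver_options()) {
  if (inherits(conductances, "bif_domain"))
    conductances <- conductance_tensor(conductances, options)
  thr <- function(G) {
    cs <- colSums(G)
    # P1 = -G12/G11 * P2 ; cs1 P1 + cs2 P2 = 1
    ratio <- -G[1, 2] / G[1, 1]
    P2 <- 1 / (cs[1] * ratio + cs[2])
    P1 <- ratio * P2
    unname(P1 - P2)
  }
  dstar <- thr(conductances$tensor)
  # bracket verification: Q1 is affine in delta_p
  q1_of <- function(dp) {
    G <- conductances$tensor; cs <- colSums(G)
    P1 <- (dp * cs[2] + 1) / (cs[1] + cs[2]); P2 <- P1 - dp
    G[1, 1] * P1 + G[1, 2] * P2
  }
  lo <- dstar - 1; hi <- dstar + 1
  if (sign(q1_of(lo)) == sign(q1_of(hi)))
    stop(sprintf("no sign change of Q1 in [%g, %g]", lo, hi))
  root <- stats::uniroot(q1_of, c(lo, hi), tol = 1e-12)$root
  pois <- poiseuille_reference(conductances$spec)
  list(stokes = dstar, poiseuille = thr(pois$tensor),
       bracket_check = abs(root - dstar))
}

## ---- streamline tracing ----------------------------------------------------

# velocity at a single complex point (helper for the integrator)
velocity_at <- function(solution, z) {
  f <- fields_at(solution, z)
  complex(real = f$U, imaginary = f$V)
}

#' Trace a streamline through the flow
#'
#' Integrates the normalised velocity field with an adaptive embedded
#' Runge-Kutta (Fehlberg 4(5)) scheme from a starting point until the path
#' leaves the domain through an opening, approaches a wall, or stagnates.
#'
#' @param solution A solved flow (from [solve_stokes()] or a
#'   [constrained_flow()] `$solution`).
#' @param start Complex starting point strictly inside the domain.
#' @param step_tol Local error tolerance per unit-arclength step.
#' @param max_length Maximum path length before giving up.
#' @param direction `+1` to integrate with the flow, `-1` against it.
#' @return An object of class `streamline`: list with `vertices` (complex),
#'   `psi_level`, `psi_drift` (max |psi - level| along the path) and
#'   `terminus` (`"opening0"`, `"opening1"`, `"opening2"`, `"wall"`,
#'   `"stagnation"`, `"maxlen"`).
#' @export
trace_streamline <- function(solution, start, step_tol = 1e-9,
                             max_length = NULL, direction = 1) {
  dom <- solution$system$domain
  if (!point_in_domain(dom, start))
    stop("streamline start point is outside the fluid domain")
  if (is.null(max_length))
    max_length <- 10 * max(Mod(dom$dense_polygon))
  psi0 <- fields_at(solution, start)$Psi

  # Fehlberg 4(5) coefficients
  a <- list(c(1/4),
            c(3/32, 9/32),
            c(1932/2197, -7200/2197, 7296/2197),
            c(439/216, -8, 3680/513, -845/4104),
            c(-8/27, 2, -3544/2565, 1859/4104, -11/40))
  b5 <- c(16/135, 0, 6656/12825, 28561/56430, -9/50, 2/55)
  b4 <- c(25/216, 0, 1408/2565, 2197/4104, -1/5, 0)

  rhs <- function(z) {
    u <- velocity_at(solution, z)
    s <- Mod(u)
    if (!is.finite(s) || s < 1e-300) return(list(v = 0 + 0i, speed = 0))
    list(v = direction * u / s, speed = s)
  }

  z <- start
  verts <- start
  h <- 0.02
  travelled <- 0
  slow_steps <- 0
  stuck <- 0
  terminus <- "maxlen"
  for (it in seq_len(30000)) {
    if (travelled > max_length) break
    k <- vector("list", 6)
    r1 <- rhs(z)
    if (r1$speed < 1e-10) {
      slow_steps <- slow_steps + 1
      if (slow_steps > 10) { terminus <- "stagnation"; break }
    } else slow_steps <- 0
    k[[1]] <- r1$v
    ok <- TRUE
    for (i in 2:6) {
      zi <- z + h * sum(a[[i - 1]] * unlist(k[1:(i - 1)]))
      if (!point_in_domain(dom, zi, tol = 1e-9)) { ok <- FALSE; break }
      k[[i]] <- rhs(zi)$v
    }
    if (!ok) {
      if (h > 1e-6) { h <- h / 2; next }
      terminus <- classify_exit(dom, z)
      break
    }
    ks <- unlist(k)
    z5 <- z + h * sum(b5 * ks)
    err <- Mod(h * sum((b5 - b4) * ks))
    if (err > step_tol * max(1, h) && h > 1e-6) { h <- h / 2; next }
    if (!point_in_domain(dom, z5, tol = 1e-9)) {
      if (h > 1e-6) { h <- h / 2; next }
      terminus <- classify_exit(dom, z5)
      z <- z5; verts <- c(verts, z5)
      break
    }
    z <- z5
    verts <- c(verts, z)
    travelled <- travelled + h
    if (err < step_tol / 32) h <- min(h * 2, 0.1)
    # a path crawling along a wall (or pinned at a corner) has terminated
    if (h <= 2e-6) stuck <- stuck + 1 else stuck <- 0
    if (stuck > 50) {
      terminus <- if (r1$speed < 1e-4) "stagnation" else classify_exit(dom, z)
      break
    }
    # stop on opening proximity
    ex <- classify_exit(dom, z, near = 5e-4)
    if (ex != "wall") { terminus <- ex; break }
  }
  drift_idx <- if (length(verts) > 512)
    unique(round(seq(1, length(verts), length.out = 512))) else seq_along(verts)
  psis <- fields_at(solution, verts[drift_idx])$Psi
  structure(list(vertices = verts, psi_level = psi0,
                 psi_drift = max(abs(psis - psi0)), terminus = terminus),
            class = "streamline")
}

# classify which boundary element a point is about to leave through
classify_exit <- function(dom, z, near = 2e-3) {
  dmin <- Inf; lab <- "wall"
  for (op in dom$openings) {
    ab <- op$hi - op$lo
    t <- min(1, max(0, Re(Conj(ab) * (z - op$lo)) / Mod(ab)^2))
    d <- Mod(z - (op$lo + t * ab))
    if (d < dmin) { dmin <- d; lab <- op$name }
  }
  if (dmin < near) lab else "wall"
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("<streamline> %d vertices, psi=%.6g (drift %.1e), terminus=%s\n",
              length(x$vertices), x$psi_level, x$psi_drift, x$terminus))
  invisible(x)
}

#' Separating streamline of a constrained bifurcation flow
#'
#' For forward flow (`0 < Q1 < 1`) the separatrix is the level set
#' `psi = psi(inlet bottom corner) + Q2`: its inlet ordinate `Y*` satisfies
#' `integral of U from -1/2 to Y* = Q2` (flux-coordinate anchoring).  For
#' reversed child-1 flow the returned streamline separates parent-channel
#' fluid from the channel-1 fluid entering channel 2: the level is that of
#' the upper parent wall, found where it crosses opening 2 and traced
#' upstream.
#'
#' @param flow A [constrained_flow()].
#' @param step_tol Streamline integrator tolerance.
#' @return List with `streamline` (a `streamline` object) and
#'   `inlet_ordinate` (`Y*` on the inlet for forward flow, `NA` when
#'   reversed).
#' @export
separatrix <- function(flow, step_tol = 1e-9) {
  stopifnot(inherits(flow, "constrained_flow"))
  sol <- flow$solution
  dom <- sol$system$domain
  q1 <- flow$partition["Q1"]
  if (abs(q1) < 1e-8)
    stop("flow is at the reversal threshold (Q1 = 0); separatrix undefined")
  inlet <- dom$openings[[1]]
  psi_bottom <- fields_at(sol, inlet$lo)$Psi
  if (q1 > 0) {
    level <- psi_bottom + flow$partition["Q2"]
    eps <- 1e-6
    g <- function(y) fields_at(sol, complex(real = Re(inlet$centre),
                                            imaginary = y))$Psi - level
    ystar <- stats::uniroot(g, c(Im(inlet$lo) + eps, Im(inlet$hi) - eps),
                            tol = 1e-12)$root
    start <- complex(real = Re(inlet$centre) + 1e-3, imaginary = ystar)
    sl <- trace_streamline(sol, start, step_tol = step_tol)
    list(streamline = sl, inlet_ordinate = ystar)
  } else {
    level <- psi_bottom + 1   # upper parent wall carries the full inlet flux
    op2 <- dom$openings[[3]]
    g <- function(s) fields_at(sol, op2$lo + (op2$hi - op2$lo) * s)$Psi -
      (psi_bottom + (level - psi_bottom))
    eps <- 1e-6
    sstar <- stats::uniroot(function(s) {
      fields_at(sol, op2$lo + (op2$hi - op2$lo) * s)$Psi - level
    }, c(eps, 1 - eps), tol = 1e-12)$root
    start <- op2$lo + (op2$hi - op2$lo) * sstar - 1e-3 * op2$outward
    sl <- trace_streamline(sol, start, step_tol = step_tol, direction = -1)
    list(streamline = sl, inlet_ordinate = NA_real_)
  }
}
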