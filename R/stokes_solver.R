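# Assembly and solution of the boundary least-squares problem for the Goursat
# functions, and field evaluation.
#
# The stream function is psi = Im[conj(zeta) f(zeta) + g(zeta)] with analytic
# Goursat functions f, g; velocity U - iV = -conj(f) + conj(zeta) f' + g',
# pressure and vorticity P - i Omega = 4 f'.  Both f and g are expanded in the
# same rational basis; each complex coefficient contributes two real unknowns,
# so the least-squares matrix is real.

# Complex response matrices at given points: one column per real unknown, in
# the layout [f-Re | f-Im | g-Re | g-Im | log-Re | log-Im].
#   E   : U - iV response
#   P   : P - i Omega response
#   Psi : stream function response, encoded so that psi = Im(Psi %*% x)
goursat_columns <- function(basis, zeta, what = c("E", "P"), second = FALSE) {
  ev <- evaluate_basis(basis, zeta, second = second)
  V <- ev$V; D <- ev$D
  zb <- Conj(zeta)
  out <- list()
  haslog <- !is.null(basis$log_centre)
  if (haslog) {
    w <- zeta - basis$log_centre
    lw <- log(Mod(w))
  }
  if ("E" %in% what) {
    Efx <- -Conj(V) + zb * D
    Efy <- 1i * (Conj(V) + zb * D)
    E <- cbind(Efx, Efy, D, 1i * D)
    if (haslog) {
      # stokeslet pair (complex strength a: two real columns) and rotlet
      # (real strength): the three single-valued log degrees of freedom of a
      # hole, carrying the net force and torque on the particle
      elx <- -2 * lw + Conj(w) / w
      ely <- 1i * (2 * lw + Conj(w) / w)
      erot <- 1i / w
      E <- cbind(E, elx, ely, erot)
    }
    out$E <- E
  }
  if ("P" %in% what) {
    Z <- matrix(0 + 0i, length(zeta), ncol(V))
    P <- cbind(4 * D, 4i * D, Z, Z)
    if (haslog) P <- cbind(P, 4 / w, 4i / w, 0 + 0i)
    out$P <- P
  }
  if ("Psi" %in% what) {
    Psi <- cbind(zb * V, 1i * zb * V, V, 1i * V)
    if (haslog) {
      # real-valued log-pair stream function, stored as i * psi
      psix <- (1 - 2 * lw) * Im(w)
      psiy <- (2 * lw - 1) * Re(w)
      Psi <- cbind(Psi, 1i * psix, 1i * psiy, 1i * lw)
    }
    out$Psi <- Psi
  }
  if (second) {
    # d/ds of E along a direction tau (needed for the normal-stress option):
    # dE/ds = tau * (conj(zeta) phi'') + conj(tau) * (phi' - conj(phi')) ...
    # returned as the two Wirtinger derivative blocks.
    D2 <- ev$D2
    dEdz <- cbind(zb * D2, 1i * zb * D2, D2, 1i * D2)
    dEdzb <- cbind(D - Conj(D), 1i * (D + Conj(D)),
                   matrix(0 + 0i, length(zeta), 2 * ncol(V)))
    if (haslog)
      stop("normal-stress rows are not implemented for domains with a hole")
    out$dEdz <- dEdz
    out$dEdzb <- dEdzb
  }
  out
}

n_real_unknowns <- function(basis) {
  4L * basis$n_columns + (if (is.null(basis$log_centre)) 0L else 3L)
}

#' Assemble the boundary least-squares system
#'
#' Two real rows per wall or particle sample (zero velocity), and two per
#' opening sample (prescribed pressure via `Re(4 f') = P_k`, zero transverse
#' velocity).  Each row is scaled by the square root of the sample's
#' arc-length weight.  Unknowns are the stacked real and imaginary parts of
#' the coefficients of f and g (plus the log-pair strength for a hole).
#'
#' @param domain A `bif_domain`.
#' @param samples Boundary samples from [sample_boundary()].
#' @param basis A [build_basis()] basis.
#' @param opening_pressures Numeric vector, one pressure per opening.
#' @param options A [solver_options()].
#' @return List with the real matrix `A`, right-hand side `b`, and row
#'   bookkeeping (`row_tag`).
#' @export
assemble_system <- function(domain, samples, basis, opening_pressures,
                            options = solver_options()) {
  o <- resolve_options(domain, options)
  nunk <- n_real_unknowns(basis)
  if (nrow(samples) < nunk)
    stop(sprintf("under-resolved: %d samples for %d real unknowns",
                 nrow(samples), nunk))
  cols <- goursat_columns(basis, samples$zeta, what = c("E", "P"),
                          second = o$normal_stress)
  sw <- sqrt(samples$weight)
  wall <- samples$bc_tag %in% c("wall", "particle")

  blocks <- list(); rhs <- list(); tags <- list()
  if (any(wall)) {
    Ew <- cols$E[wall, , drop = FALSE] * sw[wall]
    blocks <- c(blocks, list(Re(Ew), -Im(Ew)))
    rhs <- c(rhs, list(numeric(sum(wall)), numeric(sum(wall))))
    tags <- c(tags, list(paste0(samples$bc_tag[wall], ":U"),
                         paste0(samples$bc_tag[wall], ":V")))
  }
  for (op in domain$openings) {
    idx <- samples$bc_tag == op$name
    if (!any(idx)) next
    pk <- opening_pressures[op$index + 1L]
    swk <- sw[idx]
    if (!o$normal_stress) {
      Prow <- Re(cols$P[idx, , drop = FALSE]) * swk
    } else {
      tau <- (op$hi - op$lo) / op$width
      dE <- tau * cols$dEdz[idx, , drop = FALSE] +
        Conj(tau) * cols$dEdzb[idx, , drop = FALSE]
      # (sigma n) . n = -P - 2 d(u_t)/ds ; impose = -P_k
      Prow <- (Re(cols$P[idx, , drop = FALSE]) +
                 2 * Re(tau * dE)) * swk
    }
    Trow <- Im(op$axis * cols$E[idx, , drop = FALSE]) * swk
    blocks <- c(blocks, list(Prow, Trow))
    rhs <- c(rhs, list(pk * swk, numeric(sum(idx))))
    tags <- c(tags, list(rep(paste0(op$name, ":P"), sum(idx)),
                         rep(paste0(op$name, ":T"), sum(idx))))
  }
  A <- do.call(rbind, blocks)
  list(A = A, b = unlist(rhs), row_tag = unlist(tags))
}

#' Pre-factorised Stokes system for a domain
#'
#' Builds boundary samples, the rational basis and the least-squares matrix
#' once, and factorises it (SVD) so that multiple pressure vectors can be
#' solved against the same geometry at marginal cost.
#'
#' @param domain A `bif_domain`.
#' @param options A [solver_options()].
#' @return An object of class `stokes_system`.
#' @export
stokes_system <- function(domain, options = solver_options()) {
  o <- resolve_options(domain, options)
  samples <- sample_boundary(domain, o)
  basis <- build_basis(domain, samples, o)
  sys0 <- assemble_system(domain, samples, basis, rep(0, domain$n_openings), o)
  sv <- svd(sys0$A)
  keep <- sv$d > o$svd_tol * sv$d[1]
  structure(list(domain = domain, options = o, samples = samples,
                 basis = basis, row_tag = sys0$row_tag, A = sys0$A,
                 svd = list(u = sv$u[, keep, drop = FALSE],
                            d = sv$d[keep],
                            v = sv$v[, keep, drop = FALSE]),
                 rank = sum(keep), n_unknowns = n_real_unknowns(basis)),
            class = "stokes_system")
}

# right-hand side for a pressure vector (zero rows except opening P rows)
system_rhs <- function(sys, opening_pressures) {
  b <- numeric(length(sys$row_tag))
  sw <- sqrt(sys$samples$weight)
  for (op in sys$domain$openings) {
    rows <- sys$row_tag == paste0(op$name, ":P")
    idx <- sys$samples$bc_tag == op$name
    b[rows] <- opening_pressures[op$index + 1L] * sw[idx]
  }
  b
}

solve_coefficients <- function(sys, opening_pressures) {
  b <- system_rhs(sys, opening_pressures)
  x <- sys$svd$v %*% (crossprod(sys$svd$u, b) / sys$svd$d)
  drop(x)
}

coeff_split <- function(basis, x) {
  K <- basis$n_columns
  cf <- complex(real = x[1:K], imaginary = x[K + (1:K)])
  cg <- complex(real = x[2 * K + (1:K)], imaginary = x[3 * K + (1:K)])
  clog <- if (!is.null(basis$log_centre))
    list(stokeslet = complex(real = x[4 * K + 1], imaginary = x[4 * K + 2]),
         rotlet = x[4 * K + 3]) else NULL
  list(cf = cf, cg = cg, clog = clog)
}

#' Solve a Stokes flow problem on a domain
#'
#' One-shot driver: samples the boundary, builds the basis, assembles and
#' solves the weighted least-squares problem by truncated SVD, and attaches a
#' boundary residual report.
#'
#' @param domain A `bif_domain`.
#' @param opening_pressures Numeric pressures, one per opening (the inlet is
#'   `opening0`; the convention `P0 = 0` is the caller's responsibility).
#' @param options A [solver_options()].
#' @param system Optionally, a pre-factorised [stokes_system()] to reuse.
#' @return An object of class `goursat_solution` with elements `coeff` (the
#'   complex coefficient vectors of f and g and, for a hole, the log-pair
#'   strength), `system`, `opening_pressures` and `residual_report`.
#' @export
solve_stokes <- function(domain, opening_pressures,
                         options = solver_options(), system = NULL) {
  sys <- if (is.null(system)) stokes_system(domain, options) else system
  stopifnot(length(opening_pressures) == sys$domain$n_openings)
  x <- solve_coefficients(sys, opening_pressures)
  sol <- structure(list(coeff = coeff_split(sys$basis, x), x = x,
                        system = sys, opening_pressures = opening_pressures,
                        residual_report = NULL),
                   class = "goursat_solution")
  sol$residual_report <- if (identical(sys$options$residual_check, "solve_grid"))
    collocation_residual(sol) else boundary_residual(sol, refine = 2)
  if (sol$residual_report$overall > sys$options$residual_warn)
    sol$residual_report$warning <- sprintf(
      "boundary residual %.3g above %.3g",
      sol$residual_report$overall, sys$options$residual_warn)
  sol
}

#' @export
print.goursat_solution <- function(x, ...) {
  cat(sprintf("<goursat_solution> %d real unknowns, rank %d, residual %.3g\n",
              x$system$n_unknowns, x$system$rank,
              x$residual_report$overall))
  invisible(x)
}

# raw field evaluation (no inside-domain masking); returns list of vectors
fields_at <- function(solution, zeta) {
  cols <- goursat_columns(solution$system$basis, zeta,
                          what = c("E", "P", "Psi"))
  x <- solution$x
  E <- drop(cols$E %*% x)
  Pq <- drop(cols$P %*% x)
  psi <- Im(drop(cols$Psi %*% x))
  list(U = Re(E), V = -Im(E), P = Re(Pq), Omega = -Im(Pq), Psi = psi)
}

#' Evaluate flow fields at query points
#'
#' @param solution A [solve_stokes()] solution.
#' @param points Complex vector of query points, or a data frame with columns
#'   `X` and `Y`.
#' @return A tibble with columns `X`, `Y`, `U`, `V`, `P`, `Omega`, `Psi`;
#'   points outside the closed fluid domain get `NA` fields.
#' @export
evaluate_fields <- function(solution, points) {
  if (is.data.frame(points))
    points <- complex(real = points$X, imaginary = points$Y)
  inside <- point_in_domain(solution$system$domain, points, tol = 1e-12)
  out <- tibble::tibble(X = Re(points), Y = Im(points),
                        U = NA_real_, V = NA_real_, P = NA_real_,
                        Omega = NA_real_, Psi = NA_real_)
  if (any(inside)) {
    f <- fields_at(solution, points[inside])
    out$U[inside] <- f$U; out$V[inside] <- f$V; out$P[inside] <- f$P
    out$Omega[inside] <- f$Omega; out$Psi[inside] <- f$Psi
  }
  out
}

# quick residual at the collocation points themselves (unweighted), from the
# stored least-squares matrix; used in bulk sweeps where re-sampling the
# boundary per solve would dominate the cost
collocation_residual <- function(solution) {
  sys <- solution$system
  b <- system_rhs(sys, solution$opening_pressures)
  r <- abs(drop(sys$A %*% solution$x) - b)
  sw <- sqrt(sys$samples$weight)
  # undo the sqrt-weight row scaling; rows were built block-wise from sample
  # subsets in sample order, so reconstruct per-row weights from the tags
  wrow <- numeric(length(b))
  tags <- rle(sys$row_tag)
  idx <- 1L
  for (k in seq_along(tags$lengths)) {
    n <- tags$lengths[k]
    part <- strsplit(tags$values[k], ":")[[1]]
    sel <- sys$samples$bc_tag == part[1]
    wrow[idx:(idx + n - 1)] <- sw[sel]
    idx <- idx + n
  }
  per <- tapply(r / wrow, sys$row_tag, max)
  list(per_tag = per, overall = max(per), near_corner = NA_real_,
       grid = "collocation")
}

#' Boundary residual of a solved problem
#'
#' Re-samples every boundary arc at `refine` times the solve density and
#' reports the maximum violation of the imposed boundary conditions per
#' boundary-condition tag.  The check grid is uniform in arc length (the
#' convention under which boundary-accuracy claims for corner-singular
#' domains are stated); a separate `near_corner` figure reports the maximum
#' error on a corner-clustered grid reaching down to the innermost pole
#' distance, where the velocity itself vanishes like a fractional power of
#' the corner distance and absolute errors are intrinsically larger.
#'
#' @param solution A [solve_stokes()] solution.
#' @param refine Refinement factor for the check sampling.
#' @return List with `per_tag` (named numeric vector of max absolute errors),
#'   `overall` (max over tags, uniform grid) and `near_corner`.
#' @export
boundary_residual <- function(solution, refine = 4) {
  sys <- solution$system
  dom <- sys$domain
  per <- c()

  uniform_grid <- function(n_per_unit) {
    zs <- complex(0)
    for (ar in dom$arcs) {
      if (ar$kind == "polyline") {
        pts <- ar$pts
        for (i in seq_len(length(pts) - 1)) {
          len <- Mod(pts[i + 1] - pts[i])
          n <- max(8, ceiling(n_per_unit * len))
          s <- (seq_len(n) - 0.5) / n
          zs <- c(zs, pts[i] + (pts[i + 1] - pts[i]) * s)
        }
      } else {
        n <- max(8, ceiling(n_per_unit * 3))
        zs <- c(zs, bezier_point(ar$ctrl, (seq_len(n) - 0.5) / n))
      }
    }
    zs
  }

  dens <- refine * nrow(sys$samples) / 12   # samples per unit length, roughly
  zw <- uniform_grid(dens)
  fw <- fields_at(solution, zw)
  per["wall_velocity"] <- max(abs(fw$U), abs(fw$V))
  if (!is.null(dom$particle)) {
    n <- max(64, ceiling(dens * 2 * pi * dom$particle$R))
    zp <- dom$particle$centre +
      dom$particle$R * exp(2i * pi * (seq_len(n) - 0.5) / n)
    fp <- fields_at(solution, zp)
    per["particle_velocity"] <- max(abs(fp$U), abs(fp$V))
  }
  for (op in dom$openings) {
    n <- max(32, ceiling(dens * op$width))
    s <- (seq_len(n) - 0.5) / n
    zo <- op$lo + (op$hi - op$lo) * s
    fo <- fields_at(solution, zo)
    pk <- solution$opening_pressures[op$index + 1L]
    uperp <- -Im(op$axis * complex(real = fo$U, imaginary = -fo$V))
    per[paste0(op$name, "_pressure")] <- max(abs(fo$P - pk))
    per[paste0(op$name, "_transverse")] <- max(abs(uperp))
  }

  near <- NA_real_
  if (length(dom$corners)) {
    o <- sys$options
    o$refine <- o$refine * refine
    fine <- sample_boundary(dom, o)
    wall <- fine$bc_tag == "wall"
    fn <- fields_at(solution, fine$zeta[wall])
    near <- max(abs(fn$U), abs(fn$V))
  }
  list(per_tag = per, overall = max(per), near_corner = near)
}
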