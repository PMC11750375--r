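#' Solver options
#'
#' Numerical parameters of the rational-approximation solver.  The defaults
#' follow the lightning-solver conventions: clustering rate `sigma = 4`, pole
#' length scale equal to the distance from each corner to its nearest adjacent
#' opening, and roughly three boundary samples per pole near each corner.
#'
#' @param poly_degree Degree of the Arnoldi-orthogonalised polynomial part.
#'   `NULL` picks a geometry-appropriate default (24 for straight walls, 48
#'   for Bezier walls, 80 with a particle).
#' @param poles_per_corner Number of exponentially clustered poles per
#'   reentrant corner.
#' @param opening_corner_poles Poles per wall/opening junction corner (the
#'   truncated channel ends carry weak convex-corner singularities); 0
#'   disables them.
#' @param sigma Exponential clustering rate of poles and corner samples.
#' @param laurent_degree Degree of the Laurent block per hole.
#' @param aaa_tol,aaa_max_degree AAA tolerance and maximum number of support
#'   points for curved-wall pole placement.
#' @param wall_oversample Corner-adjacent wall samples per pole.
#' @param n_uniform_wall Additional uniform samples per wall segment.
#' @param opening_points Samples per opening (`NULL`: `max(60, 3*poly_degree)`).
#' @param particle_points Samples on the particle circle
#'   (`NULL`: `max(160, 8*laurent_degree)`).
#' @param residual_warn Boundary-residual level above which a warning is
#'   recorded in the solution's residual report.
#' @param svd_tol Relative singular-value truncation threshold of the
#'   least-squares solve.
#' @param normal_stress If `TRUE`, impose the full normal-stress condition at
#'   openings instead of the (equivalent, for parallel flow) pressure
#'   condition.
#' @param residual_check `"uniform"` (default; refined uniform boundary grid
#'   after each solve) or `"solve_grid"` (cheap unweighted residual at the
#'   collocation points, used in bulk sweeps).
#' @param refine Multiplier on all sampling densities.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(poly_degree = NULL, poles_per_corner = 48,
                           opening_corner_poles = 16,
                           sigma = 4, laurent_degree = 20,
                           aaa_tol = 1e-8, aaa_max_degree = 120,
                           wall_oversample = 4, n_uniform_wall = 16,
                           opening_points = NULL, particle_points = NULL,
                           residual_warn = 1e-6, svd_tol = 1e-14,
                           normal_stress = FALSE, residual_check = "uniform",
                           refine = 1) {
  structure(as.list(environment()), class = "solver_options")
}

# fill geometry-dependent defaults
resolve_options <- function(domain, options = solver_options()) {
  o <- options
  if (is.null(o$poly_degree)) {
    o$poly_degree <- if (!is.null(domain$particle)) 80
    else if (!is.null(domain$spec) && domain$spec$wall_kind == "bezier") 48
    else 24
  }
  if (is.null(o$opening_points)) o$opening_points <- max(60, 3 * o$poly_degree)
  if (is.null(o$particle_points)) o$particle_points <- max(160, 8 * o$laurent_degree)
  o
}

# exponentially clustered distances from a corner: scale*exp(-sigma*(sqrt(N)-sqrt(k)))
cluster_distances <- function(N, sigma, scale = 1) {
  scale * exp(-sigma * (sqrt(N) - sqrt(seq_len(N))))
}

# sample distances matching the depth range of an N-pole cluster, with
# `os` interleaved samples per pole (k runs over j/os, j = 1..N*os)
cluster_sample_distances <- function(N, os, sigma, scale = 1) {
  k <- seq_len(round(N * os)) / os
  scale * exp(-sigma * (sqrt(N) - sqrt(k)))
}

#' Sample the domain boundary for collocation
#'
#' Places least-squares collocation points on every wall arc, opening and (if
#' present) particle circle.  Corner-adjacent wall segments are sampled with
#' the same root-exponential clustering law as the lightning poles; openings
#' use Chebyshev-clustered points; the particle circle is sampled uniformly.
#' Weights are local arc-length quadrature weights.
#'
#' @param domain A `bif_domain`.
#' @param options A [solver_options()].
#' @return A tibble with complex columns `zeta` (positions), `tangent`
#'   (unit tangents along the counter-clockwise traversal), `normal` (unit
#'   normals pointing out of the fluid), numeric `weight`, and character
#'   `bc_tag` (`"wall"`, `"opening0"`, `"opening1"`, `"opening2"`,
#'   `"particle"`).
#' @export
sample_boundary <- function(domain, options = solver_options()) {
  o <- resolve_options(domain, options)
  r <- o$refine
  zs <- complex(0); tg <- complex(0); wt <- numeric(0); tag <- character(0)
  arc_id <- character(0)

  add <- function(z, t, w, bc, arc) {
    zs <<- c(zs, z); tg <<- c(tg, t); wt <<- c(wt, w)
    tag <<- c(tag, rep(bc, length(z))); arc_id <<- c(arc_id, rep(arc, length(z)))
  }

  os <- o$wall_oversample * r
  sample_segment <- function(p, q, poles_at_p, poles_at_q, arc) {
    # poles_at_p / poles_at_q: pole-cluster sizes whose depth range the
    # samples must cover (0 = no cluster at that end)
    len <- Mod(q - p); dir <- (q - p) / len
    nu <- max(4, round(o$n_uniform_wall * r))
    s <- (seq_len(nu) - 0.5) / nu * len
    if (poles_at_p > 0) {
      d <- cluster_sample_distances(poles_at_p, os, o$sigma, len / 2)
      s <- c(s, d[d > len * 1e-15])
    }
    if (poles_at_q > 0) {
      d <- cluster_sample_distances(poles_at_q, os, o$sigma, len / 2)
      s <- c(s, len - d[d > len * 1e-15])
    }
    s <- sort(unique(s))
    z <- p + dir * s
    gaps <- diff(c(0, s, len))
    w <- (gaps[-length(gaps)] + gaps[-1]) / 2
    add(z, rep(dir, length(z)), w, "wall", arc)
  }

  nop <- o$opening_corner_poles
  for (ar in domain$arcs) {
    if (ar$kind == "polyline") {
      pts <- ar$pts
      if (!is.null(ar$corner)) {
        nc <- o$poles_per_corner
        sample_segment(pts[1], pts[2], nop, nc, ar$name)
        sample_segment(pts[2], pts[3], nc, nop, ar$name)
      } else {
        sample_segment(pts[1], pts[length(pts)], nop, nop, ar$name)
      }
    } else {
      # Bezier arc: uniform-in-t midpoints plus clustering toward t = 0.5,
      # where the control-point construction concentrates curvature
      nu <- max(16, round(120 * r))
      tu <- (seq_len(nu) - 0.5) / nu
      dc <- 0.5 * cluster_sample_distances(16, max(2, os / 2), o$sigma, 1)
      tc <- c(0.5 - dc, 0.5 + dc)
      de <- cluster_sample_distances(max(4, round(nop / 2)), 2, o$sigma, 0.25)
      tc <- c(tc, de, 1 - de)
      ts <- sort(unique(c(tu, tc[tc > 1e-9 & tc < 1 - 1e-9])))
      z <- bezier_point(ar$ctrl, ts)
      dv <- bezier_deriv(ar$ctrl, ts)
      ends <- c(bezier_point(ar$ctrl, 0), bezier_point(ar$ctrl, 1))
      gaps <- Mod(diff(c(ends[1], z, ends[2])))
      w <- (gaps[-length(gaps)] + gaps[-1]) / 2
      add(z, dv / Mod(dv), w, "wall", ar$name)
    }
  }

  for (op in domain$openings) {
    n <- max(8, round(o$opening_points * r))
    th <- pi * (seq_len(n) - 0.5) / n
    s <- (1 - cos(th)) / 2
    if (o$opening_corner_poles > 0) {
      d <- cluster_sample_distances(nop, os, o$sigma, 0.5)
      s <- c(s, d[d > 1e-15], 1 - d[d > 1e-15])
    }
    s <- sort(unique(s)) * op$width
    z <- op$lo + (op$hi - op$lo) / op$width * s
    gaps <- diff(c(0, s, op$width))
    w <- (gaps[-length(gaps)] + gaps[-1]) / 2
    add(z, rep((op$hi - op$lo) / op$width, length(s)), w, op$name, op$name)
  }

  if (!is.null(domain$particle)) {
    n <- max(16, round(o$particle_points * r))
    th <- 2 * pi * (seq_len(n) - 0.5) / n
    z <- domain$particle$centre + domain$particle$R * exp(1i * th)
    # clockwise traversal keeps the fluid on the left of the hole boundary
    add(z, -1i * exp(1i * th), rep(2 * pi * domain$particle$R / n, n),
        "particle", "particle")
  }

  tibble::tibble(zeta = zs, tangent = tg, normal = -1i * tg, weight = wt,
                 bc_tag = tag, arc = arc_id, bc_value = NA_real_)
}
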