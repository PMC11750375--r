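#' Dimensional scales of a bifurcation flow
#'
#' Bundle of the dimensional quantities used to convert the solver's
#' dimensionless outputs back to physical units: the parent channel width `d`
#' (length), the inlet flux `q` (area/time, per unit depth) and the dynamic
#' viscosity `mu` (Pa s).  Lengths scale with `d`, velocities with `q/d` and
#' pressures with `mu*q/d^2`.  The scales never enter the solver itself.
#'
#' @param d Parent channel width, length units.  Strictly positive.
#' @param q Inlet flux per unit depth.  Strictly positive.
#' @param mu Dynamic viscosity.  Strictly positive.
#' @return An object of class `dimensional_scales` with fields `d`, `q`, `mu`
#'   and the derived `velocity` (`q/d`) and `pressure` (`mu*q/d^2`) scales.
#' @export
dimensional_scales <- function(d, q, mu) {
  stopifnot(is.numeric(d), is.numeric(q), is.numeric(mu),
            d > 0, q > 0, mu > 0)
  structure(list(d = d, q = q, mu = mu,
                 velocity = q / d, pressure = mu * q / d^2),
            class = "dimensional_scales")
}

#' Specify a dimensionless bifurcation geometry
#'
#' A bifurcation consists of one parent channel of unit width whose centreline
#' runs along the negative X axis, and two child channels of widths `D1`
#' (upper, centreline at angle `alpha` counter-clockwise from +X) and `D2`
#' (lower, centreline at angle `beta` clockwise from +X).  All three
#' centrelines meet at the origin and each channel has centreline length `L`.
#' Walls are straight segments, or single cubic Bezier arcs per wall when
#' `wall_kind = "bezier"`.  An optional fixed circular particle (a hole in the
#' fluid domain) is described by its centre `(X0, Y0)` and radius `R`.
#'
#' @param D1,D2 Child channel widths relative to the parent width, in (0, 1].
#' @param alpha,beta Bifurcation angles in radians, in \[0, pi/2\].
#' @param L Dimensionless centreline length of each channel (default 2).
#' @param wall_kind `"straight"` or `"bezier"`.
#' @param particle Optional `list(X0 =, Y0 =, R =)` (or `NULL`).
#' @param bezier_control_fraction For Bezier walls, where along the straight
#'   wall directions the two interior control points sit: both control points
#'   are placed at `endpoint + f * (corner - endpoint)`, with `f = 1` (the
#'   default) putting both at the straight-geometry corner, which guarantees
#'   tangency to the straight channel walls at the openings.
#' @return An object of class `bif_spec`.
#' @examples
#' bif_spec(0.9, 0.8, pi / 4, pi / 3)
#' @export
bif_spec <- function(D1, D2, alpha, beta, L = 2,
                     wall_kind = c("straight", "bezier"),
                     particle = NULL, bezier_control_fraction = 1) {
  wall_kind <- match.arg(wall_kind)
  if (!is.null(particle)) {
    particle <- as.list(particle)
    stopifnot(all(c("X0", "Y0", "R") %in% names(particle)))
    particle <- particle[c("X0", "Y0", "R")]
  }
  structure(list(D1 = D1, D2 = D2, alpha = alpha, beta = beta, L = L,
                 wall_kind = wall_kind, particle = particle,
                 bezier_control_fraction = bezier_control_fraction),
            class = "bif_spec")
}

#' @export
print.bif_spec <- function(x, ...) {
  cat(sprintf("<bif_spec> D1=%g D2=%g alpha=%.4g beta=%.4g L=%g walls=%s\n",
              x$D1, x$D2, x$alpha, x$beta, x$L, x$wall_kind))
  if (!is.null(x$particle))
    cat(sprintf("  particle at (%g, %g), R=%g\n",
                x$particle$X0, x$particle$Y0, x$particle$R))
  invisible(x)
}

## ---- internal line / segment helpers (complex points throughout) ----------

# intersection of lines Re(Conj(n1) z) = c1 and Re(Conj(n2) z) = c2;
# returns list(kind = "point"/"coincident"/"parallel", z =)
line_intersect <- function(n1, c1, n2, c2) {
  a1 <- Re(n1); b1 <- Im(n1); a2 <- Re(n2); b2 <- Im(n2)
  det <- a1 * b2 - a2 * b1
  if (abs(det) < 1e-12) {
    # parallel: coincident iff the (signed) offsets agree after aligning normals
    s <- if (a1 * a2 + b1 * b2 >= 0) 1 else -1
    if (abs(c1 - s * c2) < 1e-12) list(kind = "coincident", z = NA_complex_)
    else list(kind = "parallel", z = NA_complex_)
  } else {
    x <- (c1 * b2 - c2 * b1) / det
    y <- (a1 * c2 - a2 * c1) / det
    list(kind = "point", z = complex(real = x, imaginary = y))
  }
}

seg_intersects <- function(p1, p2, q1, q2) {
  # proper segment intersection test (shared endpoints do not count)
  o <- function(a, b, c) {
    v <- Im(Conj(b - a) * (c - a))
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
  d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  (d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
}

## ---- validation ------------------------------------------------------------

#' Validate a bifurcation specification
#'
#' Always returns a report (never throws).  Checks parameter ranges, the
#' child-channel overlap rule `alpha + beta >= pi/2`, existence and placement
#' of the three reentrant wall corners, simplicity of the boundary polygon and,
#' if a particle is present, its clearance (at least `1e-3`) from the walls.
#'
#' @param spec A [bif_spec()].
#' @return A list of class `bif_validation` with elements `ok` (logical) and
#'   `violations` (character vector of violated predicates, empty when valid).
#' @examples
#' validate_spec(bif_spec(1, 1, pi / 8, pi / 8))$violations
#' @export
validate_spec <- function(spec) {
  v <- character()
  p <- spec
  if (!(is.finite(p$D1) && p$D1 > 0 && p$D1 <= 1)) v <- c(v, "D1 out of range (0,1]")
  if (!(is.finite(p$D2) && p$D2 > 0 && p$D2 <= 1)) v <- c(v, "D2 out of range (0,1]")
  if (!(is.finite(p$alpha) && p$alpha >= 0 && p$alpha <= pi / 2 + 1e-12))
    v <- c(v, "alpha out of range [0,pi/2]")
  if (!(is.finite(p$beta) && p$beta >= 0 && p$beta <= pi / 2 + 1e-12))
    v <- c(v, "beta out of range [0,pi/2]")
  if (!(is.finite(p$L) && p$L > 0)) v <- c(v, "L not positive")
  if (length(v) == 0L && p$alpha + p$beta < pi / 2 - 1e-12)
    v <- c(v, "child channels overlap")
  dom <- NULL
  if (length(v) == 0L) {
    dom <- tryCatch(build_bifurcation_core(spec), error = function(e) conditionMessage(e))
    if (is.character(dom)) { v <- c(v, dom); dom <- NULL }
  }
  if (!is.null(dom)) {
    for (co in dom$corners)
      if (Mod(co$z) > p$L - 1e-9)
        v <- c(v, "corner beyond centreline distance L from origin")
    # boundary polygon must be simple
    poly <- dom$vertex_polygon
    n <- length(poly)
    segs <- cbind(poly, poly[c(2:n, 1)])
    for (i in seq_len(n - 2)) {
      jmax <- if (i == 1) n - 1 else n
      for (j in (i + 2):jmax)
        if (seg_intersects(segs[i, 1], segs[i, 2], segs[j, 1], segs[j, 2])) {
          v <- c(v, "boundary self-intersects"); break
        }
      if (length(v) > 0 && v[length(v)] == "boundary self-intersects") break
    }
    if (!is.null(p$particle)) {
      pc <- complex(real = p$particle$X0, imaginary = p$particle$Y0)
      R <- p$particle$R
      if (!(is.finite(R) && R > 0)) v <- c(v, "particle radius not positive")
      else {
        dwall <- polygon_distance(dom$dense_polygon, pc)
        if (!point_in_polygon(dom$dense_polygon, pc))
          v <- c(v, "particle centre outside fluid domain")
        else if (dwall - R < 1e-3)
          v <- c(v, "particle too close to boundary (clearance < 1e-3)")
      }
    }
  }
  structure(list(ok = length(v) == 0L, violations = v), class = "bif_validation")
}

#' @export
print.bif_validation <- function(x, ...) {
  if (x$ok) cat("valid bifurcation specification\n")
  else cat("invalid:", paste(x$violations, collapse = "; "), "\n")
  invisible(x)
}

## ---- domain construction ---------------------------------------------------

# core construction without validation wrapper; errors on truly impossible
# wall intersections.  Returns the domain skeleton used by both validate_spec
# and build_bifurcation.
build_bifurcation_core <- function(spec) {
  D1 <- spec$D1; D2 <- spec$D2; a <- spec$alpha; b <- spec$beta; L <- spec$L
  e1 <- exp(1i * a)          # child-1 outward direction (upper)
  e2 <- exp(-1i * b)         # child-2 outward direction (lower)
  n1 <- 1i * e1              # left normal of child 1
  n2 <- 1i * e2              # left normal of child 2
  nup <- complex(real = 0, imaginary = 1)

  # opening endpoints ("lo" first in the CCW boundary traversal)
  inlet_lo <- complex(real = -L, imaginary = -0.5)
  inlet_hi <- complex(real = -L, imaginary = 0.5)
  o1c <- L * e1; o1_lo <- o1c - D1 / 2 * n1; o1_hi <- o1c + D1 / 2 * n1
  o2c <- L * e2; o2_lo <- o2c - D2 / 2 * n2; o2_hi <- o2c + D2 / 2 * n2

  corner_of <- function(na, ca, nb, cb, what) {
    r <- line_intersect(na, ca, nb, cb)
    if (r$kind == "parallel")
      stop(sprintf("wall lines of %s are parallel and distinct", what))
    if (r$kind == "coincident") NULL else r$z
  }
  cA <- corner_of(nup, 0.5, n1, D1 / 2, "parent-upper/child-1-upper")
  cB <- corner_of(n1, -D1 / 2, n2, D2 / 2, "child-1-lower/child-2-upper")
  cC <- corner_of(nup, -0.5, n2, -D2 / 2, "parent-lower/child-2-lower")

  mkarc <- function(name, start, corner, end) {
    pts <- c(start, corner, end)   # corner NULL drops out
    list(name = name, kind = "polyline", pts = pts, corner = corner)
  }
  # arcs in CCW traversal order of the boundary
  arcs <- list(
    lower  = mkarc("lower",  inlet_lo, cC, o2_lo),
    middle = mkarc("middle", o2_hi,    cB, o1_lo),
    upper  = mkarc("upper",  o1_hi,    cA, inlet_hi)
  )

  # sanity: wall segments must run outward from corner toward their openings
  for (ar in arcs) {
    if (is.null(ar$corner)) next
    s1 <- ar$pts[1] - ar$corner; s2 <- ar$pts[3] - ar$corner
    if (Mod(s1) < 1e-9 || Mod(s2) < 1e-9)
      stop(sprintf("degenerate wall segment at the %s corner", ar$name))
  }

  if (spec$wall_kind == "bezier") {
    f <- spec$bezier_control_fraction
    arcs <- lapply(arcs, function(ar) {
      if (is.null(ar$corner)) return(ar)      # straight degenerate wall stays
      p0 <- ar$pts[1]; p3 <- ar$pts[3]; cr <- ar$corner
      list(name = ar$name, kind = "bezier",
           ctrl = c(p0, p0 + f * (cr - p0), p3 + f * (cr - p3), p3),
           corner = NULL, straight_corner = cr)
    })
  }

  openings <- list(
    list(name = "opening0", index = 0L, centre = complex(real = -L),
         width = 1, lo = inlet_lo, hi = inlet_hi,
         outward = complex(real = -1), axis = complex(real = -1)),
    list(name = "opening1", index = 1L, centre = o1c, width = D1,
         lo = o1_lo, hi = o1_hi, outward = e1, axis = e1),
    list(name = "opening2", index = 2L, centre = o2c, width = D2,
         lo = o2_lo, hi = o2_hi, outward = e2, axis = e2)
  )

  # corners with outward (into-solid) bisectors and pole length scales
  corners <- list()
  addcorner <- function(z, toward1, toward2, adj1, adj2) {
    d1 <- (toward1 - z) / Mod(toward1 - z)
    d2 <- (toward2 - z) / Mod(toward2 - z)
    bis <- d1 + d2
    bis <- bis / Mod(bis)     # solid wedge < pi, so d1+d2 bisects it
    list(z = z, bisector = bis,
         scale = min(Mod(adj1 - z), Mod(adj2 - z)))
  }
  if (!is.null(cC)) corners <- c(corners, list(addcorner(cC, inlet_lo, o2_lo, inlet_lo, o2_lo)))
  if (!is.null(cB)) corners <- c(corners, list(addcorner(cB, o2_hi, o1_lo, o2_hi, o1_lo)))
  if (!is.null(cA)) corners <- c(corners, list(addcorner(cA, o1_hi, inlet_hi, o1_hi, inlet_hi)))

  # coarse vertex polygon (straight-wall skeleton) for validity tests
  vertex_polygon <- c(inlet_lo, if (!is.null(cC)) cC, o2_lo, o2_hi,
                      if (!is.null(cB)) cB, o1_lo, o1_hi,
                      if (!is.null(cA)) cA, inlet_hi)

  dom <- list(spec = spec, arcs = arcs, openings = openings, corners = corners,
              vertex_polygon = vertex_polygon)
  dom$dense_polygon <- dense_boundary_polygon(dom)
  dom
}

# dense polygon (CCW) used for point-in-domain and pole filtering
dense_boundary_polygon <- function(dom, n_bezier = 400) {
  op <- dom$openings
  poly <- c(op[[1]]$lo,
            arc_points(dom$arcs$lower, n_bezier),
            op[[3]]$lo, op[[3]]$hi,
            arc_points(dom$arcs$middle, n_bezier),
            op[[2]]$lo, op[[2]]$hi,
            arc_points(dom$arcs$upper, n_bezier),
            op[[1]]$hi)
  # drop consecutive duplicates (arc endpoints coincide with opening corners)
  keep <- c(TRUE, Mod(diff(poly)) > 1e-14)
  poly[keep]
}

arc_points <- function(ar, n = 400) {
  if (ar$kind == "polyline") ar$pts
  else bezier_point(ar$ctrl, seq(0, 1, length.out = n))
}

#' Build the fluid domain of a bifurcation
#'
#' Computes wall arcs, openings, reentrant corners (as wall-line
#' intersections), the optional particle circle, and the three region polygons
#' used for area accounting.  Region dividing lines connect the origin to the
#' three wall corners (straight walls) or to the Bezier points at parameter
#' `t = 0.5` (curved walls).
#'
#' @param spec A valid [bif_spec()].
#' @return An object of class `bif_domain`.
#' @examples
#' dom <- build_bifurcation(bif_spec(0.9, 0.8, pi / 4, pi / 3))
#' length(dom$corners)
#' @export
build_bifurcation <- function(spec) {
  rep <- validate_spec(spec)
  if (!rep$ok)
    stop("invalid bifurcation geometry: ", paste(rep$violations, collapse = "; "))
  dom <- build_bifurcation_core(spec)
  if (!is.null(spec$particle))
    dom$particle <- list(centre = complex(real = spec$particle$X0,
                                          imaginary = spec$particle$Y0),
                         R = spec$particle$R)
  dom$region_polygons <- region_polygons(dom)
  dom$n_openings <- 3L
  class(dom) <- "bif_domain"
  dom
}

#' @export
print.bif_domain <- function(x, ...) {
  cat(sprintf("<bif_domain> %d openings, %d corners, walls=%s%s\n",
              length(x$openings), length(x$corners), x$spec$wall_kind,
              if (!is.null(x$particle)) sprintf(", particle R=%g", x$particle$R) else ""))
  invisible(x)
}

# division point for region accounting on one arc
arc_division_point <- function(ar) {
  if (!is.null(ar$corner)) return(ar$corner)
  if (ar$kind == "bezier") return(bezier_point(ar$ctrl, 0.5))
  # straight corner-less wall: point at half arc length
  (ar$pts[1] + ar$pts[length(ar$pts)]) / 2
}

# path along an arc between its division point and one end, as vertices
arc_half <- function(ar, half = c("start", "end"), n = 120) {
  half <- match.arg(half)
  if (ar$kind == "bezier") {
    ts <- if (half == "start") seq(0.5, 0, length.out = n) else seq(0.5, 1, length.out = n)
    bezier_point(ar$ctrl, ts)
  } else {
    dv <- arc_division_point(ar)
    if (half == "start") c(dv, ar$pts[1]) else c(dv, ar$pts[length(ar$pts)])
  }
}

region_polygons <- function(dom) {
  op <- dom$openings
  dU <- arc_division_point(dom$arcs$upper)
  dM <- arc_division_point(dom$arcs$middle)
  dW <- arc_division_point(dom$arcs$lower)
  # region 0 (parent): origin -> upper arc (div..inlet_hi) -> inlet -> lower arc (inlet_lo..div)
  r0 <- c(0 + 0i, arc_half(dom$arcs$upper, "end"), op[[1]]$hi, op[[1]]$lo,
          rev(arc_half(dom$arcs$lower, "start")))
  # region 1 (child 1): origin -> middle arc (div..o1_lo) -> opening1 -> upper arc (o1_hi..div)
  r1 <- c(0 + 0i, arc_half(dom$arcs$middle, "end"), op[[2]]$lo, op[[2]]$hi,
          rev(arc_half(dom$arcs$upper, "start")))
  # region 2 (child 2): origin -> lower arc (div..o2_lo) -> opening2 -> middle arc (o2_hi..div)
  r2 <- c(0 + 0i, arc_half(dom$arcs$lower, "end"), op[[3]]$lo, op[[3]]$hi,
          rev(arc_half(dom$arcs$middle, "start")))
  list(parent = r0, child1 = r1, child2 = r2)
}

#' Region areas of a bifurcation
#'
#' Splits the fluid domain into parent / child-1 / child-2 regions by
#' connecting the origin to the per-wall division points (corners for straight
#' walls, Bezier midpoints for curved walls) and returns the region areas.
#' When a particle is present its clipped overlap with each region is
#' subtracted, so the areas sum to the fluid area.
#'
#' @param domain A [build_bifurcation()] domain.
#' @return A tibble with columns `region` (`"parent"`, `"child1"`, `"child2"`)
#'   and `area`.
#' @examples
#' region_areas(build_bifurcation(bif_spec(1, 1, pi / 4, pi / 4)))
#' @export
region_areas <- function(domain) {
  polys <- domain$region_polygons
  areas <- vapply(polys, polygon_area, numeric(1))
  if (!is.null(domain$particle)) {
    circ <- domain$particle$centre +
      domain$particle$R * exp(2i * pi * (seq_len(720) - 1) / 720)
    ov <- vapply(polys, function(pp) {
      cl <- clip_polygon(pp, circ)
      if (length(cl) < 3) 0 else polygon_area(cl)
    }, numeric(1))
    areas <- areas - ov
  }
  tibble::tibble(region = names(polys), area = unname(areas))
}

#' Test whether points lie inside the fluid domain
#'
#' @param domain A `bif_domain` (or channel domain).
#' @param z Complex vector of query points.
#' @param tol Points within `tol` of the boundary count as inside.
#' @return Logical vector.
#' @export
point_in_domain <- function(domain, z, tol = 0) {
  inside <- point_in_polygon(domain$dense_polygon, z, tol = tol)
  if (!is.null(domain$particle))
    inside <- inside & (Mod(z - domain$particle$centre) > domain$particle$R - tol)
  inside
}

## ---- straight two-opening channel (used for exactness oracles) -------------

#' Build a straight rectangular channel domain
#'
#' A plain channel of given width and length with two pressure openings (left
#' and right) and two straight walls: the configuration on which plane
#' Poiseuille flow is exact and the solver must reproduce the conductance
#' `width^3 / (12 * length)` to machine accuracy.
#'
#' @param width Channel width (Y extent, centred on the X axis).
#' @param length Channel length (X from `-length/2` to `length/2`).
#' @return An object of class `bif_domain` with two openings.
#' @export
build_channel <- function(width = 1, length = 4) {
  h <- width / 2; l <- length / 2
  a_lo <- complex(real = -l, imaginary = -h); b_lo <- complex(real = l, imaginary = -h)
  a_hi <- complex(real = -l, imaginary = h);  b_hi <- complex(real = l, imaginary = h)
  arcs <- list(
    lower = list(name = "lower", kind = "polyline", pts = c(a_lo, b_lo), corner = NULL),
    upper = list(name = "upper", kind = "polyline", pts = c(b_hi, a_hi), corner = NULL)
  )
  openings <- list(
    list(name = "opening0", index = 0L, centre = complex(real = -l), width = width,
         lo = a_lo, hi = a_hi, outward = complex(real = -1), axis = complex(real = -1)),
    list(name = "opening1", index = 1L, centre = complex(real = l), width = width,
         lo = b_lo, hi = b_hi, outward = complex(real = 1), axis = complex(real = 1))
  )
  dom <- list(spec = NULL, arcs = arcs, openings = openings, corners = list(),
              vertex_polygon = c(a_lo, b_lo, b_hi, a_hi))
  dom$dense_polygon <- dom$vertex_polygon
  dom$region_polygons <- NULL
  dom$n_openings <- 2L
  class(dom) <- "bif_domain"
  dom
}
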