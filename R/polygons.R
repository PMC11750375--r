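# Polygon and Bezier primitives used by the geometry module.  Polygons are
# complex vectors of vertices (implicitly closed, no repeated last vertex).

# signed shoelace area; abs() for the geometric area
polygon_area <- function(poly) {
  x <- Re(poly); y <- Im(poly)
  n <- length(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# even-odd ray casting; edge-vectorised for few query points, point-vectorised
# for many
point_in_polygon <- function(poly, z, tol = 0) {
  px <- Re(poly); py <- Im(poly)
  n <- length(poly)
  j <- c(n, seq_len(n - 1))
  x <- Re(z); y <- Im(z)
  if (length(z) <= 16) {
    xi <- px; yi <- py; xj <- px[j]; yj <- py[j]
    inside <- vapply(seq_along(z), function(q) {
      cr <- ((yi > y[q]) != (yj > y[q])) &
        (x[q] < (xj - xi) * (y[q] - yi) / (yj - yi) + xi)
      sum(cr) %% 2L == 1L
    }, logical(1))
  } else {
    inside <- logical(length(z))
    for (k in seq_len(n)) {
      xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
      cross <- ((yi > y) != (yj > y)) &
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
  }
  if (tol > 0) inside | (polygon_distance(poly, z) <= tol)
  else inside
}

# distance from point(s) to the polygon boundary (min over edges)
polygon_distance <- function(poly, z) {
  n <- length(poly)
  a <- poly
  b <- poly[c(2:n, 1)]
  vapply(z, function(p) {
    ab <- b - a
    t <- pmin(1, pmax(0, Re(Conj(ab) * (p - a)) / pmax(Mod(ab)^2, 1e-300)))
    min(Mod(p - (a + t * ab)))
  }, numeric(1))
}

# Sutherland-Hodgman: clip (possibly non-convex) subject polygon against a
# convex clip polygon (both CCW).  Returns the clipped vertex list.
clip_polygon <- function(subject, clip) {
  n <- length(clip)
  out <- subject
  for (k in seq_len(n)) {
    if (length(out) < 3) return(complex(0))
    a <- clip[k]; b <- clip[if (k == n) 1 else k + 1]
    edge <- b - a
    inside <- function(p) Im(Conj(edge) * (p - a)) >= -1e-14
    m <- length(out)
    res <- complex(0)
    prev <- out[m]; prev_in <- inside(prev)
    for (i in seq_len(m)) {
      cur <- out[i]; cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) res <- c(res, seg_line_cross(prev, cur, a, b))
        res <- c(res, cur)
      } else if (prev_in) {
        res <- c(res, seg_line_cross(prev, cur, a, b))
      }
      prev <- cur; prev_in <- cur_in
    }
    out <- res
  }
  out
}

# intersection of segment p->q with the infinite line a->b
seg_line_cross <- function(p, q, a, b) {
  d1 <- Im(Conj(b - a) * (p - a))
  d2 <- Im(Conj(b - a) * (q - a))
  t <- d1 / (d1 - d2)
  p + t * (q - p)
}

# cubic Bezier point(s) at parameter t (vectorised over t)
bezier_point <- function(ctrl, t) {
  u <- 1 - t
  u^3 * ctrl[1] + 3 * u^2 * t * ctrl[2] + 3 * u * t^2 * ctrl[3] + t^3 * ctrl[4]
}

# cubic Bezier derivative d/dt
bezier_deriv <- function(ctrl, t) {
  u <- 1 - t
  3 * (u^2 * (ctrl[2] - ctrl[1]) + 2 * u * t * (ctrl[3] - ctrl[2]) +
         t^2 * (ctrl[4] - ctrl[3]))
}
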