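# Rational basis for the Goursat functions: Arnoldi-orthogonalised polynomial,
# lightning poles at reentrant corners, AAA poles for curved walls, Laurent
# series and a single-valued log pair for holes.

## ---- Vandermonde with Arnoldi ---------------------------------------------

# Build the Hessenberg recurrence orthogonalising {1, s, s^2, ...} against the
# (scaled) boundary samples.  Returns the complex (n+1) x n recurrence matrix.
arnoldi_fit <- function(S, n) {
  M <- length(S)
  H <- matrix(0 + 0i, n + 1, n)
  Q <- matrix(0 + 0i, M, n + 1)
  Q[, 1] <- 1
  for (k in seq_len(n)) {
    q <- S * Q[, k]
    for (j in seq_len(k)) {
      H[j, k] <- sum(Conj(Q[, j]) * q) / M
      q <- q - H[j, k] * Q[, j]
    }
    H[k + 1, k] <- sqrt(sum(Mod(q)^2) / M)
    Q[, k + 1] <- q / H[k + 1, k]
  }
  H
}

# Evaluate the Arnoldi polynomial basis and its first (and optionally second)
# derivative with respect to s by differentiating the recurrence.
arnoldi_eval <- function(S, H, second = FALSE) {
  n <- ncol(H)
  M <- length(S)
  V <- matrix(0 + 0i, M, n + 1); V[, 1] <- 1
  D <- matrix(0 + 0i, M, n + 1)
  D2 <- if (second) matrix(0 + 0i, M, n + 1) else NULL
  for (k in seq_len(n)) {
    q <- S * V[, k]
    d <- V[, k] + S * D[, k]
    d2 <- if (second) 2 * D[, k] + S * D2[, k] else NULL
    for (j in seq_len(k)) {
      q <- q - H[j, k] * V[, j]
      d <- d - H[j, k] * D[, j]
      if (second) d2 <- d2 - H[j, k] * D2[, j]
    }
    V[, k + 1] <- q / H[k + 1, k]
    D[, k + 1] <- d / H[k + 1, k]
    if (second) D2[, k + 1] <- d2 / H[k + 1, k]
  }
  list(V = V, D = D, D2 = D2)
}

## ---- lightning poles -------------------------------------------------------

#' Exponentially clustered poles at a reentrant corner
#'
#' Places `N` simple poles along the corner's outward (into-solid) bisector at
#' distances `scale * exp(-sigma * (sqrt(N) - sqrt(k)))`, `k = 1..N`, the
#' root-exponential clustering that yields lightning-solver convergence for
#' corner singularities.
#'
#' @param corner Complex corner location.
#' @param bisector Unit complex direction pointing out of the fluid.
#' @param N Number of poles (>= 1).
#' @param sigma Clustering rate (> 0).
#' @param scale Length scale (distance of the farthest pole from the corner).
#' @return Complex vector of `N` pole locations, ordered outermost first.
#' @examples
#' lightning_poles(0 + 0i, 1 + 0i, N = 4, sigma = 4, scale = 1)
#' @export
lightning_poles <- function(corner, bisector, N, sigma = 4, scale = 1) {
  stopifnot(N >= 1, sigma > 0, scale > 0)
  corner + bisector * rev(cluster_distances(N, sigma, scale))
}

## ---- AAA rational approximation -------------------------------------------

#' AAA rational approximation
#'
#' Greedy barycentric rational approximation of data `F` on points `Z`:
#' support points are chosen where the current error is largest, weights come
#' from the smallest singular vector of the Loewner matrix, and poles from the
#' generalised eigenvalue problem of the barycentric form.  Spurious poles
#' with negligible residue are discarded.
#'
#' @param Z Complex sample points.
#' @param F Complex data values at `Z`.
#' @param tol Relative tolerance (on `max(abs(F))`).
#' @param mmax Maximum number of support points.
#' @return A list with `poles`, `residues`, `support`, `values`, `weights`,
#'   `error` (achieved max abs error on the samples) and `degree` (number of
#'   support points minus one).
#' @export
aaa <- function(Z, F, tol = 1e-8, mmax = 120) {
  M <- length(Z)
  stopifnot(length(F) == M, M >= 2)
  fscale <- max(Mod(F))
  J <- seq_len(M)
  zs <- complex(0); fs <- complex(0)
  R <- rep(mean(F), M)
  w <- complex(0)
  err <- Inf
  for (m in seq_len(min(mmax, M - 1))) {
    j <- J[which.max(Mod(F[J] - R[J]))]
    zs <- c(zs, Z[j]); fs <- c(fs, F[j])
    J <- J[J != j]
    C <- 1 / outer(Z[J], zs, "-")
    A <- F[J] * C - C * matrix(fs, nrow = length(J), ncol = m, byrow = TRUE)
    sv <- svd(A, nu = 0, nv = m)
    w <- sv$v[, m]
    R[J] <- (C %*% (w * fs)) / (C %*% w)
    err <- max(Mod(F[J] - R[J]))
    if (err < tol * fscale) break
  }
  m <- length(zs)
  poles <- complex(0); residues <- complex(0)
  if (m >= 2) {
    E <- rbind(c(0 + 0i, w), cbind(rep(1 + 0i, m), diag(zs, nrow = m)))
    B <- diag(c(0, rep(1, m))) + 0i
    mu <- tryCatch(eigen(solve(E, B), only.values = TRUE)$values,
                   error = function(e) complex(0))
    poles <- 1 / mu[Mod(mu) > 1e-13]
    # poles many orders beyond the data diameter are eigenvalue artifacts of
    # degenerate (entire) data, indistinguishable from polynomial behaviour
    zc <- mean(zs)
    zscale <- max(Mod(Z - zc))
    poles <- poles[Mod(poles - zc) < 1e6 * zscale]
    if (length(poles)) {
      # residues via N(p)/D'(p) of the barycentric form
      Cp <- 1 / outer(poles, zs, "-")
      num <- Cp %*% (w * fs)
      den <- -(Cp^2) %*% w
      residues <- as.complex(num / den)
      keep <- Mod(residues) > 1e-13 * max(fscale, 1)
      poles <- poles[keep]; residues <- residues[keep]
    }
  }
  list(poles = poles, residues = residues, support = zs, values = fs,
       weights = w, error = err, degree = m - 1)
}

#' Exterior poles from the Schwarz function of a curved arc
#'
#' Approximates the Schwarz function `F(zeta) = Conj(zeta)` of one boundary
#' arc by AAA and returns the poles of the approximant, optionally filtered to
#' those strictly outside the fluid domain.  The Schwarz function depends only
#' on the arc's shape, so its exterior poles capture the singularity structure
#' any Goursat function can inherit from that wall.
#'
#' @param samples Complex points on one curved boundary arc (>= 16).
#' @param tol AAA tolerance.
#' @param domain Optional `bif_domain`; when given, poles inside the closed
#'   fluid domain are discarded.
#' @param mmax Maximum AAA support points.
#' @return List with `poles` (filtered), `all_poles`, `error`, `degree`.
#' @export
aaa_schwarz_poles <- function(samples, tol = 1e-8, domain = NULL, mmax = 120) {
  stopifnot(length(samples) >= 16)
  fit <- aaa(samples, Conj(samples), tol = tol, mmax = mmax)
  if (fit$error > tol * max(Mod(samples)) * 10 && fit$degree >= mmax - 1)
    stop(sprintf("AAA did not converge: achieved error %.3g", fit$error))
  poles <- fit$poles
  if (!is.null(domain) && length(poles))
    poles <- poles[!point_in_domain(domain, poles, tol = 1e-9)]
  list(poles = poles, all_poles = fit$poles, error = fit$error,
       degree = fit$degree)
}

## ---- basis assembly --------------------------------------------------------

#' Build the rational basis for a domain
#'
#' Combines the Arnoldi-orthogonalised polynomial (degree `poly_degree`),
#' lightning poles at each reentrant corner (straight walls) or AAA poles from
#' the Schwarz functions of the Bezier arcs (curved walls), and, per hole, a
#' Laurent block about the particle centre plus one single-valued log pair.
#' Pole and Laurent columns are scaled to unit maximum modulus on the
#' boundary samples.
#'
#' @param domain A `bif_domain`.
#' @param samples Boundary samples from [sample_boundary()].
#' @param options A [solver_options()].
#' @return An object of class `rational_basis`.
#' @export
build_basis <- function(domain, samples, options = solver_options()) {
  o <- resolve_options(domain, options)
  zb <- samples$zeta
  zc <- mean(zb)
  sc <- max(Mod(zb - zc))

  n <- o$poly_degree
  H <- arnoldi_fit((zb - zc) / sc, n)

  poles <- complex(0)
  curved <- !is.null(domain$spec) && domain$spec$wall_kind == "bezier"
  if (curved) {
    for (ar in domain$arcs) {
      if (ar$kind != "bezier") next
      zarc <- samples$zeta[samples$arc == ar$name]
      fit <- aaa_schwarz_poles(zarc, tol = o$aaa_tol, domain = domain,
                               mmax = o$aaa_max_degree)
      poles <- c(poles, fit$poles)
    }
  }
  for (co in if (curved) list() else domain$corners) {
    pk <- lightning_poles(co$z, co$bisector, o$poles_per_corner,
                          o$sigma, co$scale)
    if (any(point_in_domain(domain, pk)))
      stop("lightning pole placed inside the fluid domain (bisector misdirected)")
    poles <- c(poles, pk)
  }
  if (o$opening_corner_poles > 0) {
    # mild clusters behind the wall/opening junction corners: the truncated
    # channel ends induce weak convex-corner singularities there
    for (op in domain$openings) {
      tlo <- (op$hi - op$lo) / op$width
      for (side in c("lo", "hi")) {
        corner <- op[[side]]
        tin <- if (side == "lo") tlo else -tlo
        bis <- op$outward - tin
        bis <- bis / Mod(bis)
        poles <- c(poles, lightning_poles(corner, bis, o$opening_corner_poles,
                                          o$sigma, op$width / 2))
      }
    }
  }
  pole_scale <- if (length(poles))
    vapply(poles, function(p) min(Mod(zb - p)), numeric(1)) else numeric(0)

  laurent <- NULL
  log_centre <- NULL
  if (!is.null(domain$particle)) {
    laurent <- list(centre = domain$particle$centre, degree = o$laurent_degree,
                    R = domain$particle$R)
    log_centre <- domain$particle$centre
  }

  structure(list(centre = zc, scale = sc, H = H, poly_degree = n,
                 poles = poles, pole_scale = pole_scale,
                 laurent = laurent, log_centre = log_centre,
                 n_columns = (n + 1) + length(poles) +
                   (if (is.null(laurent)) 0L else laurent$degree)),
            class = "rational_basis")
}

#' @export
print.rational_basis <- function(x, ...) {
  cat(sprintf("<rational_basis> polynomial degree %d, %d poles%s%s\n",
              x$poly_degree, length(x$poles),
              if (!is.null(x$laurent))
                sprintf(", Laurent degree %d", x$laurent$degree) else "",
              if (!is.null(x$log_centre)) ", log pair" else ""))
  invisible(x)
}

#' Evaluate the rational basis
#'
#' Values and first derivatives (optionally second derivatives) of every
#' non-log basis column at the query points.  Derivatives of the Arnoldi
#' polynomial come from differentiating the recurrence, never from finite
#' differences.
#'
#' @param basis A [build_basis()] object.
#' @param points Complex query points.
#' @param second Also return second derivatives.
#' @return List with complex matrices `V` (values), `D` (d/dzeta) and, if
#'   requested, `D2`.
#' @export
evaluate_basis <- function(basis, points, second = FALSE) {
  S <- (points - basis$centre) / basis$scale
  pe <- arnoldi_eval(S, basis$H, second = second)
  V <- pe$V
  D <- pe$D / basis$scale
  D2 <- if (second) pe$D2 / basis$scale^2 else NULL
  if (length(basis$poles)) {
    dif <- outer(points, basis$poles, "-")
    sc <- matrix(basis$pole_scale, nrow = length(points),
                 ncol = length(basis$poles), byrow = TRUE)
    V <- cbind(V, sc / dif)
    D <- cbind(D, -sc / dif^2)
    if (second) D2 <- cbind(D2, 2 * sc / dif^3)
  }
  if (!is.null(basis$laurent)) {
    w <- points - basis$laurent$centre
    q <- basis$laurent$degree
    R <- basis$laurent$R
    Vl <- sapply(seq_len(q), function(j) (R / w)^j)
    Dl <- sapply(seq_len(q), function(j) -j * R^j / w^(j + 1))
    if (length(points) == 1) { Vl <- matrix(Vl, 1); Dl <- matrix(Dl, 1) }
    V <- cbind(V, Vl)
    D <- cbind(D, Dl)
    if (second)
      D2 <- cbind(D2, sapply(seq_len(q), function(j) {
        m <- j * (j + 1) * R^j / w^(j + 2)
        if (length(points) == 1) matrix(m, 1) else m
      }))
  }
  list(V = V, D = D, D2 = D2)
}
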