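test_that("lightning pole distances follow the root-exponential clustering law", {
  p <- lightning_poles(0 + 0i, 1 + 0i, N = 1, sigma = 4, scale = 0.7)
  expect_equal(p, 0.7 + 0i)
  p <- lightning_poles(2 + 1i, exp(1i * pi / 3), N = 48, sigma = 4, scale = 1.3)
  d <- Mod(p - (2 + 1i))
  expect_equal(sort(d), sort(1.3 * exp(-4 * (sqrt(48) - sqrt(1:48)))),
               tolerance = 1e-14)
  # span of distances matches the formula end points (absolute tolerance:
  # the innermost offset is ~5e-11 against a corner of magnitude ~2)
  expect_lt(abs(min(d) / 1.3 - exp(-4 * (sqrt(48) - 1))), 1e-14)
  expect_equal(max(d) / 1.3, 1, tolerance = 1e-12)
})

test_that("AAA recovers the Schwarz singularity of a circle and is exact on lines", {
  th <- seq(0.2, 2.4, length.out = 120)
  c0 <- 1.1 - 0.4i; r <- 0.6
  Z <- c0 + r * exp(1i * th)
  fit <- aaa(Z, Conj(Z), tol = 1e-10)
  expect_gte(length(fit$poles), 1)
  expect_lt(min(Mod(fit$poles - c0)), 1e-8)
  expect_lt(fit$error, 1e-9)
  # line: Schwarz function is entire (linear); no significant poles survive
  Zl <- complex(real = seq(-1, 1, length.out = 64), imaginary = 0.3)
  fl <- aaa(Zl, Conj(Zl), tol = 1e-10)
  expect_lt(fl$error, 1e-10)
  expect_lte(fl$degree, 1)
  expect_length(fl$poles[Mod(fl$residues) > 1e-8], 0)
})

test_that("aaa_schwarz_poles filters poles to the domain exterior", {
  dom <- build_bifurcation(bif_spec(0.9, 0.8, pi / 4, pi / 3,
                                    wall_kind = "bezier"))
  s <- sample_boundary(dom, fast_options())
  zarc <- s$zeta[s$arc == "middle"]
  fit <- aaa_schwarz_poles(zarc, tol = 1e-8, domain = dom)
  expect_gt(length(fit$poles), 0)
  expect_false(any(point_in_domain(dom, fit$poles)))
  expect_lt(fit$error, 1e-6)
})

test_that("basis derivatives match finite differences and exact columns", {
  dom <- build_bifurcation(ref_spec())
  s <- sample_boundary(dom, fast_options())
  basis <- build_basis(dom, s, fast_options())
  set.seed(1)
  # random interior points away from the boundary
  pts <- complex(real = runif(200, -1.9, 1.2), imaginary = runif(200, -1, 1))
  pts <- pts[point_in_domain(dom, pts, tol = 0)]
  pts <- pts[bifstokes:::polygon_distance(dom$dense_polygon, pts) > 0.05]
  ev <- evaluate_basis(basis, pts)
  h <- 1e-6
  fd <- (evaluate_basis(basis, pts + h)$V -
           evaluate_basis(basis, pts - h)$V) / (2 * h)
  rel <- Mod(ev$D - fd) / pmax(Mod(ev$D), 1)
  expect_lt(max(rel), 1e-6)
  # constant column
  expect_equal(ev$V[, 1], rep(1 + 0i, length(pts)))
  expect_equal(ev$D[, 1], rep(0 + 0i, length(pts)))
  # pole column derivative is exactly -s/(z - zj)^2
  j <- basis$poly_degree + 2L
  zj <- basis$poles[1]; sc <- basis$pole_scale[1]
  expect_equal(ev$D[, j], -sc / (pts - zj)^2, tolerance = 1e-12)
})

test_that("all basis singularities lie outside the closed fluid domain", {
  for (name in c("reference", "particle")) {
    spec <- fixture_catalog()[[name]]
    dom <- build_bifurcation(spec)
    s <- sample_boundary(dom, fast_options())
    basis <- build_basis(dom, s, fast_options())
    expect_false(any(point_in_domain(dom, basis$poles)))
    if (!is.null(basis$laurent)) {
      expect_false(point_in_domain(dom, basis$laurent$centre))
      expect_lt(Mod(basis$laurent$centre - dom$particle$centre),
                dom$particle$R)
    }
  }
})

test_that("the log pair is single-valued around the hole", {
  dom <- build_bifurcation(fixture_catalog()$particle)
  s <- sample_boundary(dom, fast_options())
  basis <- build_basis(dom, s, fast_options())
  th <- seq(0, 2 * pi, length.out = 257)  # closed loop encircling the hole
  loop <- 0.35 * exp(1i * th)
  cols <- bifstokes:::goursat_columns(basis, loop, what = c("E", "Psi"))
  K <- 4 * basis$n_columns
  for (j in K + (1:3)) {
    expect_lt(Mod(cols$E[1, j] - cols$E[257, j]), 1e-12)
    expect_lt(Mod(cols$Psi[1, j] - cols$Psi[257, j]), 1e-12)
  }
})

test_that("the Arnoldi polynomial basis spans monomials on random points", {
  set.seed(3)
  Z <- complex(real = rnorm(300), imaginary = rnorm(300))
  H <- bifstokes:::arnoldi_fit(Z, 12)
  V <- bifstokes:::arnoldi_eval(Z, H)$V
  # monomials are reproduced by least squares in the orthogonalised basis
  for (k in c(3, 7, 12)) {
    y <- Z^k
    co <- qr.solve(V, y)
    expect_lt(max(Mod(V %*% co - y)), 1e-8 * max(Mod(y)))
  }
})
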