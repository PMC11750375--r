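# The closed-form plane-Poiseuille pair f = -z^2, g' = 1 + z^2 gives
# U = 1 - 4Y^2, V = 0, P = -8X, Omega = 8Y: the exactness oracle for the
# solver, since a rectangle channel flow lies exactly in the basis span.

test_that("a rectangle channel reproduces plane Poiseuille to machine level", {
  ch <- build_channel(width = 1, length = 4)
  sol <- solve_stokes(ch, c(16, -16), solver_options(poly_degree = 10))
  set.seed(11)
  pts <- complex(real = runif(50, -1.8, 1.8), imaginary = runif(50, -0.45, 0.45))
  f <- evaluate_fields(sol, pts)
  expect_equal(f$U, 1 - 4 * Im(pts)^2, tolerance = 1e-8)
  expect_lt(max(abs(f$V)), 1e-8)
  expect_equal(f$P, -8 * Re(pts), tolerance = 1e-8)
  expect_equal(f$Omega, 8 * Im(pts), tolerance = 1e-7)
  # stream function consistency: U = dPsi/dY by finite differences
  h <- 1e-5
  up <- evaluate_fields(sol, pts + 1i * h)$Psi
  dn <- evaluate_fields(sol, pts - 1i * h)$Psi
  expect_equal((up - dn) / (2 * h), f$U, tolerance = 1e-6)
})

test_that("channel conductance equals D^3/(12 L) for several shapes", {
  for (geom in list(c(1, 4), c(0.7, 3), c(1, 2))) {
    ch <- build_channel(geom[1], geom[2])
    sol <- solve_stokes(ch, c(0, -1), solver_options(poly_degree = 10))
    ps <- bifstokes:::fields_at(sol, c(ch$openings[[2]]$lo, ch$openings[[2]]$hi))$Psi
    expect_equal(ps[2] - ps[1], geom[1]^3 / (12 * geom[2]), tolerance = 1e-8)
  }
})

test_that("zero opening pressures give the zero solution", {
  ch <- build_channel(1, 4)
  sol <- solve_stokes(ch, c(0, 0), solver_options(poly_degree = 8))
  f <- evaluate_fields(sol, complex(real = c(0, 1), imaginary = c(0.1, -0.2)))
  expect_lt(max(abs(c(f$U, f$V, f$P))), 1e-12)
  expect_lt(sol$residual_report$overall, 1e-12)
})

test_that("solutions superpose linearly in the opening pressures", {
  dom <- build_bifurcation(ref_spec())
  sys <- stokes_system(dom, fast_options())
  s10 <- solve_stokes(dom, c(0, 1, 0), system = sys)
  s01 <- solve_stokes(dom, c(0, 0, 1), system = sys)
  lam <- -1.3; mu <- 0.4
  smix <- solve_stokes(dom, c(0, lam, mu), system = sys)
  expect_equal(smix$x, lam * s10$x + mu * s01$x, tolerance = 1e-9)
  pts <- complex(real = c(-1.5, 0, 0.9), imaginary = c(0.1, -0.2, 0.4))
  fm <- evaluate_fields(smix, pts)
  f1 <- evaluate_fields(s10, pts)
  f2 <- evaluate_fields(s01, pts)
  for (col in c("U", "V", "P", "Psi"))
    expect_equal(fm[[col]], lam * f1[[col]] + mu * f2[[col]], tolerance = 1e-8)
})

test_that("walls carry no slip and the symmetry axis no transverse flow", {
  dom <- build_bifurcation(sym_spec())
  sol <- solve_stokes(dom, c(0, -1, -1), fast_options())
  # mid-wall points, away from corners
  zw <- c(complex(real = -1, imaginary = 0.5),
          complex(real = -1.5, imaginary = -0.5))
  fw <- bifstokes:::fields_at(sol, zw)
  expect_lt(max(abs(fw$U), abs(fw$V)), 1e-6)
  # upstream of the junction the axis is a streamline
  za <- complex(real = seq(-1.9, -0.5, length.out = 7), imaginary = 0)
  expect_lt(max(abs(bifstokes:::fields_at(sol, za)$V)), 1e-7)
})

test_that("mirror anti-symmetry relates swapped pressure solves", {
  dom <- build_bifurcation(sym_spec())
  sys <- stokes_system(dom, fast_options())
  sab <- solve_stokes(dom, c(0, 0.7, -0.2), system = sys)
  sba <- solve_stokes(dom, c(0, -0.2, 0.7), system = sys)
  pts <- complex(real = c(-1.2, 0.2, 0.8), imaginary = c(0.3, 0.1, -0.3))
  fa <- evaluate_fields(sab, Conj(pts))
  fb <- evaluate_fields(sba, pts)
  expect_equal(fa$U, fb$U, tolerance = 1e-6)
  expect_equal(fa$V, -fb$V, tolerance = 1e-6)
  expect_equal(fa$P, fb$P, tolerance = 1e-5)
})

test_that("field evaluation flags points outside the domain as NA", {
  dom <- build_bifurcation(ref_spec())
  sol <- solve_stokes(dom, c(0, -1, -1), fast_options())
  f <- evaluate_fields(sol, tibble::tibble(X = c(0, 5, -1), Y = c(0, 5, 2)))
  expect_false(anyNA(f$U[1]))
  expect_true(all(is.na(f$U[2:3])))
})

test_that("the residual degrades monotonically as the basis shrinks", {
  dom <- build_bifurcation(ref_spec())
  r <- sapply(c(6, 12, 24), function(np) {
    sol <- solve_stokes(dom, c(0, 1, 0),
                        fast_options(poles_per_corner = np))
    sol$residual_report$overall
  })
  expect_true(all(diff(r) < 0))
})

test_that("under-resolved sampling is rejected", {
  dom <- build_bifurcation(ref_spec())
  o <- fast_options(poly_degree = 60, poles_per_corner = 60,
                    n_uniform_wall = 4, wall_oversample = 1,
                    opening_points = 8, opening_corner_poles = 0)
  s <- sample_boundary(dom, o)
  b <- build_basis(dom, s, o)
  expect_error(assemble_system(dom, s, b, c(0, 0, 0), o), "under-resolved")
})

test_that("the normal-stress opening condition reproduces the pressure one", {
  # for parallel outflow the two conditions coincide; conductances agree
  ch <- build_channel(1, 4)
  s1 <- solve_stokes(ch, c(0, -1), solver_options(poly_degree = 10))
  s2 <- solve_stokes(ch, c(0, -1), solver_options(poly_degree = 10,
                                                  normal_stress = TRUE))
  p1 <- bifstokes:::fields_at(s1, 0.2 + 0.1i)
  p2 <- bifstokes:::fields_at(s2, 0.2 + 0.1i)
  expect_equal(p1$U, p2$U, tolerance = 1e-6)
  expect_equal(p1$P, p2$P, tolerance = 1e-6)
})
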