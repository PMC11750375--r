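test_that("reference bifurcation builds with the documented openings and corners", {
  dom <- build_bifurcation(ref_spec())
  expect_s3_class(dom, "bif_domain")
  expect_length(dom$corners, 3)
  op0 <- dom$openings[[1]]
  expect_equal(op0$lo, complex(real = -2, imaginary = -0.5))
  expect_equal(op0$hi, complex(real = -2, imaginary = 0.5))
  expect_equal(dom$openings[[2]]$width, 0.9)
  expect_equal(dom$openings[[3]]$width, 0.8)
  # child openings sit at centreline distance L, perpendicular to the axis
  for (k in 2:3) {
    op <- dom$openings[[k]]
    expect_equal(Mod(op$centre), 2, tolerance = 1e-12)
    expect_lt(abs(Re(Conj(op$outward) * (op$hi - op$lo))), 1e-12)
  }
})

test_that("mirror-symmetric spec yields a domain symmetric about the X axis", {
  dom <- build_bifurcation(sym_spec())
  # reflecting child-1's boundary arc gives child-2's (reverse orientation)
  up <- dom$arcs$upper$pts
  lo <- dom$arcs$lower$pts
  expect_lt(max(Mod(Conj(rev(lo)) - up)), 1e-12)
  expect_lt(Mod(Conj(dom$corners[[1]]$z) - dom$corners[[3]]$z), 1e-12)
  expect_lt(abs(Im(dom$corners[[2]]$z)), 1e-12)
})

test_that("swapping (D1, alpha) and (D2, beta) reflects the domain", {
  a <- build_bifurcation(bif_spec(0.7, 0.95, pi / 3, pi / 4))
  b <- build_bifurcation(bif_spec(0.95, 0.7, pi / 4, pi / 3))
  expect_lt(Mod(Conj(a$openings[[2]]$centre) - b$openings[[3]]$centre), 1e-12)
  expect_lt(Mod(Conj(a$corners[[2]]$z) - b$corners[[2]]$z), 1e-12)
})

test_that("degenerate angles are supported (collinear child)", {
  # child 2 collinear with the parent: the lower wall is straight, no corner
  dom <- build_bifurcation(bif_spec(1, 1, pi / 2, 0, 2))
  expect_length(dom$corners, 2)
  expect_null(dom$arcs$lower$corner)
  expect_true(validate_spec(bif_spec(1, 1, pi / 2, 0, 2))$ok)
})

test_that("validate_spec rejects overlapping children and accepts known-good cases", {
  bad <- validate_spec(bif_spec(1, 1, pi / 8, pi / 8))
  expect_false(bad$ok)
  expect_true(any(grepl("overlap", bad$violations)))
  expect_true(validate_spec(bif_spec(1, 1, pi / 4, pi / 4))$ok)
  expect_true(validate_spec(bif_spec(0.5, 1, pi / 4, pi / 4))$ok)
  expect_false(validate_spec(bif_spec(1.4, 1, pi / 4, pi / 4))$ok)
  expect_false(validate_spec(bif_spec(1, 1, -0.1, pi / 2))$ok)
  # particle sticking out of the domain
  expect_false(validate_spec(bif_spec(1, 1, pi / 4, pi / 4,
                                      particle = list(X0 = 0, Y0 = 0.45,
                                                      R = 0.2)))$ok)
  # build_bifurcation errors with a structured message on invalid geometry
  expect_error(build_bifurcation(bif_spec(1, 1, pi / 8, pi / 8)), "overlap")
})

test_that("boundary samples lie on the boundary with unit frames and positive weights", {
  dom <- build_bifurcation(ref_spec())
  s <- sample_boundary(dom, fast_options())
  expect_true(all(s$weight > 0))
  expect_equal(Mod(s$tangent), rep(1, nrow(s)), tolerance = 1e-12)
  expect_equal(Mod(s$normal), rep(1, nrow(s)), tolerance = 1e-12)
  d <- bifstokes:::polygon_distance(dom$dense_polygon, s$zeta)
  expect_lt(max(d), 1e-12)
  # all five tags present on a particle domain
  domp <- build_bifurcation(fixture_catalog()$particle)
  sp <- sample_boundary(domp, fast_options())
  expect_setequal(unique(sp$bc_tag),
                  c("wall", "opening0", "opening1", "opening2", "particle"))
  onp <- Mod(sp$zeta[sp$bc_tag == "particle"] - domp$particle$centre)
  expect_equal(onp, rep(0.2, length(onp)), tolerance = 1e-12)
})

test_that("region areas are positive, symmetric and add up to the fluid area", {
  dom <- build_bifurcation(sym_spec())
  ar <- region_areas(dom)
  expect_true(all(ar$area > 0))
  expect_equal(ar$area[ar$region == "child1"], ar$area[ar$region == "child2"],
               tolerance = 1e-10)
  total <- bifstokes:::polygon_area(dom$dense_polygon)
  expect_equal(sum(ar$area), total, tolerance = 1e-6 * total)
})

test_that("a central particle removes exactly its own area", {
  dom0 <- build_bifurcation(sym_spec())
  domp <- build_bifurcation(bif_spec(1, 1, pi / 4, pi / 4,
                                     particle = list(X0 = 0, Y0 = 0, R = 0.2)))
  a0 <- sum(region_areas(dom0)$area)
  ap <- sum(region_areas(domp)$area)
  # the 720-gon approximation of the circle bounds the residual error
  expect_equal(a0 - ap, pi * 0.2^2, tolerance = 1e-4)
})

test_that("region areas agree with a Monte-Carlo point-in-polygon estimate", {
  dom <- build_bifurcation(sym_spec())
  ar <- region_areas(dom)
  set.seed(42)
  n <- 1e5
  bb <- dom$dense_polygon
  xr <- range(Re(bb)); yr <- range(Im(bb))
  z <- complex(real = runif(n, xr[1], xr[2]), imaginary = runif(n, yr[1], yr[2]))
  box <- diff(xr) * diff(yr)
  inside <- point_in_domain(dom, z)
  phat <- mean(inside)
  est <- box * phat
  se <- box * sqrt(phat * (1 - phat) / n)
  expect_lt(abs(est - sum(ar$area)), 3 * se)
})

test_that("dimensional scales validate and expose derived velocity/pressure scales", {
  sc <- dimensional_scales(d = 1e-5, q = 2e-9, mu = 1.2e-3)
  expect_equal(sc$velocity, 2e-4)
  expect_equal(sc$pressure, 1.2e-3 * 2e-9 / 1e-10)
  expect_error(dimensional_scales(-1, 1, 1))
})
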