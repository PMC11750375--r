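test_that("fluxes conserve mass and match the quadrature cross-check", {
  dom <- build_bifurcation(ref_spec())
  sol <- solve_stokes(dom, c(0, -1, -0.5), fast_options())
  fl <- channel_fluxes(sol)
  expect_equal(fl$flux[1], fl$flux[2] + fl$flux[3], tolerance = 1e-6)
  expect_equal(fl$flux, fl$flux_quadrature, tolerance = 1e-7)
  expect_gt(fl$flux[1], 0)
})

test_that("plane Poiseuille carries flux 2/3 at unit centre velocity", {
  # U = 1 - 4Y^2 on width 1: closed-form integral 2/3
  ch <- build_channel(1, 4)
  sol <- solve_stokes(ch, c(16, -16), solver_options(poly_degree = 10))
  fl <- bifstokes:::opening_fluxes(sol)
  expect_equal(fl$flux_out[2], 2 / 3, tolerance = 1e-8)
  expect_equal(-fl$flux_out[1], 2 / 3, tolerance = 1e-8)
})

test_that("the conductance triple recovery round-trips exactly", {
  triple <- c(G0 = 3, G1 = 2, G2 = 1)
  G <- bifstokes:::triple_to_tensor(triple)
  # synthetic fluxes for the two canonical pressure vectors
  q1 <- G %*% c(1, 0); q2 <- G %*% c(0, 1)
  qin1 <- sum(q1); qin2 <- sum(q2)  # inlet influx equals total outflux
  r <- qin2 / qin1
  Pc1 <- q2[1] / (q2[1] - r * q1[1])
  Pc2 <- r * Pc1
  rec <- c(G0 = -qin1 / Pc1, G1 = q2[1] / Pc2, G2 = q1[2] / Pc1)
  expect_equal(rec, triple, tolerance = 1e-12)
  # tensor-based fallback agrees too
  expect_equal(unname(bifstokes:::tensor_to_triple(G)), unname(triple),
               tolerance = 1e-12)
})

test_that("Poiseuille reference matches the 2D channel law", {
  pr <- poiseuille_reference(D1 = 1, D2 = 1, L = 2)
  expect_equal(unname(pr$triple), rep(1 / 24, 3))
  pr <- poiseuille_reference(ref_spec())
  expect_equal(round(unname(pr$triple), 4), c(0.0417, 0.0304, 0.0213))
  # even partition of the symmetric idealised tensor
  q <- poiseuille_reference(D1 = 1, D2 = 1, L = 2)$tensor %*% c(1, 1)
  expect_equal(q[1], q[2])
})

test_that("a symmetric bifurcation has equal child conductances and reciprocity", {
  cs <- sym_conductances()
  expect_equal(cs$triple[["G1"]], cs$triple[["G2"]], tolerance = 1e-6)
  expect_lt(abs(cs$tensor[1, 2] - cs$tensor[2, 1]),
            1e-5 * abs(cs$tensor[1, 2]))
  expect_true(all(cs$triple > 0))
})

test_that("swapping (D1, alpha) with (D2, beta) exchanges child conductances", {
  a <- conductance_tensor(build_bifurcation(bif_spec(0.8, 1, pi / 3, pi / 4)),
                          solver_options())
  b <- conductance_tensor(build_bifurcation(bif_spec(1, 0.8, pi / 4, pi / 3)),
                          solver_options())
  expect_equal(a$triple[["G1"]], b$triple[["G2"]], tolerance = 1e-6)
  expect_equal(a$triple[["G2"]], b$triple[["G1"]], tolerance = 1e-6)
  expect_equal(a$triple[["G0"]], b$triple[["G0"]], tolerance = 1e-6)
})

test_that("area-preserved conductances follow the scaled-width law", {
  dom <- build_bifurcation(fixture_catalog()$curved)
  ref <- area_preserved_reference(dom)
  ar <- region_areas(dom)
  expect_equal(unname(ref$triple), (ar$area / 2)^3 / 24, tolerance = 1e-12)
  # particle occupancy reduces the area-preserved conductances
  domp <- build_bifurcation(fixture_catalog()$particle)
  dom0 <- build_bifurcation(sym_spec())
  expect_true(all(area_preserved_reference(domp)$triple <
                    area_preserved_reference(dom0)$triple))
})

test_that("relative differences are zero at equality and tidy output is consistent", {
  pr <- poiseuille_reference(D1 = 0.9, D2 = 0.8, L = 2)
  rd <- relative_differences(pr$triple, pr)
  expect_equal(rd$rel_pct, c(0, 0, 0))
  cs <- ref_conductances()
  td <- tidy(cs, reference = poiseuille_reference(ref_spec()))
  expect_equal(td$G, unname(cs$triple))
  expect_equal(td$rel_pct,
               relative_differences(cs, poiseuille_reference(ref_spec()))$rel_pct)
  gl <- glance(cs)
  expect_equal(gl$G0, cs$triple[["G0"]])
})

test_that("conductance_sweep returns tidy rows and flags invalid geometries", {
  grid <- tibble::tibble(D1 = c(1, 1), D2 = c(1, 1),
                         alpha = c(pi / 4, pi / 8), beta = c(pi / 4, pi / 8))
  sw <- conductance_sweep(grid, fast_options())
  expect_equal(nrow(sw), 2)
  expect_true(sw$valid[1])
  expect_false(sw$valid[2])
  expect_match(sw$reason[2], "overlap")
  expect_equal(sw$G1[1], sw$G2[1], tolerance = 1e-4)
  expect_true(is.na(sw$G1[2]))
})

test_that("murray_2d marks the optimal-width curve", {
  expect_true(murray_2d(0.6, 0.8))
  expect_false(murray_2d(0.9, 0.9))
})
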