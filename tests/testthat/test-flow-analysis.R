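test_that("a symmetric flow splits evenly at zero pressure difference", {
  fl <- constrained_flow(sym_conductances(), 0)
  expect_equal(unname(fl$partition), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(fl$partition), 1, tolerance = 1e-6)
  expect_equal(unname(diff(rev(fl$pressures))), 0)
})

test_that("superposed constrained flow matches a direct re-solve", {
  cs <- sym_conductances()
  fl <- constrained_flow(cs, 10)
  expect_equal(unname(fl$pressures[1] - fl$pressures[2]), 10)
  expect_equal(sum(fl$partition), 1, tolerance = 1e-6)
  direct <- solve_stokes(cs$system$domain,
                         c(0, fl$pressures[1], fl$pressures[2]),
                         system = cs$system)
  pts <- complex(real = c(-1, 0.3, 1.2), imaginary = c(0.2, 0, -0.4))
  fs <- evaluate_fields(fl$solution, pts)
  fd <- evaluate_fields(direct, pts)
  for (col in c("U", "V", "P", "Psi"))
    expect_equal(fs[[col]], fd[[col]], tolerance = 1e-8)
})

test_that("flow partition is affine and strictly decreasing in delta_p", {
  cs <- sym_conductances()
  dps <- seq(-5, 15, by = 5)
  q1 <- sapply(dps, function(d) constrained_flow(cs, d)$partition[["Q1"]])
  expect_true(all(diff(q1) < 0))
  # affine: second differences vanish
  d2 <- diff(q1, differences = 2)
  expect_lt(max(abs(d2)), 1e-8)
})

test_that("the reversal threshold matches its bracketed root and ordering", {
  th <- reversal_threshold(sym_conductances())
  expect_lt(th$bracket_check, 1e-8)
  expect_lt(th$stokes, th$poiseuille)
  # crossing the threshold flips the sign of Q1
  below <- constrained_flow(sym_conductances(), th$stokes - 0.5)
  above <- constrained_flow(sym_conductances(), th$stokes + 0.5)
  expect_gt(below$partition[["Q1"]], 0)
  expect_lt(above$partition[["Q1"]], 0)
})

test_that("streamlines hold their stream-function level", {
  cs <- sym_conductances()
  fl <- constrained_flow(cs, 6)
  sl <- trace_streamline(fl$solution, complex(real = -1.9, imaginary = 0.17))
  expect_lt(sl$psi_drift, 1e-6)
  expect_gt(length(sl$vertices), 10)
})

test_that("the symmetric centre streamline follows the axis to the junction", {
  fl <- constrained_flow(sym_conductances(), 0)
  sl <- trace_streamline(fl$solution, complex(real = -1.95, imaginary = 0))
  upstream <- Re(sl$vertices) < 0.5
  expect_lt(max(abs(Im(sl$vertices[upstream]))), 1e-7)
  # it reaches the junction region (the inter-child corner is at Re ~ 0.707)
  expect_gt(max(Re(sl$vertices)), 0.5)
})

test_that("the forward separatrix starts at the flux-split ordinate", {
  cs <- sym_conductances()
  fl <- constrained_flow(cs, 0)
  sep <- separatrix(fl)
  expect_lt(abs(sep$inlet_ordinate), 1e-6)
  fl2 <- constrained_flow(cs, 10)
  sep2 <- separatrix(fl2)
  # flux below the split ordinate equals Q2 (quadrature cross-check)
  gl <- pracma::gaussLegendre(96, -0.5, sep2$inlet_ordinate)
  u <- bifstokes:::fields_at(fl2$solution,
                             complex(real = -2 + 1e-9, imaginary = gl$x))$U
  expect_equal(sum(gl$w * u), fl2$partition[["Q2"]], tolerance = 1e-4)
  # and the separatrix ends near the inter-child corner
  endp <- sep2$streamline$vertices[length(sep2$streamline$vertices)]
  corner <- cs$system$domain$corners[[2]]$z
  expect_lt(Mod(endp - corner), 0.05)
})

test_that("the reversed-flow separatrix is anchored at the wall level", {
  cs <- sym_conductances()
  fl <- constrained_flow(cs, 30)
  expect_lt(fl$partition[["Q1"]], 0)
  sep <- separatrix(fl)
  expect_true(is.na(sep$inlet_ordinate))
  # its level equals the upper-parent-wall stream function (inlet flux 1
  # above the bottom wall)
  sol <- fl$solution
  psib <- bifstokes:::fields_at(sol, cs$system$domain$openings[[1]]$lo)$Psi
  expect_equal(sep$streamline$psi_level, psib + 1, tolerance = 1e-6)
})

test_that("separatrix refuses the degenerate threshold case", {
  cs <- sym_conductances()
  th <- reversal_threshold(cs)
  fl <- constrained_flow(cs, th$stokes)
  expect_error(separatrix(fl), "threshold")
})
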