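test_that("pressure-area law round-trips to machine precision", {
  A0 <- pi * 0.3^2
  f <- (4 / 3) * wall_stiffness(0.3, 2.5e6, -15, 6.4e4)
  p <- seq(-2e4, 8e4, length.out = 50)
  expect_equal(pressure_from_area(area_from_pressure(p, A0, f), A0, f), p,
               tolerance = 1e-12)
  A <- seq(0.5 * A0, 2 * A0, length.out = 50)
  expect_equal(area_from_pressure(pressure_from_area(A, A0, f), A0, f), A,
               tolerance = 1e-12)
})

test_that("flux-form pressure term is consistent for tapering vessels", {
  # finite-difference check that dB/dx - S_geo == (A/rho) dp/dx at frozen A
  hp <- hemo_params()
  geo <- vasctrees:::.vessel_geometry(c(0.5, 0.3), 4, 101, hp)
  g <- geo$n
  A <- 1.3 * g$A0[51]                      # constant A across the stencil
  i <- 50:52
  B <- g$f[i] * A^1.5 / (3 * hp$rho * sqrt(g$A0[i]))
  p <- pressure_from_area(A, g$A0[i], g$f[i])
  dx <- geo$dx
  dBdx <- (B[3] - B[1]) / (2 * dx)
  dpdx <- (p[3] - p[1]) / (2 * dx)
  gi <- lapply(g, function(z) z[51])
  S_geo <- vasctrees:::.source2(A, 0, gi, hp, 1)  # q = 0: pure geometric part
  expect_equal(dBdx - S_geo, (A / hp$rho) * dpdx, tolerance = 1e-4 * abs(dpdx))
})

test_that("zero inflow leaves the system exactly at rest", {
  net <- make_synthetic_network(levels = 2, root_radius = 0.3, seed = 1)
  tr <- build_labeled_tree(net$centerlines)
  wf <- make_inflow_waveform(0.85, 0, shape = "constant")
  hp <- hemo_params(cycles = 2, grid = 10, p0 = 0)
  sol <- solve_large_vessels(tr, wf, hp, outflow = "resistance",
                             outflow_R = c(R.1 = 500, R.2 = 500))
  expect_lt(max(abs(sol$vessels$R$q)), 1e-10)
  expect_lt(max(abs(sol$vessels$R$p)), 1e-10)
  expect_lt(periodicity_check(sol)[1], 1e-6)
})

test_that("steady flow through one vessel obeys the resistive outlet", {
  net <- make_synthetic_network(levels = 1, root_radius = 0.3, n_nodes = 30,
                                seed = 1)
  tr <- build_labeled_tree(net$centerlines)
  q0 <- 8
  wf <- make_inflow_waveform(0.85, q0 * 0.85, shape = "constant")
  hp <- hemo_params(cycles = 6, grid = 10, p0 = 0)
  Rout <- 4000
  sol <- solve_large_vessels(tr, wf, hp, outflow = "resistance",
                             outflow_R = c(R = Rout), radii = list(R = 0.25))
  # outlet boundary condition satisfied: p(L) = R * q(L)
  pL <- sol$vessels$R$p[10, ] * 1333.22
  qL <- sol$vessels$R$q[10, ]
  expect_lt(max(abs(pL - Rout * qL)) / max(abs(pL)), 1e-8)
  # flow settles to the prescribed inflow all along the vessel
  expect_equal(mean(sol$vessels$R$q[5, ]), q0, tolerance = 1e-3)
  # pressure drops monotonically downstream
  pmean <- rowMeans(sol$vessels$R$p)
  expect_true(all(diff(pmean) < 0))
})

test_that("junction coupling conserves flow and pressure continuity", {
  net <- make_synthetic_network(levels = 2, root_radius = 0.3, n_nodes = 30,
                                seed = 2)
  tr <- build_labeled_tree(net$centerlines)
  wf <- make_inflow_waveform(0.85, 10 * 0.85 * 0.35)
  hp <- hemo_params(cycles = 4, grid = 10, p0 = 0)
  sol <- solve_large_vessels(tr, wf, hp, outflow = "resistance",
                             outflow_R = c(R.1 = 3000, R.2 = 3000))
  qp <- sol$vessels$R$q[10, ]
  qd <- sol$vessels$R.1$q[1, ] + sol$vessels$R.2$q[1, ]
  expect_lt(max(abs(qp - qd)) / max(abs(qp)), 1e-10)
  pp <- sol$vessels$R$p[10, ]
  expect_lt(max(abs(pp - sol$vessels$R.1$p[1, ])), 1e-9)
})

test_that("periodicity decreases monotonically over later cycles", {
  net <- make_synthetic_network(levels = 1, root_radius = 0.3, n_nodes = 30,
                                seed = 1)
  tr <- build_labeled_tree(net$centerlines)
  wf <- make_inflow_waveform(0.85, 10 * 0.85 * 0.3)
  hp <- hemo_params(cycles = 8, grid = 10, p0 = 0, period_tol = 1e-12)
  sol <- solve_large_vessels(tr, wf, hp, outflow = "resistance",
                             outflow_R = c(R = 4000), radii = list(R = 0.3))
  tr_p <- periodicity_check(sol)
  late <- tr_p[max(1, length(tr_p) - 4):length(tr_p)]
  expect_true(all(diff(late) < 0))
})
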