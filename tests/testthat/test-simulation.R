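# Time integration, shift experiments, basin membership.

test_that("equilibria and invariant lines are respected by the integrator", {
  p <- params_at(k = 20, nu = 0.9)
  eq <- interior_equilibrium(p)
  tr <- integrate_model(p, eq$state, c(0, 100))
  expect_lt(max(abs(tr$f - eq$state[[1]])), 1e-6)
  expect_lt(max(abs(tr$x - eq$state[[2]])), 1e-6)
  # x = 0 and x = 1 stay put while f relaxes
  for (x0 in c(0, 1)) {
    tr <- integrate_model(params_at(k = 10, nu = 0.5), c(0.3, x0),
                          c(0, 20))
    expect_lt(max(abs(tr$x - x0)), 1e-9)
  }
})

test_that("simulated attractor amplitude matches the continued stable cycle", {
  p <- params_at(k = 10, nu = 0.5)
  cyc <- cycle_census(mosaic, p, n_scan = 25)[[1]]
  tr <- integrate_model(p, c(0.45, 0.6), c(0, 400), n_out = 4001)
  tail <- tr[tr$t > 360, ]
  amp_sim <- max(tail$f) - min(tail$f)
  expect_equal(amp_sim, cyc$amplitude, tolerance = 1e-3)
})

test_that("parameter steps across the supercritical window shift smoothly", {
  p <- params_at(k = 13, nu = 2)
  eq <- interior_equilibrium(p)
  res <- shift_experiment(p, eq$state + c(0.01, 0.01),
                          shift_protocol(param = "k", new_value = 11))
  expect_identical(res$classification, "smooth")
  # the quasi-static amplitude path grows without a jump
  expect_true(all(diff(res$amplitude_path) < 0.2))
  expect_gt(res$amp_post, 0.05)
})

test_that("state kicks across the separatrix are catastrophic; null kicks are not", {
  p <- params_at(k = 30, nu = 0.2)
  eq <- interior_equilibrium(p)
  expect_identical(eq$stability, "stable")
  res <- shift_experiment(p, eq$state + c(0.001, 0.001),
                          shift_protocol(delta = c(0.3, 0.2)))
  expect_identical(res$classification, "catastrophic")
  expect_gt(res$amp_post, 0.5)
  expect_lt(res$amp_pre, 1e-3)
  res0 <- shift_experiment(p, eq$state,
                           shift_protocol(delta = c(0, 0)))
  expect_identical(res0$classification, "smooth")
  # classification is robust to halving the integrator tolerances
  res_t <- shift_experiment(p, eq$state + c(0.001, 0.001),
                            shift_protocol(delta = c(0.3, 0.2)),
                            rtol = 5e-11, atol = 5e-13)
  expect_identical(res_t$classification, "catastrophic")
})

test_that("basin membership is decided by the unstable cycle separatrix", {
  reg <- classify_regime(6, 0.2)
  expect_identical(reg$label, "III")
  p <- params_at(k = 6, nu = 0.2)
  eq <- reg$equilibrium
  unstable <- reg$cycles[[1]]
  stable <- reg$cycles[[2]]
  expect_identical(
    basin_membership(p, eq$state + c(0.005, 0.005), eq, stable),
    "equilibrium")
  expect_identical(
    basin_membership(p, c(0.05, 0.5), eq, stable), "cycle")
  # points just inside / outside the separatrix mesh diverge
  i <- which.max(unstable$mesh$f)
  pt <- as.numeric(unstable$mesh[i, c("f", "x")])
  ctr <- eq$state
  inside <- ctr + 0.97 * (pt - ctr)
  outside <- ctr + 1.03 * (pt - ctr)
  expect_identical(basin_membership(p, inside, eq, stable),
                   "equilibrium")
  expect_identical(basin_membership(p, outside, eq, stable), "cycle")
})
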