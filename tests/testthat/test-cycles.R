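# Return-map cycle machinery, validated on the normal forms (exact
# closed forms) and on the study model.

test_that("return-map cycles on the Hopf normal form are exact", {
  sys <- hopf_normal_form(1, -1)
  p <- list(mu = 0.04, omega = 1, a = -1)
  cyc <- find_cycle(sys, p, a0 = 0.35)
  expect_s3_class(cyc, "limit_cycle")
  expect_equal(cyc$a, 0.2, tolerance = 1e-7)
  expect_equal(cyc$period, 2 * pi, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(cyc$stability, "stable")
  # nontrivial multiplier of the radial equation: exp(-2 mu T)
  expect_equal(Re(cyc$multipliers[2]), exp(-2 * 0.04 * 2 * pi),
               tolerance = 1e-6)
})

test_that("cycles seeded from Hopf points have normal-form asymptotics", {
  sys <- hopf_normal_form(1, -1)
  p0 <- list(mu = -0.005, omega = 1, a = -1)
  br <- continue_branch(sys, p0, c(0, 0), "mu", c(-0.02, 0.02),
                        step = 0.005, max_step = 0.01)
  hp <- detect_hopf(br)[[1]]
  cyc <- initial_cycle_from_hopf(hp, sys, offset = 0.01)
  expect_equal(cyc$params$mu, 0.01, tolerance = 1e-6)
  expect_equal(cyc$a, 0.1, tolerance = 1e-3)
  expect_equal(cyc$period, 2 * pi, tolerance = 1e-4, ignore_attr = TRUE)

  # model, supercritical side: small stable cycle just past the Hopf
  hps <- hopf_points_on_slice(param_set(k = 11, nu = 2))
  c_sup <- initial_cycle_from_hopf(hps[[1]], mosaic, offset = 1e-3)
  expect_identical(c_sup$stability, "stable")
  expect_lt(c_sup$amplitude, 0.05)
  # model, subcritical side: small unstable cycle coexisting with the
  # stable equilibrium below the low-k Hopf point
  hps04 <- hopf_points_on_slice(param_set(k = 11, nu = 0.4))
  c_sub <- initial_cycle_from_hopf(hps04[[1]], mosaic, offset = 1e-3)
  expect_identical(c_sub$stability, "unstable")
  expect_lt(c_sub$params$k, hps04[[1]]$params$k)
  eq <- interior_equilibrium(c_sub$params)
  expect_identical(eq$stability, "stable")
  expect_true(cycle_encloses(c_sub, eq$state))
})

test_that("Floquet multipliers satisfy the autonomous-flow identities", {
  p <- params_at(k = 10, nu = 0.5)  # regime with a stable cycle
  cycles <- cycle_census(mosaic, p, n_scan = 25)
  expect_length(cycles, 1)
  cyc <- cycles[[1]]
  expect_identical(cyc$stability, "stable")
  fl <- floquet_multipliers(cyc)
  expect_lt(fl$trivial_error, 1e-4)
  expect_lt(abs(Re(fl$multipliers[2])), 1)
  # Liouville: product of multipliers = exp(integral of trace)
  expect_equal(Re(fl$product), fl$liouville_product, tolerance = 1e-6)
})

test_that("periods are converged with respect to the discretization", {
  p <- params_at(k = 10, nu = 0.5)
  sec <- mosaic$section(p)
  c_tight <- find_cycle(mosaic, p, sec, 0.3, rtol = 1e-10, atol = 1e-12)
  c_loose <- find_cycle(mosaic, p, sec, 0.3, rtol = 1e-8, atol = 1e-10)
  expect_lt(abs(c_tight$period - c_loose$period) / c_tight$period, 1e-6)
  expect_lt(c_tight$closure_error, 1e-7)
})

test_that("fold of cycles on the Bautin normal form sits at beta1 = -beta2^2/4", {
  sys <- bautin_normal_form()
  p <- list(beta1 = -0.2, beta2 = 1)
  sec <- sys$section(p)
  inner <- find_cycle(sys, p, sec, 0.5)
  outer <- find_cycle(sys, p, sec, 0.9)
  expect_equal(inner$a, sqrt((1 - sqrt(0.2)) / 2), tolerance = 1e-8)
  expect_equal(outer$a, sqrt((1 + sqrt(0.2)) / 2), tolerance = 1e-8)
  expect_identical(inner$stability, "unstable")
  expect_identical(outer$stability, "stable")

  cb <- continue_cycle_branch(sys, inner, "beta1", c(-0.5, 0.1),
                              step = 0.02, max_step = 0.1)
  lpcs <- detect_lpc(cb)
  expect_length(lpcs, 1)
  expect_equal(lpcs[[1]]$param, -0.25, tolerance = 1e-6)
  expect_equal(lpcs[[1]]$a, sqrt(0.5), tolerance = 1e-6)
  expect_lt(abs(lpcs[[1]]$multiplier - 1), 1e-3)
  # stability flips across the fold
  pts <- cb$points
  i_fold <- which.min(abs(pts$param - (-0.25)))
  expect_true(any(pts$stability[seq_len(i_fold)] == "unstable"))
  expect_true(any(pts$stability[seq(i_fold, nrow(pts))] == "stable"))
})
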