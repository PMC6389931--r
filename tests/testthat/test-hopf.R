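# Hopf detection, first Lyapunov coefficient, Bautin location.

test_that("the closed-form Hopf locus is the zero-trace set of the analytic Jacobian", {
  p <- param_set()
  for (k in seq(6, 16, by = 0.5)) {
    nu <- hopf_locus_nu(k, p)
    pp <- param_set(k = k, nu = nu)
    eq <- interior_equilibrium(pp)
    if (is.null(eq)) next
    expect_lt(abs(sum(diag(eq$jacobian))), 1e-12)
    expect_gt(det(eq$jacobian), 0)
  }
  expect_equal(hopf_locus_nu(11, p), 11 / 4, tolerance = 1e-12)
  expect_error(hopf_locus_nu(5, param_set(m = 2)), "default")
})

test_that("eigenvalue-based Hopf detection agrees with the closed-form locus", {
  p <- params_at(k = 10, nu = 0.2)
  br <- continue_branch(mosaic, p, interior_equilibrium(p)$state, "k",
                        c(5, 20), step = 0.05, max_step = 0.2)
  hps <- detect_hopf(br)
  expect_length(hps, 2)
  for (h in hps) {
    # the detected point lies on nu_H(k) and has pure-imaginary pair
    expect_equal(hopf_locus_nu(h$params$k, p), 0.2, tolerance = 1e-6)
    eq <- interior_equilibrium(h$params)
    ev <- eq$eigenvalues
    expect_lt(max(abs(Re(ev))), 1e-8)
    # omega = 2 sqrt(h s x (1 - x)), cross-checked against eigen()
    x <- eq$state[["x"]]
    expect_equal(h$omega, 2 * sqrt(p$h * p$s * x * (1 - x)),
                 tolerance = 1e-6)
    expect_equal(h$omega, abs(Im(ev[1])), tolerance = 1e-6)
  }
  # above the bell's peak no trace zero exists
  peak <- stats::optimize(function(k) -hopf_locus_nu(k, p), c(5, 20))
  expect_lt(-peak$objective, 3)
  p3 <- params_at(k = 10, nu = 3)
  br3 <- continue_branch(mosaic, p3, interior_equilibrium(p3)$state,
                         "k", c(5, 20), step = 0.05, max_step = 0.2)
  expect_length(detect_hopf(br3), 0)
})

test_that("first Lyapunov coefficient has the defining normal-form signs", {
  sup <- hopf_normal_form(1, -1)
  expect_lt(first_lyapunov_coefficient(sup, c(0, 0),
                                       list(mu = 0, omega = 1, a = -1)),
            0)
  sub <- hopf_normal_form(2, +1)
  expect_gt(first_lyapunov_coefficient(sub, c(0, 0),
                                       list(mu = 0, omega = 2, a = 1)),
            0)
  # Bautin normal form: cubic coefficient is beta2
  bz <- bautin_normal_form()
  l1b <- function(b2) as.numeric(
    first_lyapunov_coefficient(bz, c(0, 0), list(beta1 = 0, beta2 = b2)))
  expect_gt(l1b(0.5), 0)
  expect_lt(l1b(-0.5), 0)
  expect_lt(abs(stats::uniroot(l1b, c(-0.5, 0.5), tol = 1e-12)$root),
            1e-10)
  # off the Hopf set the computation refuses to run
  expect_error(
    first_lyapunov_coefficient(mosaic, c(0.5, 0.6), params_at(k = 10, nu = 1)),
    "trace")
})

test_that("model Hopf criticality switches from subcritical to supercritical with nu", {
  crit_at <- function(nu) {
    hps <- hopf_points_on_slice(param_set(k = 11, nu = nu))
    vapply(hps, function(h) h$criticality, character(1))
  }
  expect_identical(crit_at(0.4), c("subcritical", "subcritical"))
  expect_identical(crit_at(1.7), c("subcritical", "subcritical"))
  expect_identical(crit_at(1.82), c("subcritical", "supercritical"))
  expect_identical(crit_at(2.0), c("supercritical", "supercritical"))
})

test_that("find_bautin solves the independent criticality-switch condition", {
  for (b in c(11, 4)) {
    p <- param_set(b = b, k = 5, nu = 1)
    for (side in c("low_k", "high_k")) {
      gh <- find_bautin(p, side)
      expect_s3_class(gh, "bautin_point")
      expect_lt(abs(bautin_condition(gh$k, b)), 1e-6)
      expect_equal(gh$nu, hopf_locus_nu(gh$k, p), tolerance = 1e-10)
      expect_equal(gh$f, 0.5)
      expect_lt(abs(gh$l1_residual), 1e-6)
      if (side == "low_k") expect_lt(gh$k, b) else expect_gt(gh$k, b)
    }
  }
  # the switch point is independent of the recruitment ceiling c
  gh1 <- find_bautin(param_set(c = 0.4, k = 5, nu = 1), "low_k")
  gh2 <- find_bautin(param_set(c = 1, k = 5, nu = 1), "low_k")
  expect_equal(gh1$k, gh2$k, tolerance = 1e-8)
  # no sign change inside a window strictly between the switch points
  expect_message(
    res <- find_bautin(param_set(k = 5, nu = 1), "low_k",
                       k_window = c(10.2, 10.8)),
    "no Bautin point")
  expect_null(res)
})
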