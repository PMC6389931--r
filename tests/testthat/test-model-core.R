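test_that("recruitment switch matches hand evaluations, is monotone and bounded", {
  p <- params_at(k = 10.03)
  expect_equal(recruitment_rate(0.5, p), 1 / (1 + exp(0.97)),
               tolerance = 1e-12)
  # at f = 1/2 the odds ratio f/(1-f) is 1, so k = b cancels the offset
  expect_equal(recruitment_rate(0.5, params_at(k = 11)), 0.5,
               tolerance = 1e-12)
  expect_equal(recruitment_rate(0.5, param_set(k = 11, c = 3)), 1.5,
               tolerance = 1e-12)
  expect_equal(recruitment_rate(0, p), 1 / (1 + exp(11)),
               tolerance = 1e-12)
  # strict growth checked below the saturation zone of the switch (the
  # odds ratio f/(1-f) overflows the exponential for f close to 1)
  grid <- seq(0, 0.8, length.out = 400)
  w <- recruitment_rate(grid, p)
  expect_true(all(diff(w) > 0))
  wide <- recruitment_rate(seq(0, 0.999, length.out = 400), p)
  expect_true(all(wide > 0 & wide <= p$c))
  expect_error(recruitment_rate(1, p), "domain")
  expect_error(recruitment_rate(-0.1, p), "-0.1")
})

test_that("perceived value and human feedback follow their sign conventions", {
  p <- param_set()
  expect_identical(perceived_value(0.5, p), 0)
  expect_identical(perceived_value(0, p), 1)
  expect_equal(perceived_value(0.25, param_set(m = 2)),
               0.75^2 - 0.25, tolerance = 1e-15)
  # u reduces to 1 - 2f under the default gains and exponents
  fs <- seq(0, 1, length.out = 21)
  expect_equal(perceived_value(fs, p), 1 - 2 * fs, tolerance = 1e-15)

  expect_identical(human_feedback(0.5, p), 0)
  expect_identical(human_feedback(1, p), -2)
  expect_equal(human_feedback(0.722, p), 2 * (1 - 1.444),
               tolerance = 1e-12)
  # -J(x) > 0 (reforestation) exactly when the majority prefers forest
  expect_true(-human_feedback(0.6, p) > 0)
  expect_true(-human_feedback(0.4, p) < 0)
})

test_that("coupled rhs vanishes at the printed Bautin state and respects invariant lines", {
  p <- param_set(k = 9.946, nu = 1.906)
  expect_lt(max(abs(mosaic_rhs(c(0.5, 0.722), p))), 5e-3)
  # x = 0 and x = 1 are invariant lines of the opinion dynamics
  for (f in c(0.1, 0.5, 0.8)) {
    expect_identical(mosaic_rhs(c(f, 0), p)[2], 0)
    expect_identical(mosaic_rhs(c(f, 1), p)[2], 0)
  }
  # at the symmetric state the feedback vanishes
  p2 <- params_at(k = 9, nu = 0.7)
  expect_equal(mosaic_rhs(c(0.5, 0.5), p2),
               c(recruitment_rate(0.5, p2) / 4 - p2$nu / 2, 0),
               tolerance = 1e-14)
  # with defaults dx/dt = 0 at interior x only at f = 1/2
  fs <- setdiff(seq(0.05, 0.95, by = 0.05), 0.5)
  expect_true(all(abs(vapply(fs, function(f) mosaic_rhs(c(f, 0.3), p2)[2],
                             numeric(1))) > 0))
})

test_that("the uncoupled forest model is the h = 0 limit", {
  p0 <- param_set(k = 9, nu = 0.4, h = 0)
  expect_identical(forest_only_rhs(0, p0), 0)
  for (f in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(mosaic_rhs(c(f, 0.37), p0)[1], forest_only_rhs(f, p0),
                 tolerance = 1e-15)
  }
  expect_equal(forest_only_rhs(0.5, param_set(k = 11, nu = 0)), 1 / 8,
               tolerance = 1e-12)
})

test_that("analytic derivative tensors agree with finite differences and are symmetric", {
  states <- random_interior_states(100)
  worst <- 0
  for (i in seq_len(nrow(states))) {
    u <- as.numeric(states[i, ])
    p <- param_set(k = 8 + (i %% 7), nu = 0.3 + 0.1 * (i %% 5))
    d <- mosaic_derivatives(u, p)
    Jfd <- fd_jacobian(function(s) mosaic_rhs(s, p), u)
    worst <- max(worst, max(abs(d$jacobian - Jfd) /
                              pmax(abs(Jfd), 1)))
  }
  expect_lt(worst, 1e-5)

  # second/third forms are symmetric under argument permutation
  p <- param_set(k = 9, nu = 0.6, r = 1.3, q = 0.8, m = 2, n = 3)
  d <- mosaic_derivatives(c(0.4, 0.3), p)
  set.seed(7)
  for (rep in 1:5) {
    u <- stats::rnorm(2); v <- stats::rnorm(2); w <- stats::rnorm(2)
    expect_equal(bilinear_form(d, u, v), bilinear_form(d, v, u),
                 tolerance = 1e-13)
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))
    base <- trilinear_form(d, u, v, w)
    args <- list(u, v, w)
    for (pm in perms) {
      # tensor entries are permutation-symmetric; summation order leaves
      # only rounding-level differences
      expect_equal(base, trilinear_form(d, args[[pm[1]]], args[[pm[2]]],
                                        args[[pm[3]]]),
                   tolerance = 1e-13)
    }
  }
  # second-order tensor against finite differences of the Jacobian
  Bfd <- (mosaic_derivatives(c(0.4 + 1e-5, 0.3), p)$jacobian -
            mosaic_derivatives(c(0.4 - 1e-5, 0.3), p)$jacobian) / 2e-5
  expect_equal(d$second[, , 1], Bfd, tolerance = 1e-4)

  # generalized u-shape also matches finite differences
  Jfd <- fd_jacobian(function(s) mosaic_rhs(s, p), c(0.4, 0.3))
  expect_equal(d$jacobian, Jfd, tolerance = 1e-6)
})

test_that("the interior Jacobian determinant is 4 h s x (1 - x)", {
  for (x in c(0.2, 0.5, 0.722)) {
    p <- params_at(k = 9.5, nu = 1.2)
    d <- mosaic_derivatives(c(0.5, x), p)
    # u(1/2) = 0 kills the lower-right entry, leaving only the
    # off-diagonal product: the interior family is never a saddle
    expect_identical(d$jacobian[2, 2], 0)
    expect_equal(det(d$jacobian), 4 * p$h * p$s * x * (1 - x),
                 tolerance = 1e-10)
    expect_gt(det(d$jacobian), 0)
  }
})
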