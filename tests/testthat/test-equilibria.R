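test_that("closed-form interior equilibrium matches the printed Bautin states", {
  eq1 <- interior_equilibrium(param_set(k = 9.946, nu = 1.906))
  expect_equal(eq1$state[["f"]], 0.5)
  expect_equal(eq1$state[["x"]], 0.722, tolerance = 1e-3)
  eq2 <- interior_equilibrium(param_set(k = 12.59, nu = 1.768))
  expect_equal(eq2$state[["x"]], 0.669, tolerance = 1e-3)

  # nu = w(1/2)/2 balances the forest budget without any feedback
  p <- params_at(k = 10)
  p$nu <- recruitment_rate(0.5, p) / 2
  expect_equal(interior_equilibrium(p)$state[["x"]], 0.5,
               tolerance = 1e-14)

  # x* outside (0, 1) means no interior equilibrium
  expect_null(interior_equilibrium(params_at(k = 10, nu = 10)))

  # Newton from a nearby guess converges to the same point
  eqN <- newton_equilibrium(mosaic, param_set(k = 9.946, nu = 1.906),
                            c(0.45, 0.7), tol = 1e-10)
  expect_equal(eqN$state, eq1$state, tolerance = 1e-8,
               ignore_attr = TRUE)

  # non-default u has no closed form
  expect_error(interior_equilibrium(param_set(m = 2)), "default")
})

test_that("boundary equilibria come from sign scans of the invariant-line balance", {
  # strong reforestation pressure (h = 2) dominates the bounded
  # regrowth term w f (1-f) <= c/4 on the x = 0 line: no roots there
  eqs <- boundary_equilibria(params_at(k = 10, nu = 0.5))
  expect_false(any(vapply(eqs, function(e) e$type, character(1)) ==
                     "boundary-x0"))

  # without human influence the bare-ground state f = 0 persists
  eqs0 <- boundary_equilibria(param_set(k = 10, nu = 0.5, h = 0))
  f0 <- vapply(eqs0, function(e) e$state[[1]], numeric(1))
  expect_true(any(abs(f0) < 1e-9))

  # root count agrees with an independent dense bisection oracle
  p <- param_set(k = 10, nu = 0.3, h = 0.1)
  for (xb in c(0, 1)) {
    resid <- function(f) {
      recruitment_rate(f, p) * f * (1 - f) - p$nu * f -
        p$h * (1 - 2 * xb)
    }
    grid <- seq(0, 1 - 1e-6, length.out = 3e4)
    v <- resid(grid)
    n_oracle <- sum(v == 0) + sum(v[-1] * v[-length(v)] < 0)
    got <- sum(vapply(boundary_equilibria(p), function(e) e$type,
                      character(1)) ==
                 paste0("boundary-x", ifelse(xb == 0, "0", "1")))
    expect_identical(got, n_oracle)
  }
})

test_that("pseudo-arclength continuation reproduces the interior family", {
  p <- params_at(k = 10, nu = 2)
  br <- continue_branch(mosaic, p, interior_equilibrium(p)$state,
                        "k", c(5, 20), step = 0.05, max_step = 0.2)
  pts <- br$points
  expect_gt(nrow(pts), 50)
  expect_lt(max(pts$residual), 1e-6)
  # the family sits at f = 1/2 and the x-values obey the closed form
  expect_lt(max(abs(pts$f - 0.5)), 1e-8)
  x_exact <- vapply(pts$param, function(k) {
    interior_equilibrium(param_set(k = k, nu = 2))$state[["x"]]
  }, numeric(1))
  expect_lt(max(abs(pts$x - x_exact)), 1e-8)
  # stability flips exactly twice: at the two Hopf points of this slice
  stable <- pts$stability == "stable"
  expect_identical(sum(diff(stable) != 0), 2L)
  # determinant positive all along: instability only via the trace
  dets <- (pts$re_lambda1 * pts$re_lambda2 - pts$im_lambda1 *
             pts$im_lambda2)
  expect_true(all(dets > 0))
  # eigenvalues vary continuously along arclength
  expect_lt(max(abs(diff(pts$re_lambda1))), 0.5)
})

test_that("stability classification matches the phase-portrait regimes", {
  expect_identical(interior_equilibrium(params_at(k = 20, nu = 0.9))$stability,
                   "stable")
  expect_identical(interior_equilibrium(params_at(k = 10, nu = 0.5))$stability,
                   "unstable")
  # eigenvalue product equals the determinant
  eq <- interior_equilibrium(params_at(k = 10, nu = 0.5))
  expect_equal(Re(prod(eq$eigenvalues)), det(eq$jacobian),
               tolerance = 1e-10)
  # on the Hopf locus the real parts sit below the margin: marginal
  p <- params_at(k = 9)
  p$nu <- hopf_locus_nu(9, p)
  expect_identical(interior_equilibrium(p)$stability, "marginal")
})
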