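# Two-parameter structure: Hopf curve, criticality split, regime
# classification and the curve-based map.

test_that("the Hopf curve is supercritical exactly between the Bautin k-values", {
  curve <- trace_hopf_curve(param_set(), c(5, 20))
  pts <- curve$points
  gh1 <- find_bautin(param_set(), "low_k")
  gh2 <- find_bautin(param_set(), "high_k")
  inside <- pts$k > gh1$k + 1e-4 & pts$k < gh2$k - 1e-4
  outside <- pts$k < gh1$k - 1e-4 | pts$k > gh2$k + 1e-4
  expect_true(all(pts$l1[inside] < 0))
  expect_true(all(pts$l1[outside] > 0))
  # the l1 sign change on the sampled curve brackets find_bautin's root
  flips <- which(pts$l1[-1] * pts$l1[-nrow(pts)] < 0)
  ks <- sort(c(pts$k[flips], pts$k[flips + 1]))
  expect_lt(abs(mean(ks[1:2]) - gh1$k), 1e-3)
  expect_lt(abs(mean(ks[3:4]) - gh2$k), 1e-3)
  # the curve passes through the nu = 0.2 Hopf pair of the 1D diagrams
  expect_equal(hopf_locus_nu(7.4398, param_set()), 0.2, tolerance = 1e-3)
  expect_equal(hopf_locus_nu(15.3114, param_set()), 0.2, tolerance = 1e-3)
  # internal consistency: the sampled maximum is an interior peak
  i_max <- which.max(pts$nu)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(pts))
})

test_that("hopf_points_on_slice agrees with branch-based detection", {
  p <- params_at(k = 10, nu = 1.4)
  br <- continue_branch(mosaic, p, interior_equilibrium(p)$state, "k",
                        c(5, 20), step = 0.05, max_step = 0.2)
  from_branch <- vapply(detect_hopf(br), function(h) h$params$k,
                        numeric(1))
  from_locus <- vapply(hopf_points_on_slice(p), function(h) h$params$k,
                       numeric(1))
  expect_equal(from_branch, from_locus, tolerance = 1e-6)
})

test_that("regime classification reproduces the three phase portraits", {
  r1 <- classify_regime(20, 0.9)
  expect_identical(r1$label, "I")
  expect_length(r1$cycles, 0)
  r2 <- classify_regime(10, 0.5)
  expect_identical(r2$label, "II")
  r3 <- classify_regime(6, 0.2)
  expect_identical(r3$label, "III")
  # the unstable cycle is the separatrix: it encloses the equilibrium
  # and is itself enclosed by the stable cycle
  expect_true(cycle_encloses(r3$cycles[[1]], r3$equilibrium$state))
  expect_lt(r3$cycles[[1]]$amplitude, r3$cycles[[2]]$amplitude)
  # points on the Hopf locus are flagged as boundary
  p <- param_set()
  expect_identical(classify_regime(9, hopf_locus_nu(9, p), p)$label,
                   "boundary")
})

test_that("the curve-based regime map matches direct attractor inventories", {
  map <- build_regime_map(param_set(), k_range = c(5, 20),
                          nu_range = c(0.05, 3), nu_seed = 0.4,
                          n_lpc = 8)
  # both LPC curves reach their Bautin end points
  expect_length(map$lpc_curves, 2)
  for (cv in map$lpc_curves) {
    pts <- cv$points
    last <- pts[nrow(pts), ]
    gh <- if (mean(pts$k) < 11) map$bautin$low else map$bautin$high
    expect_lt(sqrt((last$k - gh$k)^2 + (last$nu - gh$nu)^2), 1e-3)
  }
  # classifier vs the Fig. 2 sample points (census-verified above)
  expect_identical(map$classify(20, 0.9), "I")
  expect_identical(map$classify(10, 0.5), "II")
  expect_identical(map$classify(6, 0.2), "III")
  # bistability narrows as nu grows: III-band width at nu = 0.2
  # exceeds the one at nu = 1.4 on the low-k flank
  lpc1 <- map$lpc_curves[[which(vapply(map$lpc_curves, function(cv)
    mean(cv$points$k), numeric(1)) < 11)]]
  k_lpc <- stats::approxfun(lpc1$points$nu, lpc1$points$k, rule = 2)
  k_h1 <- function(nu) stats::uniroot(function(k)
    hopf_locus_nu(k, param_set()) - nu, c(2, 11), tol = 1e-10)$root
  w02 <- k_h1(0.4) - k_lpc(0.4)
  w14 <- k_h1(1.4) - k_lpc(1.4)
  expect_gt(w02, w14)
  expect_gt(w14, 0)
  # no regime-III cell above the larger Bautin nu
  nus <- seq(map$bautin$low$nu + 0.01, 2.9, length.out = 8)
  for (nu in nus) {
    for (k in seq(5.5, 19.5, length.out = 8)) {
      expect_false(map$classify(k, nu) == "III")
    }
  }
})
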