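## Two-parameter analysis in the (k, nu) plane: Hopf and LPC loci,
## Bautin organizing centers, and the partition of the plane into the
## three dynamical regimes
##   I   unique stable equilibrium
##   II  unstable equilibrium + stable cycle
##   III stable equilibrium + unstable cycle + stable cycle.

new_codim1_curve <- function(kind, points, termination = "completed") {
  structure(list(kind = kind, points = points, termination = termination),
            class = "codim1_curve")
}

#' @export
print.codim1_curve <- function(x, ...) {
  cat(sprintf("<codim1_curve %s> %d points (%s)\n", x$kind,
              nrow(x$points), x$termination))
  invisible(x)
}

#' Trace the Hopf locus of the interior equilibrium
#'
#' Samples the closed-form bell curve \eqn{\nu = \nu_H(k)} (see
#' \code{\link{hopf_locus_nu}}), annotating each point with the
#' equilibrium x-coordinate, the angular frequency and the first
#' Lyapunov coefficient. The grid is refined near sign changes of l1 so
#' the criticality split is well resolved.
#'
#' @param p a \code{\link{param_set}}.
#' @param k_range length-2 numeric.
#' @param n grid resolution before refinement.
#' @return a \code{codim1_curve} of kind \code{"hopf"} with columns
#'   k, nu, x, omega, l1.
#' @export
trace_hopf_curve <- function(p = param_set(), k_range = c(5, 20),
                             n = 301) {
  ks <- seq(k_range[1], k_range[2], length.out = n)
  eval_pt <- function(k) {
    l1 <- l1_on_hopf_locus(k, p)
    if (length(l1) == 1 && is.na(l1)) {
      return(c(k = k, nu = hopf_locus_nu(k, p), x = NA, omega = NA,
               l1 = NA))
    }
    nu <- hopf_locus_nu(k, p)
    pp <- p; pp$k <- k; pp$nu <- nu
    eq <- interior_equilibrium(pp)
    c(k = k, nu = nu, x = eq$state[["x"]], omega = attr(l1, "omega"),
      l1 = as.numeric(l1))
  }
  pts <- t(vapply(ks, eval_pt, numeric(5)))
  ## refine near l1 sign changes
  l1v <- pts[, "l1"]
  flips <- which(!is.na(l1v[-1]) & !is.na(l1v[-n]) &
                   l1v[-1] * l1v[-n] < 0)
  for (i in flips) {
    extra <- seq(ks[i], ks[i + 1], length.out = 22)[2:21]
    pts <- rbind(pts, t(vapply(extra, eval_pt, numeric(5))))
  }
  pts <- as.data.frame(pts[order(pts[, "k"]), ])
  rownames(pts) <- NULL
  new_codim1_curve("hopf", pts)
}

#' Hopf points of a k-sweep at fixed nu (closed form)
#'
#' Roots of \eqn{\nu_H(k) = \nu} on the two flanks of the bell, each
#' refined by Brent's method and equipped with its first Lyapunov
#' coefficient. This is the fast closed-form route; it agrees with the
#' eigenvalue-based \code{\link{detect_hopf}} along a continued branch.
#'
#' @param p a \code{\link{param_set}} (its \code{nu} is the slice value).
#' @param k_range search window.
#' @param n_scan bracketing resolution.
#' @return list of \code{hopf_point}s ordered by k (possibly empty).
#' @export
hopf_points_on_slice <- function(p, k_range = c(0.5, 40), n_scan = 400) {
  ks <- seq(k_range[1], k_range[2], length.out = n_scan)
  gap <- hopf_locus_nu(ks, p) - p$nu
  out <- list()
  for (i in which(gap[-1] * gap[-n_scan] < 0)) {
    k_h <- stats::uniroot(function(k) hopf_locus_nu(k, p) - p$nu,
                          c(ks[i], ks[i + 1]), tol = 1e-12)$root
    pp <- p; pp$k <- k_h
    eq <- interior_equilibrium(pp)
    if (is.null(eq)) next
    l1 <- first_lyapunov_coefficient(mosaic_system(), eq$state, pp)
    out[[length(out) + 1]] <-
      new_hopf_point(eq$state, pp, attr(l1, "omega"), as.numeric(l1),
                     param_name = "k")
  }
  out
}

#' Two-parameter continuation of a fold-of-cycles (LPC) curve
#'
#' Steps the second parameter through \code{curve_values} and, at each
#' value, re-solves the exact fold system \{P(a) = a, P'(a) = 1\} in the
#' (ray coordinate, fold parameter) plane, seeded from the previous fold
#' and with the Poincare section re-anchored at the current interior
#' equilibrium. Failed steps are retried at the midpoint of the last
#' gap until the gap is below 1e-5.
#'
#' @param sys an \code{ode_system}.
#' @param seed an \code{lpc_point} (from \code{\link{detect_lpc}}).
#' @param curve_param name of the stepped parameter (e.g. "nu").
#' @param curve_values values of \code{curve_param} to visit, starting
#'   near the seed's value.
#' @param amp_min stop when the fold cycle's f-amplitude drops below
#'   this.
#' @param rtol,atol integrator tolerances.
#' @return a \code{codim1_curve} of kind \code{"lpc"} with columns
#'   nu (or the chosen curve parameter), k (fold parameter), a, period,
#'   amplitude_f, amplitude_x.
#' @export
trace_lpc_curve <- function(sys, seed, curve_param, curve_values,
                            amp_min = 1e-4, rtol = 1e-10, atol = 1e-12) {
  param_name <- seed$param_name
  p <- seed$params
  sec <- seed$cycle$sec
  k_cur <- seed$param
  u_cross <- sec$center + seed$a * sec$direction
  nu_cur <- p[[curve_param]]
  rows <- list()
  termination <- "completed"
  queue <- curve_values
  fails <- 0
  amp_prev <- seed$cycle$amplitude
  while (length(queue) > 0) {
    nu_next <- queue[1]
    pp <- p
    pp[[curve_param]] <- nu_next
    pp[[param_name]] <- k_cur
    sec_i <- tryCatch(sys$section(pp), error = function(e) NULL)
    if (is.null(sec_i)) { termination <- "no section"; break }
    a_guess <- sum(sec_i$direction * (u_cross - sec_i$center))
    sol <- solve_lpc(sys, pp, sec_i, a_guess, k_cur, param_name,
                     rtol = rtol, atol = atol)
    cyc <- NULL
    if (!is.null(sol)) {
      pp[[param_name]] <- sol$alpha
      cyc <- new_limit_cycle(sys, pp, sec_i, sol$a, sol$rm, n_mesh = 60)
      ## a vanishing orbit is the equilibrium on the Hopf locus, which
      ## satisfies the fold equations degenerately -- not a fold; the
      ## genuine fold amplitude varies continuously along the curve, so
      ## an abrupt collapse also flags the spurious solution
      if (cyc$amplitude < max(amp_min, 0.25 * amp_prev)) cyc <- NULL
    }
    if (is.null(cyc)) {
      ## bisect the step
      if (abs(nu_next - nu_cur) < 1e-5 || fails > 60) {
        termination <- if (is.null(sol)) "fold solve failed" else
          "amplitude_vanished"
        break
      }
      queue <- c((nu_cur + nu_next) / 2, queue)
      fails <- fails + 1
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(curve = nu_next, k = sol$alpha, a = sol$a,
                 period = sol$rm$period, amplitude_f = cyc$amplitude,
                 amplitude_x = cyc$amplitude_x)
    nu_cur <- nu_next
    k_cur <- sol$alpha
    amp_prev <- cyc$amplitude
    u_cross <- sec_i$center + sol$a * sec_i$direction
    queue <- queue[-1]
  }
  pts <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(curve = numeric(0), k = numeric(0), a = numeric(0),
               period = numeric(0), amplitude_f = numeric(0),
               amplitude_x = numeric(0))
  names(pts)[1] <- curve_param
  new_codim1_curve("lpc", pts, termination)
}

#' Census of limit cycles crossing the Poincare ray
#'
#' Scans the return-map displacement g(a) = P(a) - a over a ray grid,
#' brackets its sign changes and converges each to a cycle. Used by the
#' regime classifier to assemble the attractor inventory at one
#' parameter point.
#'
#' @param sys an \code{ode_system}.
#' @param p parameter list.
#' @param a_range scan range; default from just outside the equilibrium
#'   to just inside the domain boundary.
#' @param n_scan grid size.
#' @param ... forwarded to \code{\link{find_cycle}} /
#'   \code{return_map} (\code{rtol}, \code{atol}, \code{t_max}).
#' @return list of \code{limit_cycle}s ordered by amplitude.
#' @export
cycle_census <- function(sys, p, a_range = NULL, n_scan = 40, ...) {
  sec <- sys$section(p)
  if (is.null(a_range)) {
    a_hi <- if (sys$name == "mosaic") (1 - sec$center[2]) - 1e-3 else 1.5
    a_range <- c(2e-3, a_hi)
  }
  grid <- seq(a_range[1], a_range[2], length.out = n_scan)
  g <- rep(NA_real_, n_scan)
  for (i in seq_len(n_scan)) {
    rm <- return_map(sys, p, sec, grid[i], ...)
    if (rm$ok) g[i] <- rm$a - grid[i]
  }
  cycles <- list()
  for (i in seq_len(n_scan - 1)) {
    if (is.na(g[i]) || is.na(g[i + 1])) next
    if (g[i] == 0 || sign(g[i]) == sign(g[i + 1])) next
    cyc <- find_cycle(sys, p, sec, (grid[i] + grid[i + 1]) / 2,
                      a_bracket = c(grid[i], grid[i + 1]), n_mesh = 100,
                      ...)
    if (is.null(cyc)) next
    dup <- any(vapply(cycles, function(cc) abs(cc$a - cyc$a) < 1e-5,
                      logical(1)))
    if (!dup) cycles[[length(cycles) + 1]] <- cyc
  }
  cycles[order(vapply(cycles, function(cc) cc$amplitude, numeric(1)))]
}

#' Classify the dynamical regime at one (k, nu) point
#'
#' Assembles the attractor inventory -- interior equilibrium stability
#' plus the cycle census on the Poincare ray -- and maps it to the
#' region labels I (unique stable equilibrium), II (unstable equilibrium
#' surrounded by a stable cycle) and III (stable equilibrium inside an
#' unstable cycle inside a stable cycle). Points closer than
#' \code{boundary_tol} (in nu) to the Hopf locus are labelled
#' \code{"boundary"}; anything else unexpected is \code{"other"}.
#'
#' @param k,nu the parameter point.
#' @param p remaining model constants.
#' @param boundary_tol half-width of the boundary band.
#' @param n_scan census resolution.
#' @param ... forwarded to \code{\link{cycle_census}}.
#' @return list with \code{label}, \code{equilibrium}, \code{cycles}.
#' @examples
#' \donttest{
#' classify_regime(20, 0.9, param_set())$label  # "I"
#' }
#' @export
classify_regime <- function(k, nu, p = param_set(), boundary_tol = 1e-3,
                            n_scan = 40, ...) {
  pp <- p; pp$k <- k; pp$nu <- nu
  sys <- mosaic_system()
  eq <- interior_equilibrium(pp)
  if (is.null(eq)) {
    return(list(label = "other", equilibrium = NULL, cycles = list()))
  }
  if (abs(nu - hopf_locus_nu(k, pp)) < boundary_tol) {
    return(list(label = "boundary", equilibrium = eq, cycles = list()))
  }
  cycles <- cycle_census(sys, pp, n_scan = n_scan, ...)
  stab <- vapply(cycles, function(cc) cc$stability, character(1))
  label <- if (eq$stability == "stable" && length(cycles) == 0) {
    "I"
  } else if (eq$stability == "unstable" && length(cycles) == 1 &&
             stab == "stable") {
    "II"
  } else if (eq$stability == "stable" && length(cycles) == 2 &&
             identical(stab, c("unstable", "stable"))) {
    "III"
  } else {
    "other"
  }
  list(label = label, equilibrium = eq, cycles = cycles)
}

#' Build the regime map of the (k, nu) plane
#'
#' Traces the Hopf locus, locates the two Bautin points, grows the two
#' LPC curves from a seed slice up to their Bautin end points, and wraps
#' everything into a curve-based classifier: II below the Hopf bell,
#' III between an LPC curve and the bell on either flank (below the
#' respective Bautin nu), I elsewhere, with \code{"boundary"} bands of
#' half-width \code{boundary_tol} around all curves.
#'
#' @param p a \code{\link{param_set}}.
#' @param k_range,nu_range the analysed window.
#' @param nu_seed slice at which the LPC seeds are grown from the
#'   low-k Hopf point (needs to be well below both Bautin nu values).
#' @param with_lpc set \code{FALSE} to skip the (expensive) LPC curves;
#'   region III is then not resolved.
#' @param n_lpc number of nu-steps per LPC curve.
#' @param boundary_tol boundary band half-width.
#' @param verify_n if > 0, also classify an n x n grid by the direct
#'   attractor inventory (\code{\link{classify_regime}}) and attach it
#'   as \code{$grid}.
#' @param ... integrator options forwarded to the cycle machinery.
#' @return an object of class \code{regime_map}.
#' @export
build_regime_map <- function(p = param_set(), k_range = c(5, 20),
                             nu_range = c(0.05, 3), nu_seed = 0.2,
                             with_lpc = TRUE, n_lpc = 14,
                             boundary_tol = 1e-3, verify_n = 0, ...) {
  sys <- mosaic_system()
  hopf <- trace_hopf_curve(p, k_range)
  gh_low <- find_bautin(p, "low_k")
  gh_high <- find_bautin(p, "high_k")
  lpc_curves <- list()
  if (with_lpc) {
    pseed <- p; pseed$nu <- nu_seed; pseed$k <- p$b
    hps <- hopf_points_on_slice(pseed, k_range = c(0.2, 50))
    if (length(hps) == 2) {
      c0 <- initial_cycle_from_hopf(hps[[1]], sys, offset = 1e-3, ...)
      cb <- continue_cycle_branch(sys, c0, "k", c(0.2, 50), ...)
      lpcs <- detect_lpc(cb)
      gh_for <- function(l) {
        ## low-k fold pairs with the low-k Bautin point, high with high
        if (l$param < p$b) gh_low else gh_high
      }
      for (l in lpcs) {
        gh <- gh_for(l)
        if (is.null(gh)) next
        ## moderate linear steps first (the fold k moves fast at low nu),
        ## then a geometric approach to the Bautin end point
        dnu <- gh$nu - nu_seed
        lin <- seq(nu_seed + dnu / n_lpc, gh$nu - 0.2 * sign(dnu),
                   length.out = n_lpc)
        vals <- c(lin, gh$nu - 0.2 * sign(dnu) * 2^-(1:10),
                  gh$nu - sign(dnu) * 1e-4)
        up <- trace_lpc_curve(sys, l, "nu", vals)
        ## and downward, so the classifier covers the window below the
        ## seed slice
        pts <- up$points
        if (nu_seed > nu_range[1] + 1e-3) {
          down <- trace_lpc_curve(
            sys, l, "nu",
            seq(nu_seed, nu_range[1], length.out = 5)[-1])
          pts <- rbind(down$points[rev(seq_len(nrow(down$points))), ],
                       pts)
        }
        rownames(pts) <- NULL
        lpc_curves[[length(lpc_curves) + 1]] <-
          new_codim1_curve("lpc", pts, up$termination)
      }
    }
  }
  ## interpolators for the classifier
  lpc_fun <- lapply(lpc_curves, function(cv) {
    pts <- cv$points
    if (nrow(pts) < 2) return(NULL)
    side <- if (mean(pts$k) < p$b) "low" else "high"
    list(side = side,
         k_at = stats::approxfun(pts$nu, pts$k, rule = 2),
         nu_max = max(pts$nu), nu_min = min(pts$nu))
  })
  lpc_fun <- Filter(Negate(is.null), lpc_fun)
  classify <- function(k, nu) {
    nuH <- hopf_locus_nu(k, p)
    if (abs(nu - nuH) < boundary_tol) return("boundary")
    if (nu < nuH) return("II")
    for (lf in lpc_fun) {
      if (nu > lf$nu_max + boundary_tol) next
      k_lpc <- lf$k_at(nu)
      if (abs(k - k_lpc) < boundary_tol) return("boundary")
      inside <- if (lf$side == "low") {
        k > k_lpc && nu > nuH  # between LPC1 and the low flank
      } else {
        k < k_lpc && nu > nuH
      }
      ## also require being on the correct flank of the bell
      flank_ok <- if (lf$side == "low") k < p$b else k > p$b
      if (inside && flank_ok) return("III")
    }
    "I"
  }
  grid <- NULL
  if (verify_n > 0) {
    ks <- seq(k_range[1], k_range[2], length.out = verify_n)
    nus <- seq(nu_range[1], nu_range[2], length.out = verify_n)
    grid <- expand.grid(k = ks, nu = nus)
    grid$label <- mapply(function(kk, nn) {
      classify_regime(kk, nn, p, n_scan = 25, ...)$label
    }, grid$k, grid$nu)
    grid$curve_label <- mapply(classify, grid$k, grid$nu)
  }
  structure(list(params = p, k_range = k_range, nu_range = nu_range,
                 hopf_curve = hopf, lpc_curves = lpc_curves,
                 bautin = list(low = gh_low, high = gh_high),
                 classify = classify, grid = grid,
                 boundary_tol = boundary_tol),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("<regime_map> k in [%g, %g], nu in [%g, %g]\n",
              x$k_range[1], x$k_range[2], x$nu_range[1], x$nu_range[2]))
  if (!is.null(x$bautin$low)) {
    cat(sprintf("  Bautin: GH1 (k = %.4g, nu = %.4g), GH2 (k = %.4g, nu = %.4g)\n",
                x$bautin$low$k, x$bautin$low$nu, x$bautin$high$k,
                x$bautin$high$nu))
  }
  cat(sprintf("  LPC curves: %d\n", length(x$lpc_curves)))
  invisible(x)
}
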