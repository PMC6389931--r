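## Andronov-Hopf detection, first Lyapunov coefficient (planar
## normal-form reduction) and Bautin (generalized Hopf) location.

#' First Lyapunov coefficient of a planar Hopf point
#'
#' Shifts the equilibrium to the origin, transforms the Jacobian to
#' rotation form \eqn{[[0, -\omega], [\omega, 0]]} via the real and
#' imaginary parts of the critical eigenvector, and evaluates the
#' standard planar normal-form expression
#' \deqn{16 a = f_{uuu} + f_{uvv} + g_{uuv} + g_{vvv}
#'   + \frac{1}{\omega}\left[f_{uv}(f_{uu}+f_{vv})
#'   - g_{uv}(g_{uu}+g_{vv}) - f_{uu} g_{uu} + f_{vv} g_{vv}\right]}
#' using the analytic second- and third-order derivative tensors.
#'
#' Only the sign and the zero locations of the returned value are
#' normalization-independent: \code{l1 < 0} means supercritical (a stable
#' cycle emerges), \code{l1 > 0} subcritical.
#'
#' @param sys an \code{ode_system}.
#' @param state equilibrium state satisfying the Hopf conditions
#'   (|trace| < 1e-6, determinant > 0).
#' @param p parameter list for \code{sys}.
#' @return signed first Lyapunov coefficient, with the angular frequency
#'   \eqn{\omega = \sqrt{\det J - (\mathrm{tr} J/2)^2}} attached as
#'   attribute \code{"omega"}.
#' @export
first_lyapunov_coefficient <- function(sys, state, p) {
  d <- sys$derivs(state, p)
  A <- d$jacobian
  tr <- A[1, 1] + A[2, 2]
  de <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (de <= 0) stop("not a Hopf point: Jacobian determinant <= 0")
  if (abs(tr) > 1e-6 * max(1, sqrt(de))) {
    stop("not a Hopf point: |trace| = ", abs(tr))
  }
  om <- sqrt(de - (tr / 2)^2)
  ## critical eigenvector q with A q = i*omega q (up to the trace residual)
  q <- if (abs(A[1, 2]) >= abs(A[2, 1])) {
    c(A[1, 2], 1i * om - A[1, 1])
  } else {
    c(1i * om - A[2, 2], A[2, 1])
  }
  P <- cbind(Re(q), -Im(q))
  Pi <- solve(P)
  R <- Pi %*% A %*% P
  if (abs(R[2, 1] - om) > 1e-4 * max(1, om)) {
    stop("eigenplane transform failed to reach rotation form")
  }
  e1 <- P[, 1]; e2 <- P[, 2]
  b2 <- function(u, v) as.numeric(Pi %*% bilinear_form(d, u, v))
  c3 <- function(u, v, w) as.numeric(Pi %*% trilinear_form(d, u, v, w))
  Buu <- b2(e1, e1); Buv <- b2(e1, e2); Bvv <- b2(e2, e2)
  fuu <- Buu[1]; fuv <- Buv[1]; fvv <- Bvv[1]
  guu <- Buu[2]; guv <- Buv[2]; gvv <- Bvv[2]
  fuuu <- c3(e1, e1, e1)[1]
  fuvv <- c3(e1, e2, e2)[1]
  guuv <- c3(e1, e1, e2)[2]
  gvvv <- c3(e2, e2, e2)[2]
  a <- (fuuu + fuvv + guuv + gvvv) / 16 +
    (fuv * (fuu + fvv) - guv * (guu + gvv) - fuu * guu + fvv * gvv) /
      (16 * om)
  structure(a, omega = om)
}

new_hopf_point <- function(state, p, omega, l1, param_name = NULL,
                           bautin_tol = 1e-8) {
  criticality <- if (abs(l1) < bautin_tol) "degenerate"
                 else if (l1 < 0) "supercritical" else "subcritical"
  structure(list(state = state, params = p, omega = omega, l1 = l1,
                 criticality = criticality, param_name = param_name),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf("<hopf_point> %s  state = (%.6g, %.6g)\n", x$criticality,
              x$state[1], x$state[2]))
  if (!is.null(x$param_name)) {
    cat(sprintf("  %s = %.6g", x$param_name, x$params[[x$param_name]]))
  }
  cat(sprintf("  omega = %.6g, l1 = %.4g\n", x$omega, x$l1))
  invisible(x)
}

#' Hopf locus of the interior equilibrium in closed form
#'
#' On the interior family (f = 1/2, default perceived-value shape) the
#' Jacobian trace is \eqn{w'(1/2)/4 - \nu}, so the zero-trace condition
#' gives the bell-shaped locus
#' \deqn{\nu_H(k) = \frac{c\, k\, e^{b-k}}{(1 + e^{b-k})^2}.}
#' The determinant \eqn{4 h s x^*(1-x^*)} is positive throughout, so
#' every point of the locus with \eqn{x^* \in (0,1)} is a genuine Hopf
#' point.
#'
#' @param k activation steepness value(s).
#' @param p a \code{\link{param_set}} with the default perceived-value
#'   shape (only \code{b} and \code{c} enter the formula).
#' @return \eqn{\nu} value(s) on the Hopf locus.
#' @export
hopf_locus_nu <- function(k, p = param_set()) {
  if (!has_default_u(p)) {
    stop("the closed-form Hopf locus requires the default ",
         "perceived-value shape")
  }
  if (any(k <= 0)) stop("k must be > 0")
  E <- exp(p$b - k)
  ifelse(is.finite(E), p$c * k * E / (1 + E)^2, 0)
}

#' Detect Hopf points along an equilibrium branch
#'
#' Scans the branch for sign changes of the real part of the complex
#' eigenvalue pair, then refines each bracket by bisection on the
#' Jacobian trace (re-solving the equilibrium by Newton at each trial
#' parameter) until |trace| < \code{trace_tol}. Each refined point gets
#' its angular frequency and first Lyapunov coefficient.
#'
#' @param branch an \code{equilibrium_branch} from
#'   \code{\link{continue_branch}}.
#' @param trace_tol bisection stop on the trace (default 1e-9).
#' @return list of \code{hopf_point} objects, ordered by parameter value.
#' @export
detect_hopf <- function(branch, trace_tol = 1e-9) {
  pts <- branch$points
  sys <- branch$sys
  p <- branch$p0
  pname <- branch$param_name
  trace_at <- function(alpha, guess) {
    pp <- p; pp[[pname]] <- alpha
    eq <- newton_equilibrium(sys, pp, guess, tol = 1e-10)
    if (is.null(eq)) return(NULL)
    list(tr = sum(diag(eq$jacobian)), eq = eq, p = pp)
  }
  out <- list()
  re1 <- pts$re_lambda1
  complex_pair <- abs(pts$im_lambda1) > 1e-12
  for (i in seq_len(nrow(pts) - 1)) {
    if (!(complex_pair[i] && complex_pair[i + 1])) next
    if (re1[i] == 0 || sign(re1[i]) == sign(re1[i + 1])) next
    a_lo <- pts$param[i]; a_hi <- pts$param[i + 1]
    g_lo <- c(pts$f[i], pts$x[i])
    t_lo <- trace_at(a_lo, g_lo)
    t_hi <- trace_at(a_hi, c(pts$f[i + 1], pts$x[i + 1]))
    if (is.null(t_lo) || is.null(t_hi)) next
    if (abs(Im(t_lo$eq$eigenvalues[1])) < 1e-12 ||
        abs(Im(t_hi$eq$eigenvalues[1])) < 1e-12) {
      warning("eigenvalue pair becomes real inside the bracket; ",
              "not a Hopf candidate")
      next
    }
    if (sign(t_lo$tr) == sign(t_hi$tr)) next
    mid <- NULL
    for (it in seq_len(200)) {
      a_mid <- (a_lo + a_hi) / 2
      mid <- trace_at(a_mid, (t_lo$eq$state + t_hi$eq$state) / 2)
      if (is.null(mid)) break
      if (abs(mid$tr) < trace_tol || (a_hi - a_lo) < 1e-14) break
      if (sign(mid$tr) == sign(t_lo$tr)) {
        a_lo <- a_mid; t_lo <- mid
      } else {
        a_hi <- a_mid; t_hi <- mid
      }
    }
    if (is.null(mid)) next
    l1 <- first_lyapunov_coefficient(sys, mid$eq$state, mid$p)
    out[[length(out) + 1]] <-
      new_hopf_point(mid$eq$state, mid$p, attr(l1, "omega"),
                     as.numeric(l1), param_name = pname)
  }
  ord <- order(vapply(out, function(h) h$params[[pname]], numeric(1)))
  out[ord]
}

new_bautin_point <- function(f, x, k, nu, omega, l1_residual, p) {
  structure(list(f = f, x = x, k = k, nu = nu, omega = omega,
                 l1_residual = l1_residual, params = p),
            class = "bautin_point")
}

#' @export
print.bautin_point <- function(x, ...) {
  cat(sprintf(
    "<bautin_point> (f, x, k, nu) = (%.4g, %.4g, %.4g, %.4g)\n",
    signif(x$f, 4), signif(x$x, 4), signif(x$k, 4), signif(x$nu, 4)))
  cat(sprintf("  omega = %.6g, |l1 residual| = %.3g\n", x$omega,
              abs(x$l1_residual)))
  invisible(x)
}

#' First Lyapunov coefficient along the interior Hopf locus
#'
#' Helper: at a given k, places the parameters on the Hopf locus
#' (\code{nu = hopf_locus_nu(k)}), builds the interior equilibrium and
#' evaluates \code{\link{first_lyapunov_coefficient}}.
#'
#' @param k activation steepness.
#' @param p a \code{\link{param_set}} (default u-shape; its \code{k} and
#'   \code{nu} entries are overridden).
#' @return l1 value with attribute \code{"omega"}, or \code{NA} when the
#'   locus point has no interior equilibrium.
#' @export
l1_on_hopf_locus <- function(k, p = param_set()) {
  nu <- hopf_locus_nu(k, p)
  pp <- p; pp$k <- k; pp$nu <- nu
  eq <- interior_equilibrium(pp)
  if (is.null(eq)) return(NA_real_)
  first_lyapunov_coefficient(mosaic_system(), eq$state, pp)
}

#' Locate a Bautin (generalized Hopf) point on the interior Hopf locus
#'
#' Follows the one-parameter Hopf curve \eqn{\nu = \nu_H(k)} and finds
#' the zero of the first Lyapunov coefficient on the requested side of
#' k = b, by bracketing a sign change on a scan grid and refining with
#' Brent's method to |dk| < 1e-10.
#'
#' @param p a \code{\link{param_set}} with the default perceived-value
#'   shape; \code{k} and \code{nu} are swept, the rest held fixed.
#' @param branch_side \code{"low_k"} (k < b) or \code{"high_k"} (k > b).
#' @param k_window optional length-2 numeric restricting the scan.
#' @param n_scan scan resolution for bracketing.
#' @return a \code{bautin_point}, or \code{NULL} (with a message) when l1
#'   does not change sign on the requested side.
#' @examples
#' \donttest{
#' find_bautin(param_set(), "low_k")  # (1/2, 0.72, 9.94, 1.90)
#' }
#' @export
find_bautin <- function(p = param_set(),
                        branch_side = c("low_k", "high_k"),
                        k_window = NULL, n_scan = 200) {
  branch_side <- match.arg(branch_side)
  if (is.null(k_window)) {
    k_window <- if (branch_side == "low_k") {
      c(max(p$b - 8, 0.05), p$b - 1e-3)
    } else {
      c(p$b + 1e-3, p$b + 8)
    }
  }
  ks <- seq(k_window[1], k_window[2], length.out = n_scan)
  l1s <- vapply(ks, function(k) as.numeric(l1_on_hopf_locus(k, p)),
                numeric(1))
  ok <- which(is.finite(l1s))
  br <- NULL
  for (i in seq_along(ok)[-1]) {
    i1 <- ok[i - 1]; i2 <- ok[i]
    if (l1s[i1] * l1s[i2] < 0) { br <- c(ks[i1], ks[i2]); break }
  }
  if (is.null(br)) {
    message("no Bautin point: l1 does not change sign on the ",
            branch_side, " side")
    return(NULL)
  }
  k_gh <- stats::uniroot(function(k) as.numeric(l1_on_hopf_locus(k, p)),
                         br, tol = 1e-10)$root
  nu_gh <- hopf_locus_nu(k_gh, p)
  pp <- p; pp$k <- k_gh; pp$nu <- nu_gh
  eq <- interior_equilibrium(pp)
  l1 <- l1_on_hopf_locus(k_gh, p)
  new_bautin_point(f = eq$state[["f"]], x = eq$state[["x"]],
                   k = k_gh, nu = nu_gh, omega = attr(l1, "omega"),
                   l1_residual = as.numeric(l1), p = pp)
}
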