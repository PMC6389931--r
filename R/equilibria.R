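## Equilibria of the coupled model: closed-form interior family, boundary
## roots on the invariant lines x = 0 and x = 1, Newton solves and
## pseudo-arclength continuation in one parameter.

new_equilibrium <- function(state, p, jacobian, type = "interior") {
  ev <- eigen(jacobian, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  structure(list(state = state, params = p, jacobian = jacobian,
                 eigenvalues = ev, stability = stability_label(ev),
                 type = type),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium %s> state = (%.6g, %.6g)  %s\n", x$type,
              x$state[1], x$state[2], x$stability))
  cat(sprintf("  eigenvalues: %.4g%+.4gi, %.4g%+.4gi\n",
              Re(x$eigenvalues[1]), Im(x$eigenvalues[1]),
              Re(x$eigenvalues[2]), Im(x$eigenvalues[2])))
  invisible(x)
}

## Stability from eigenvalue real parts; |Re| below the margin is flagged
## "marginal" rather than forced into a class (Hopf points live there).
stability_label <- function(ev, margin = 1e-9) {
  re <- Re(ev)
  if (max(abs(re)) < margin || abs(max(re)) < margin) return("marginal")
  if (max(re) < 0) "stable" else "unstable"
}

#' Classify the stability of an equilibrium
#'
#' Eigenvalues of the analytic Jacobian; stable iff both real parts are
#' negative, with real parts smaller than 1e-9 in magnitude flagged
#' \code{"marginal"}.
#'
#' @param eq an \code{equilibrium}, or a 2 x 2 Jacobian matrix.
#' @return list with \code{eigenvalues} and \code{stability}.
#' @export
classify_stability <- function(eq) {
  J <- if (inherits(eq, "equilibrium")) eq$jacobian else eq
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(eigenvalues = ev, stability = stability_label(ev))
}

#' Interior equilibrium of the coupled model (closed form)
#'
#' With the default perceived-value shape, u(1/2) = 0 pins the interior
#' family at f* = 1/2 and the forest balance gives
#' \deqn{x^* = 1/2 + (\nu/2 - w(1/2)/4) / (2h).}
#'
#' @param p a \code{\link{param_set}} with default u-shape and h > 0.
#' @return an \code{equilibrium}, or \code{NULL} when \eqn{x^*} falls
#'   outside (0, 1) (no interior equilibrium).
#' @examples
#' interior_equilibrium(param_set(k = 9.946, nu = 1.906))$state  # x ~ 0.722
#' @export
interior_equilibrium <- function(p) {
  if (!has_default_u(p)) {
    stop("closed-form interior equilibrium requires the default ",
         "perceived-value shape (r = q = 1, m = n = 1); ",
         "use newton_equilibrium() from a guess instead")
  }
  if (p$h <= 0) stop("interior equilibrium formula requires h > 0")
  w_half <- recruitment_rate(0.5, p)
  x_star <- 0.5 + (p$nu / 2 - w_half / 4) / (2 * p$h)
  if (x_star <= 0 || x_star >= 1) return(NULL)
  state <- c(f = 0.5, x = x_star)
  new_equilibrium(state, p, mosaic_derivatives(state, p)$jacobian,
                  type = "interior")
}

#' Newton solve for an equilibrium of a planar system
#'
#' @param sys an \code{ode_system}.
#' @param p parameter list for \code{sys}.
#' @param state0 starting guess (2-vector).
#' @param tol residual tolerance (default 1e-6, both absolute on the rhs
#'   norm and relative on the step).
#' @param max_iter Newton iteration cap.
#' @return an \code{equilibrium} (type \code{"interior"}), or \code{NULL}
#'   if Newton fails to converge.
#' @export
newton_equilibrium <- function(sys, p, state0, tol = 1e-6, max_iter = 30) {
  u <- state0
  for (i in seq_len(max_iter)) {
    d <- sys$derivs(u, p)
    if (max(abs(d$value)) < tol * 1e-3) break
    step <- solve(d$jacobian, -d$value)
    u <- u + step
    if (max(abs(step)) < tol * (1 + max(abs(u)))) {
      d <- sys$derivs(u, p)
      break
    }
  }
  if (max(abs(sys$rhs(u, p))) > tol) return(NULL)
  new_equilibrium(u, p, sys$derivs(u, p)$jacobian)
}

#' Equilibria on the invariant lines x = 0 and x = 1
#'
#' The opinion dynamics vanish identically at x = 0 and x = 1, so
#' boundary equilibria are the roots of the forest balance
#' \eqn{w(f) f (1-f) - \nu f \mp h} on each line. Roots are located by a
#' sign scan on a fine grid followed by bisection.
#'
#' @param p a \code{\link{param_set}}.
#' @param n_grid scan resolution (default 1e4 points on \eqn{[0, 1)}).
#' @return list of \code{equilibrium} objects (possibly empty), with
#'   \code{type} \code{"boundary-x0"} or \code{"boundary-x1"}.
#' @export
boundary_equilibria <- function(p, n_grid = 1e4) {
  out <- list()
  grid <- seq(0, 1 - 1e-6, length.out = n_grid)
  for (xb in c(0, 1)) {
    resid <- function(f) {
      recruitment_rate(f, p) * f * (1 - f) - p$nu * f -
        human_feedback(xb, p)
    }
    vals <- resid(grid)
    roots <- numeric(0)
    exact <- which(vals == 0)
    roots <- c(roots, grid[exact])
    sgn <- which(vals[-1] * vals[-n_grid] < 0)
    for (i in sgn) {
      roots <- c(roots,
                 stats::uniroot(resid, c(grid[i], grid[i + 1]),
                                tol = 1e-12)$root)
    }
    for (f0 in roots) {
      state <- c(f = f0, x = xb)
      J <- if (f0 <= F_MAX && f0 >= 0) {
        mosaic_derivatives(c(max(f0, 1e-12), xb), p)$jacobian
      } else next
      out[[length(out) + 1]] <-
        new_equilibrium(state, p, J,
                        type = if (xb == 0) "boundary-x0" else "boundary-x1")
    }
  }
  out
}

## ---- one-parameter continuation ---------------------------------------

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Predictor-corrector continuation of \eqn{F(u, \alpha) = 0} for a
#' planar system, able to pass folds. The corrector is a Newton
#' iteration on the residual augmented with the tangent hyperplane
#' condition, at absolute/relative tolerance \code{tol} (default 1e-6).
#' Each accepted point carries the eigenvalues and stability of the
#' analytic Jacobian.
#'
#' @param sys an \code{ode_system}.
#' @param p parameter list; \code{p[[param_name]]} is the continuation
#'   parameter and must lie inside \code{range}.
#' @param start_state converged equilibrium state at \code{p}.
#' @param param_name name of the continuation parameter (e.g. "k", "nu").
#' @param range length-2 numeric; continuation stops when the parameter
#'   leaves it (the end point is clamped onto the range boundary).
#' @param step initial arclength step (default 0.01).
#' @param max_step arclength step ceiling (default 0.1); the step halves
#'   on corrector failure and grows by 1.3 on success.
#' @param tol Newton tolerance.
#' @param max_points hard cap on branch length.
#' @return an object of class \code{equilibrium_branch}: list with
#'   \code{points} (data frame: arclength, param, f, x, re_lambda1,
#'   im_lambda1, re_lambda2, im_lambda2, stability, residual),
#'   \code{param_name}, \code{sys}, \code{p0}.
#' @export
continue_branch <- function(sys, p, start_state, param_name, range,
                            step = 0.01, max_step = 0.1, tol = 1e-6,
                            max_points = 5000) {
  range <- sort(range)
  alpha0 <- p[[param_name]]
  if (alpha0 < range[1] || alpha0 > range[2]) {
    stop("starting parameter value lies outside the continuation range")
  }
  eq0 <- newton_equilibrium(sys, p, start_state, tol = tol)
  if (is.null(eq0)) stop("starting point did not converge")

  res_fun <- function(v) {
    pp <- p; pp[[param_name]] <- v[3]
    sys$rhs(v[1:2], pp)
  }
  ext_jac <- function(v) {
    pp <- p; pp[[param_name]] <- v[3]
    J <- sys$derivs(v[1:2], pp)$jacobian
    ha <- 1e-6 * max(1, abs(v[3]))
    pp1 <- p; pp1[[param_name]] <- v[3] + ha
    pp2 <- p; pp2[[param_name]] <- v[3] - ha
    dFa <- (sys$rhs(v[1:2], pp1) - sys$rhs(v[1:2], pp2)) / (2 * ha)
    cbind(J, dFa)
  }
  tangent <- function(v, prev = NULL) {
    A <- ext_jac(v)
    tv <- c(A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
            A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
            A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])  # null vector (cross product of rows)
    nt <- sqrt(sum(tv^2))
    if (nt < 1e-14) stop("singular extended Jacobian on the branch")
    tv <- tv / nt
    if (!is.null(prev) && sum(tv * prev) < 0) tv <- -tv
    tv
  }
  correct <- function(v_pred, t0) {
    v <- v_pred
    polish <- 0
    for (i in seq_len(15)) {
      G <- res_fun(v)
      g3 <- sum(t0 * (v - v_pred))
      converged <- max(abs(G)) < tol && abs(g3) < tol
      ## polish beyond the acceptance tolerance: one or two extra Newton
      ## steps push the branch points to near machine accuracy
      if (converged && (polish >= 2 || max(abs(G)) < 1e-12)) return(v)
      if (converged) polish <- polish + 1
      A <- rbind(ext_jac(v), t0)
      dv <- tryCatch(solve(A, -c(G, g3)), error = function(e) NULL)
      if (is.null(dv)) return(NULL)
      v <- v + dv
      if (!converged && max(abs(dv)) < 1e-13 * (1 + max(abs(v)))) break
    }
    if (max(abs(res_fun(v))) < tol) v else NULL
  }
  record <- function(v, arc) {
    pp <- p; pp[[param_name]] <- v[3]
    cs <- classify_stability(sys$derivs(v[1:2], pp)$jacobian)
    ev <- cs$eigenvalues
    data.frame(arclength = arc, param = v[3], f = v[1], x = v[2],
               re_lambda1 = Re(ev[1]), im_lambda1 = Im(ev[1]),
               re_lambda2 = Re(ev[2]), im_lambda2 = Im(ev[2]),
               stability = cs$stability,
               residual = max(abs(sys$rhs(v[1:2], pp))))
  }

  ## continue in both directions from the start, then stitch
  run_dir <- function(dir) {
    v <- c(eq0$state, alpha0)
    tv <- tangent(v) * dir
    h <- step
    pts <- list()
    arc <- 0
    repeat {
      if (length(pts) >= max_points) break
      v_pred <- v + h * tv
      v_new <- correct(v_pred, tv)
      if (is.null(v_new) || sys_margin(sys, v_new[1:2]) <= 0) {
        h <- h / 2
        if (h < 1e-8) break
        next
      }
      if (v_new[3] < range[1] || v_new[3] > range[2]) {
        ## clamp: solve at the range boundary with fixed parameter
        a_end <- if (v_new[3] < range[1]) range[1] else range[2]
        pp <- p; pp[[param_name]] <- a_end
        eq_end <- newton_equilibrium(sys, pp, v[1:2], tol = tol)
        if (!is.null(eq_end)) {
          arc <- arc + sqrt(sum((c(eq_end$state, a_end) - v)^2))
          pts[[length(pts) + 1]] <- record(c(eq_end$state, a_end), arc)
        }
        break
      }
      arc <- arc + sqrt(sum((v_new - v)^2))
      pts[[length(pts) + 1]] <- record(v_new, arc)
      tv <- tangent(v_new, tv)
      v <- v_new
      h <- min(h * 1.3, max_step)
    }
    pts
  }

  up <- run_dir(+1)
  down <- run_dir(-1)
  p0 <- record(c(eq0$state, alpha0), 0)
  down_df <- if (length(down) > 0) do.call(rbind, rev(down)) else NULL
  up_df <- if (length(up) > 0) do.call(rbind, up) else NULL
  if (!is.null(down_df)) down_df$arclength <- -down_df$arclength
  pts <- rbind(down_df, p0, up_df)
  pts$arclength <- pts$arclength - min(pts$arclength)
  rownames(pts) <- NULL
  structure(list(points = pts, param_name = param_name, sys = sys, p0 = p),
            class = "equilibrium_branch")
}

#' @export
print.equilibrium_branch <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("<equilibrium_branch> %d points, %s in [%.4g, %.4g]\n",
              n, x$param_name, min(x$points$param), max(x$points$param)))
  flips <- sum(diff(x$points$stability == "stable") != 0)
  cat(sprintf("  stability changes: %d\n", flips))
  invisible(x)
}
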