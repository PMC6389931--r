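## Limit cycles through a Poincare return map.
##
## For a planar system a periodic orbit is a fixed point of the scalar
## return map P on a ray transverse to the flow, anchored at the focus it
## encircles. The map and its exact derivative are computed by
## integrating the variational equations alongside the trajectory; the
## derivative of P at a fixed point is the nontrivial Floquet
## multiplier, so cycle stability, fold-of-cycles (LPC) conditions and
## pseudo-arclength continuation all reduce to scalar root problems.

#' Define a Poincare section
#'
#' The section is the ray \{center + a * direction, a > 0\} inside the
#' hyperplane through \code{center} with normal \code{normal}; crossings
#' are accepted in the direction of increasing \code{normal}-component
#' of the flow.
#'
#' @param center 2-vector, the anchor (typically the encircled
#'   equilibrium).
#' @param normal 2-vector normal of the section line.
#' @param direction 2-vector along the section line (unit length
#'   recommended).
#' @return an object of class \code{poincare_section}.
#' @export
poincare_section <- function(center, normal, direction) {
  structure(list(center = center, normal = normal / sqrt(sum(normal^2)),
                 direction = direction / sqrt(sum(direction^2))),
            class = "poincare_section")
}

## integration-safe value+jacobian
sys_vj <- function(sys, u, p) sys$vj(u, p)

## One full turn of the return map, with the variational matrix and the
## Jacobian-trace integral carried along. Returns ok = FALSE with a
## reason on domain exit or failure to return within t_max.
return_map <- function(sys, p, sec, a, t_max = 500, rtol = 1e-10,
                       atol = 1e-12) {
  ctr <- sec$center; nrm <- sec$normal; dir <- sec$direction
  u0 <- ctr + a * dir
  if (sys_margin(sys, u0) <= 0) {
    return(list(ok = FALSE, reason = "start outside domain"))
  }
  func <- function(t, y, parms) {
    u <- y[1:2]
    vj <- sys_vj(sys, u, p)
    M <- matrix(y[3:6], 2, 2)
    list(c(vj$value, as.vector(vj$jacobian %*% M),
           vj$jacobian[1, 1] + vj$jacobian[2, 2]))
  }
  rootfun <- function(t, y, parms) {
    c(sum(nrm * (y[1:2] - ctr)), sys_margin(sys, y[1:2]))
  }
  y <- c(u0, 1, 0, 0, 1, 0)
  t_cur <- 0
  eps <- 1e-4
  for (leg in 1:10) {
    ## leave the section before arming root finding; the burn-in grows
    ## until the section function is measurably nonzero (probes started
    ## near the equilibrium leave only slowly)
    burn <- eps
    repeat {
      if (t_cur + 2 * burn >= t_max) {
        return(list(ok = FALSE, reason = "no return within t_max"))
      }
      st <- tryCatch(
        deSolve::lsoda(y, c(t_cur, t_cur + burn), func, parms = NULL,
                       rtol = rtol, atol = atol),
        error = function(e) NULL)
      if (is.null(st)) {
        return(list(ok = FALSE, reason = "integration failure"))
      }
      y_try <- as.numeric(st[nrow(st), -1])
      if (abs(sum(nrm * (y_try[1:2] - ctr))) > 1e-11 || burn > 1) {
        y <- y_try
        t_cur <- t_cur + burn
        break
      }
      burn <- burn * 4
    }
    out <- tryCatch(
      deSolve::lsodar(y, c(t_cur, t_max), func, parms = NULL,
                      rootfunc = rootfun, rtol = rtol, atol = atol,
                      maxsteps = 100000),
      error = function(e) NULL)
    if (is.null(out)) {
      return(list(ok = FALSE, reason = "integration failure"))
    }
    iroot <- attributes(out)$iroot  # 0/1 indicator per root function
    t_new <- out[nrow(out), 1]
    y <- as.numeric(out[nrow(out), -1])
    t_cur <- t_new
    if (is.null(iroot) || all(iroot == 0)) {
      return(list(ok = FALSE, reason = "no return within t_max"))
    }
    if (iroot[2] != 0) {
      return(list(ok = FALSE, reason = "left the state domain"))
    }
    u_end <- y[1:2]
    F_end <- sys_vj(sys, u_end, p)$value
    gdot <- sum(nrm * F_end)
    if (gdot > 0) {
      M <- matrix(y[3:6], 2, 2)
      nMv <- sum(nrm * (M %*% dir))
      Pp <- sum(dir * (M %*% dir - F_end * nMv / gdot))
      return(list(ok = TRUE, a = sum(dir * (u_end - ctr)),
                  period = t_cur, M = M, Pprime = Pp,
                  log_det = y[7], u_end = u_end, F_end = F_end))
    }
    ## wrong-direction crossing (half turn): keep integrating
  }
  list(ok = FALSE, reason = "too many section crossings without return")
}

new_limit_cycle <- function(sys, p, sec, a, rm, n_mesh = 200,
                            rtol = 1e-10, atol = 1e-12) {
  u0 <- sec$center + a * sec$direction
  times <- seq(0, rm$period, length.out = n_mesh + 1)
  func <- function(t, y, parms) list(sys_vj(sys, y, p)$value)
  tr <- deSolve::lsoda(u0, times, func, parms = NULL, rtol = rtol,
                       atol = atol)
  mesh <- data.frame(t = tr[, 1], f = tr[, 2], x = tr[, 3])
  mult <- eigen(rm$M, only.values = TRUE)$values
  mult <- mult[order(abs(mult - 1))]  # trivial first
  nontrivial <- mult[2]
  closure_err <- sqrt(sum((as.numeric(tr[nrow(tr), -1]) - u0)^2))
  structure(list(
    mesh = mesh, period = rm$period, params = p, sec = sec, a = a,
    sys = sys,
    multipliers = mult,
    stability = if (abs(nontrivial) < 1) "stable" else "unstable",
    amplitude = max(mesh$f) - min(mesh$f),
    amplitude_x = max(mesh$x) - min(mesh$x),
    closure_error = closure_err,
    trivial_multiplier_error = abs(mult[1] - 1)),
    class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("<limit_cycle> %s  period = %.6g\n", x$stability, x$period))
  cat(sprintf("  amplitude (f) = %.4g, (x) = %.4g\n", x$amplitude,
              x$amplitude_x))
  cat(sprintf("  multipliers: %.6g (trivial), %.6g\n",
              Re(x$multipliers[1]), Re(x$multipliers[2])))
  invisible(x)
}

#' Locate a limit cycle as a fixed point of the return map
#'
#' Newton iteration on \eqn{g(a) = P(a) - a}, using the exact map
#' derivative from the variational equations, with bisection fallback
#' when a bracket is available.
#'
#' @param sys an \code{ode_system}.
#' @param p parameter list.
#' @param sec a \code{\link{poincare_section}}; defaults to the system's
#'   own section at \code{p}.
#' @param a0 starting ray coordinate.
#' @param cycle_tol closure tolerance on |P(a) - a| (default 1e-8).
#' @param a_bracket optional length-2 bracket on which g changes sign.
#' @param n_mesh number of mesh points stored on the returned orbit.
#' @param ... passed to the integrator (\code{rtol}, \code{atol},
#'   \code{t_max}).
#' @return a \code{limit_cycle}, or \code{NULL} if no cycle converges.
#' @export
find_cycle <- function(sys, p, sec = NULL, a0, cycle_tol = 1e-8,
                       a_bracket = NULL, n_mesh = 200, ...) {
  if (is.null(sec)) sec <- sys$section(p)
  g_eval <- function(a) {
    rm <- return_map(sys, p, sec, a, ...)
    if (!rm$ok) return(NULL)
    rm
  }
  lo <- hi <- g_lo <- NA
  if (!is.null(a_bracket)) {
    lo <- min(a_bracket); hi <- max(a_bracket)
    rm_lo <- g_eval(lo)
    if (!is.null(rm_lo)) g_lo <- rm_lo$a - lo
  }
  a <- a0
  rm <- g_eval(a)
  if (is.null(rm)) return(NULL)
  for (i in seq_len(40)) {
    g <- rm$a - a
    if (abs(g) < cycle_tol) {
      return(new_limit_cycle(sys, p, sec, a, rm, n_mesh = n_mesh))
    }
    dg <- rm$Pprime - 1
    a_new <- if (abs(dg) > 1e-12) a - g / dg else NA
    if (!is.na(g_lo)) {  # maintain the bracket
      if (sign(g) == sign(g_lo)) { lo <- a; g_lo <- g } else hi <- a
      if (is.na(a_new) || a_new <= lo || a_new >= hi) {
        a_new <- (lo + hi) / 2
      }
    }
    if (is.na(a_new) || a_new <= 0) return(NULL)
    a <- a_new
    rm <- g_eval(a)
    if (is.null(rm)) return(NULL)
  }
  NULL
}

#' Floquet multipliers of a limit cycle
#'
#' Recomputes the monodromy matrix by integrating the variational
#' equations over one period from the stored section point. For an
#' autonomous system one multiplier is always 1 (trivial); the cycle is
#' stable iff the other has modulus < 1. The product of the multipliers
#' equals \eqn{\exp \int_0^T \mathrm{tr}\, J\, dt} (Liouville), which is
#' returned for cross-checking.
#'
#' @param cycle a \code{limit_cycle}.
#' @param rtol,atol integrator tolerances.
#' @return list with \code{multipliers} (trivial first),
#'   \code{trivial_error}, \code{product} and \code{liouville_product}.
#' @export
floquet_multipliers <- function(cycle, rtol = 1e-10, atol = 1e-12) {
  sys <- cycle$sys; p <- cycle$params
  u0 <- as.numeric(cycle$mesh[1, c("f", "x")])
  func <- function(t, y, parms) {
    vj <- sys_vj(sys, y[1:2], p)
    M <- matrix(y[3:6], 2, 2)
    list(c(vj$value, as.vector(vj$jacobian %*% M),
           vj$jacobian[1, 1] + vj$jacobian[2, 2]))
  }
  out <- deSolve::lsoda(c(u0, 1, 0, 0, 1, 0), c(0, cycle$period), func,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  if (nrow(out) < 2 || any(!is.finite(out[nrow(out), ]))) {
    stop("monodromy integration failed at t = ", out[nrow(out), 1])
  }
  y <- as.numeric(out[nrow(out), -1])
  M <- matrix(y[3:6], 2, 2)
  mult <- eigen(M, only.values = TRUE)$values
  mult <- mult[order(abs(mult - 1))]
  list(multipliers = mult, trivial_error = abs(mult[1] - 1),
       product = prod(mult), liouville_product = exp(y[7]))
}

#' Grow a small limit cycle off a Hopf point
#'
#' Displaces the bifurcation parameter by \code{offset} into the
#' cycle-existence side -- chosen from the sign of l1 and of the trace
#' derivative along the equilibrium family -- then brackets the
#' nontrivial fixed point of the return map on a geometric ray grid and
#' converges it by Newton. The offset doubles on failure, up to three
#' retries.
#'
#' @param hp a \code{hopf_point} carrying its continuation parameter
#'   name.
#' @param sys the \code{ode_system} the Hopf point belongs to.
#' @param offset magnitude of the parameter displacement (default 1e-3).
#' @param a_max largest ray coordinate scanned.
#' @param ... passed to \code{\link{find_cycle}}.
#' @return a \code{limit_cycle}.
#' @export
initial_cycle_from_hopf <- function(hp, sys, offset = 1e-3, a_max = 0.5,
                                    ...) {
  pname <- hp$param_name
  if (is.null(pname)) stop("Hopf point carries no parameter name")
  p <- hp$params
  alpha <- p[[pname]]
  trace_at <- function(a_val) {
    pp <- p; pp[[pname]] <- a_val
    eq <- newton_equilibrium(sys, pp, hp$state, tol = 1e-10)
    if (is.null(eq)) return(NA_real_)
    sum(diag(eq$jacobian))
  }
  desired <- if (hp$l1 < 0) +1 else -1  # sign of trace where cycles live
  for (attempt in 1:4) {
    off <- offset * 2^(attempt - 1)
    for (side in c(+1, -1)) {
      tr <- trace_at(alpha + side * off)
      if (!is.na(tr) && sign(tr) == desired) {
        pp <- p; pp[[pname]] <- alpha + side * off
        sec <- sys$section(pp)
        grid <- exp(seq(log(1e-4), log(a_max), length.out = 60))
        g_prev <- NA; a_prev <- NA
        for (a in grid) {
          rm <- return_map(sys, pp, sec, a, ...)
          g <- if (rm$ok) rm$a - a else NA
          if (!is.na(g) && !is.na(g_prev) && g * g_prev < 0) {
            cyc <- find_cycle(sys, pp, sec, (a_prev + a) / 2,
                              a_bracket = c(a_prev, a), ...)
            if (!is.null(cyc)) return(cyc)
          }
          g_prev <- g; a_prev <- a
        }
        break  # correct side scanned and failed; enlarge offset
      }
    }
  }
  stop("no converged cycle near the Hopf point after 3 offset doublings")
}

## ---- cycle branch continuation ----------------------------------------

#' Continue a branch of limit cycles in one parameter
#'
#' Pseudo-arclength continuation of the fixed-point equation
#' \eqn{P(a; \alpha) = a} of the Poincare return map in the
#' (ray coordinate, parameter) plane. The map derivative comes from the
#' variational equations; the parameter derivative is a central
#' difference. Each accepted cycle carries its period, nontrivial
#' multiplier and amplitudes; stability changes only at folds, which
#' show up as sign changes of the parameter component of the branch
#' tangent.
#'
#' @param sys an \code{ode_system}.
#' @param c0 a converged \code{limit_cycle} to start from.
#' @param param_name continuation parameter name.
#' @param range length-2 numeric; the branch stops at its boundary.
#' @param step,max_step arclength step control (halving on failure).
#' @param amp_min branch terminates when the f-amplitude falls below
#'   this (cycle shrinking into a Hopf point).
#' @param period_max branch terminates when the period exceeds this.
#' @param max_points hard cap.
#' @param cycle_tol corrector tolerance on |P(a) - a|.
#' @param direction +1 (default) starts towards growing ray coordinate,
#'   -1 the other way.
#' @param rtol,atol integrator tolerances.
#' @return an object of class \code{cycle_branch}: list with
#'   \code{points} (data frame: arclength, param, a, period, amplitude_f,
#'   amplitude_x, multiplier, stability, tangent_param),
#'   \code{param_name}, \code{termination}, \code{sec}, \code{sys},
#'   \code{p0}.
#' @export
continue_cycle_branch <- function(sys, c0, param_name, range,
                                  step = 0.02, max_step = 0.35,
                                  amp_min = 1e-4, period_max = 500,
                                  max_points = 500, cycle_tol = 1e-8,
                                  direction = +1, rtol = 1e-10,
                                  atol = 1e-12) {
  range <- sort(range)
  p <- c0$params
  sec <- c0$sec
  alpha0 <- p[[param_name]]
  eval_G <- function(a, alpha) {
    pp <- p; pp[[param_name]] <- alpha
    rm <- return_map(sys, pp, sec, a, rtol = rtol, atol = atol)
    if (!rm$ok) return(NULL)
    list(G = rm$a - a, Ga = rm$Pprime - 1, rm = rm)
  }
  G_alpha <- function(a, alpha, base) {
    da <- 1e-6 * max(1, abs(alpha))
    up <- eval_G(a, alpha + da)
    if (is.null(up)) return(NULL)
    (up$G - base$G) / da
  }
  amplitudes <- function(a, alpha, period) {
    pp <- p; pp[[param_name]] <- alpha
    u0 <- sec$center + a * sec$direction
    tr <- deSolve::lsoda(u0, seq(0, period, length.out = 81),
                         function(t, y, parms) list(sys_vj(sys, y, pp)$value),
                         parms = NULL, rtol = rtol, atol = atol)
    c(max(tr[, 2]) - min(tr[, 2]), max(tr[, 3]) - min(tr[, 3]))
  }
  record <- function(a, alpha, ev, tv, arc) {
    amp <- amplitudes(a, alpha, ev$rm$period)
    data.frame(arclength = arc, param = alpha, a = a,
               period = ev$rm$period, amplitude_f = amp[1],
               amplitude_x = amp[2], multiplier = ev$rm$Pprime,
               stability = if (abs(ev$rm$Pprime) < 1) "stable"
                           else "unstable",
               tangent_param = tv[2])
  }
  ev0 <- eval_G(c0$a, alpha0)
  if (is.null(ev0) || abs(ev0$G) > 10 * cycle_tol) {
    stop("starting cycle does not satisfy the return-map equation")
  }
  Gal <- G_alpha(c0$a, alpha0, ev0)
  tv <- c(-Gal, ev0$Ga)
  tv <- tv / sqrt(sum(tv^2))
  ## by default head towards growing ray coordinate (away from the
  ## amplitude collapse at the seeding Hopf point)
  if (direction * tv[1] < 0) tv <- -tv
  run <- function(tv0) {
    v <- c(c0$a, alpha0)
    tv <- tv0
    ev <- ev0
    h <- step
    arc <- 0
    pts <- list(record(v[1], v[2], ev0, tv0, 0))
    term <- "max_points"
    while (length(pts) < max_points) {
      v_pred <- v + h * tv
      ## corrector: Newton on {G = 0, tv . (v - v_pred) = 0}, kept inside
      ## a trust region around the predictor so it cannot leap onto a
      ## distant spurious fixed point of the return map
      trust <- 4 * h + 1e-3
      vc <- v_pred
      evc <- NULL
      ok <- FALSE
      for (it in 1:10) {
        evc <- eval_G(vc[1], vc[2])
        if (is.null(evc)) break
        Gal <- G_alpha(vc[1], vc[2], evc)
        if (is.null(Gal)) break
        rhs <- -c(evc$G, sum(tv * (vc - v_pred)))
        A <- rbind(c(evc$Ga, Gal), tv)
        dv <- tryCatch(solve(A, rhs), error = function(e) NULL)
        if (is.null(dv)) break
        vc <- vc + dv
        ## the ray coordinate may cross zero when the orbit family drifts
        ## across the (fixed) section anchor; only wild steps are rejected
        if (abs(vc[1]) > 2 || max(abs(vc - v_pred)) > trust) break
        if (abs(evc$G) < cycle_tol && max(abs(dv)) < 1e-9 * (1 + max(abs(vc)))) {
          ok <- TRUE; break
        }
        if (max(abs(dv)) < 1e-10) { ok <- abs(evc$G) < cycle_tol; break }
      }
      if (ok) {
        evc <- eval_G(vc[1], vc[2])
        ok <- !is.null(evc) && abs(evc$G) < cycle_tol
      }
      if (!ok) {
        h <- h / 2
        if (h < 1e-7) { term <- "stalled"; break }
        next
      }
      ## new tangent
      Gal <- G_alpha(vc[1], vc[2], evc)
      tv_new <- c(-Gal, evc$Ga)
      tv_new <- tv_new / sqrt(sum(tv_new^2))
      if (sum(tv_new * tv) < 0) tv_new <- -tv_new
      arc <- arc + sqrt(sum((vc - v)^2))
      pts[[length(pts) + 1]] <- record(vc[1], vc[2], evc, tv_new, arc)
      last <- pts[[length(pts)]]
      if (last$amplitude_f < amp_min) { term <- "amplitude_vanished"; break }
      if (last$period > period_max) { term <- "period_blowup"; break }
      if (vc[2] < range[1] || vc[2] > range[2]) { term <- "range_end"; break }
      v <- vc; tv <- tv_new; ev <- evc
      h <- min(h * 1.3, max_step)
    }
    list(pts = do.call(rbind, pts), term = term)
  }
  res <- run(tv)
  pts <- res$pts
  rownames(pts) <- NULL
  structure(list(points = pts, param_name = param_name,
                 termination = res$term, sec = sec, sys = sys, p0 = p),
            class = "cycle_branch")
}

#' @export
print.cycle_branch <- function(x, ...) {
  cat(sprintf(
    "<cycle_branch> %d cycles, %s in [%.4g, %.4g], terminated: %s\n",
    nrow(x$points), x$param_name, min(x$points$param),
    max(x$points$param), x$termination))
  invisible(x)
}

#' Extract one converged cycle from a cycle branch
#'
#' @param branch a \code{cycle_branch}.
#' @param i row index into \code{branch$points}.
#' @param ... passed to \code{\link{find_cycle}}.
#' @return a \code{limit_cycle}.
#' @export
branch_cycle <- function(branch, i, ...) {
  pt <- branch$points[i, ]
  pp <- branch$p0; pp[[branch$param_name]] <- pt$param
  find_cycle(branch$sys, pp, branch$sec, pt$a, ...)
}

## Solve the exact fold-of-cycles system {P(a) - a = 0, P'(a) - 1 = 0}
## for (a, alpha) by Newton with finite-difference second derivatives.
solve_lpc <- function(sys, p, sec, a0, alpha0, param_name,
                      tol_g = 1e-8, tol_h = 1e-6, max_iter = 25,
                      rtol = 1e-10, atol = 1e-12) {
  eval_rm <- function(a, alpha) {
    pp <- p; pp[[param_name]] <- alpha
    rm <- return_map(sys, pp, sec, a, rtol = rtol, atol = atol)
    if (!rm$ok) NULL else rm
  }
  v <- c(a0, alpha0)
  for (it in seq_len(max_iter)) {
    rm <- eval_rm(v[1], v[2])
    if (is.null(rm)) return(NULL)
    G <- rm$a - v[1]
    H <- rm$Pprime - 1
    if (abs(G) < tol_g && abs(H) < tol_h) {
      return(list(a = v[1], alpha = v[2], rm = rm))
    }
    da <- 1e-6 * max(1, abs(v[1]))
    dal <- 1e-6 * max(1, abs(v[2]))
    rma <- eval_rm(v[1] + da, v[2])
    rmal <- eval_rm(v[1], v[2] + dal)
    if (is.null(rma) || is.null(rmal)) return(NULL)
    J <- rbind(c(rm$Pprime - 1, (rmal$a - rm$a) / dal),
               c((rma$Pprime - rm$Pprime) / da,
                 (rmal$Pprime - rm$Pprime) / dal))
    dv <- tryCatch(solve(J, -c(G, H)), error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    ## damp wild steps
    if (max(abs(dv)) > 0.5) dv <- dv * 0.5 / max(abs(dv))
    v <- v + dv
    if (v[1] <= 0) return(NULL)
  }
  NULL
}

#' Detect folds of limit cycles (LPC points) on a cycle branch
#'
#' Folds are located where the parameter component of the continuation
#' tangent changes sign, then each candidate is refined by a Newton
#' solve of the exact fold system \{P(a) = a, P'(a) = 1\}. At a fold the
#' nontrivial Floquet multiplier equals +1 by construction; the refined
#' value is checked against \code{lpc_tol}.
#'
#' @param branch a \code{cycle_branch}.
#' @param lpc_tol acceptance tolerance on |multiplier - 1| (default
#'   1e-3).
#' @param ... integrator tolerances forwarded to the fold solver.
#' @return list of \code{lpc_point} objects (possibly empty), each with
#'   the fold parameter value, ray coordinate, period, multiplier and
#'   the converged \code{limit_cycle}.
#' @export
detect_lpc <- function(branch, lpc_tol = 1e-3, ...) {
  pts <- branch$points
  if (nrow(pts) < 3) return(list())
  out <- list()
  tp <- pts$tangent_param
  for (i in seq_len(nrow(pts) - 1)) {
    if (is.na(tp[i]) || is.na(tp[i + 1])) next
    if (tp[i] == 0 || sign(tp[i]) == sign(tp[i + 1])) next
    sol <- solve_lpc(branch$sys, branch$p0, branch$sec,
                     (pts$a[i] + pts$a[i + 1]) / 2,
                     (pts$param[i] + pts$param[i + 1]) / 2,
                     branch$param_name, ...)
    if (is.null(sol)) next
    if (abs(sol$rm$Pprime - 1) > lpc_tol) next
    pp <- branch$p0; pp[[branch$param_name]] <- sol$alpha
    cyc <- new_limit_cycle(branch$sys, pp, branch$sec, sol$a, sol$rm)
    out[[length(out) + 1]] <- structure(
      list(param_name = branch$param_name, param = sol$alpha, a = sol$a,
           period = sol$rm$period, multiplier = sol$rm$Pprime,
           cycle = cyc, params = pp),
      class = "lpc_point")
  }
  out
}

#' Does a limit cycle enclose a point?
#'
#' Winding-number test of the cycle's mesh polygon around a point; used
#' e.g. to check that the unstable cycle of the bistable regime encloses
#' the stable equilibrium (it is the basin boundary).
#'
#' @param cycle a \code{limit_cycle}.
#' @param point numeric 2-vector.
#' @return logical: winding number is +/-1.
#' @export
cycle_encloses <- function(cycle, point) {
  dx <- cycle$mesh$f - point[1]
  dy <- cycle$mesh$x - point[2]
  ang <- atan2(dy, dx)
  d <- diff(ang)
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  winding <- round(sum(d) / (2 * pi))
  abs(winding) >= 1
}

#' @export
print.lpc_point <- function(x, ...) {
  cat(sprintf("<lpc_point> %s = %.6g  amplitude (f) = %.4g\n",
              x$param_name, x$param, x$cycle$amplitude))
  cat(sprintf("  nontrivial multiplier = %.6g (fold: = 1)\n",
              x$multiplier))
  invisible(x)
}
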