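## Time integration, regime-shift experiments and basin membership.

#' Integrate the model forward in time
#'
#' Adaptive integration (lsoda) at tolerance 1e-10, stopping with a
#' domain-exit flag when the state approaches the singular boundary
#' f = 1.
#'
#' @param p parameter list.
#' @param state0 initial state \code{c(f, x)}.
#' @param times output times, or a length-2 span (then \code{n_out}
#'   points are returned).
#' @param sys the \code{ode_system} (default: the mosaic model).
#' @param n_out number of output points when \code{times} is a span.
#' @param rtol,atol integrator tolerances.
#' @return a data frame (class \code{trajectory}) with columns t, f, x;
#'   attribute \code{"domain_exit"} is TRUE when integration was
#'   terminated at the state-domain boundary.
#' @examples
#' tr <- integrate_model(param_set(k = 10, nu = 0.5), c(0.4, 0.6), c(0, 50))
#' @export
integrate_model <- function(p, state0, times, sys = mosaic_system(),
                            n_out = 501, rtol = 1e-10, atol = 1e-12) {
  if (length(times) == 2) times <- seq(times[1], times[2],
                                       length.out = n_out)
  func <- function(t, y, parms) list(sys_vj(sys, y, p)$value)
  rootfun <- function(t, y, parms) sys_margin(sys, y)
  out <- deSolve::lsodar(state0, times, func, parms = NULL,
                         rootfunc = rootfun, rtol = rtol, atol = atol,
                         maxsteps = 100000)
  iroot <- attributes(out)$iroot
  df <- data.frame(t = out[, 1], f = out[, 2], x = out[, 3])
  structure(df, class = c("trajectory", "data.frame"),
            domain_exit = !is.null(iroot) && any(iroot != 0),
            params = p)
}

## peak-to-peak f-amplitude over the trailing fraction of a trajectory
tail_amplitude <- function(tr, frac = 0.2) {
  n <- nrow(tr)
  idx <- seq(max(1, ceiling(n * (1 - frac))), n)
  max(tr$f[idx]) - min(tr$f[idx])
}

## integrate from state0 until the trailing amplitude settles
settle <- function(p, state0, sys = mosaic_system(), window = 100,
                   settle_tol = 1e-4, t_max = 2000, ...) {
  state <- state0
  amp_prev <- Inf
  t_done <- 0
  tr <- NULL
  while (t_done < t_max) {
    tr <- integrate_model(p, state, c(0, window), sys = sys,
                          n_out = 401, ...)
    if (isTRUE(attr(tr, "domain_exit"))) {
      return(list(state = as.numeric(tr[nrow(tr), c("f", "x")]),
                  amplitude = NA, settled = FALSE, domain_exit = TRUE,
                  trajectory = tr))
    }
    amp <- max(tr$f) - min(tr$f)
    state <- as.numeric(tr[nrow(tr), c("f", "x")])
    t_done <- t_done + window
    if (abs(amp - amp_prev) < settle_tol) {
      return(list(state = state, amplitude = amp, settled = TRUE,
                  domain_exit = FALSE, trajectory = tr))
    }
    amp_prev <- amp
  }
  list(state = state, amplitude = amp_prev, settled = FALSE,
       domain_exit = FALSE, trajectory = tr)
}

#' Specify a regime-shift experiment
#'
#' Exactly one perturbation kind: either a state displacement
#' (\code{delta}) or a parameter step (\code{param}, \code{new_value}),
#' imposed at time \code{t_perturb}.
#'
#' @param t_perturb perturbation time (years), > 0; default 100 years.
#' @param delta state displacement 2-vector, or NULL.
#' @param param,new_value parameter name and its post-perturbation
#'   value, or NULL.
#' @param t_max settling cap after the perturbation (years).
#' @return an object of class \code{shift_protocol}.
#' @export
shift_protocol <- function(t_perturb = 100, delta = NULL, param = NULL,
                           new_value = NULL, t_max = 2000) {
  kind <- if (!is.null(delta)) "state" else "parameter"
  if (kind == "state" && (!is.null(param) || !is.null(new_value))) {
    stop("exactly one perturbation kind per protocol")
  }
  if (kind == "parameter" && (is.null(param) || is.null(new_value))) {
    stop("parameter protocols need both 'param' and 'new_value'")
  }
  stopifnot(t_perturb > 0)
  structure(list(kind = kind, t_perturb = t_perturb, delta = delta,
                 param = param, new_value = new_value, t_max = t_max),
            class = "shift_protocol")
}

#' Run a catastrophic-vs-smooth shift experiment
#'
#' Integrates to (statistical) steady state before the perturbation,
#' applies it, settles again, and classifies the transition.
#'
#' A state kick is catastrophic when the asymptotic oscillation
#' amplitude jumps by more than the configured factor (default 5, with a
#' small floor) relative to the pre-perturbation attractor -- i.e. the
#' kick crossed a basin boundary. A parameter step is additionally
#' probed quasi-statically: the parameter is walked from the old to the
#' new value in small increments, tracking the attractor amplitude; the
#' shift is catastrophic when that path contains a discontinuous jump,
#' and smooth when the amplitude changes continuously (as it does across
#' a supercritical Hopf point).
#'
#' @param p parameter list.
#' @param state0 initial state.
#' @param protocol a \code{\link{shift_protocol}}.
#' @param jump_factor amplitude ratio declaring a jump (default 5).
#' @param amp_floor amplitude floor used in the ratio test.
#' @param n_steps quasi-static increments for parameter protocols.
#' @param ... forwarded to the integrator.
#' @return list with \code{classification} ("smooth", "catastrophic" or
#'   "undecided"), \code{amp_pre}, \code{amp_post}, the quasi-static
#'   \code{amplitude_path} (parameter protocols) and the pre/post
#'   trajectories.
#' @export
shift_experiment <- function(p, state0, protocol, jump_factor = 5,
                             amp_floor = 0.02, n_steps = 20, ...) {
  stopifnot(inherits(protocol, "shift_protocol"))
  pre <- integrate_model(p, state0, c(0, protocol$t_perturb), ...)
  amp_pre <- tail_amplitude(pre, 0.2)
  state_p <- as.numeric(pre[nrow(pre), c("f", "x")])
  jumped <- function(a_old, a_new) {
    max(a_old, a_new) > jump_factor * max(min(a_old, a_new), amp_floor)
  }
  if (protocol$kind == "state") {
    if (all(protocol$delta == 0)) {
      post <- settle(p, state_p, t_max = protocol$t_max, ...)
      return(list(classification = "smooth", amp_pre = amp_pre,
                  amp_post = post$amplitude, amplitude_path = NULL,
                  pre = pre, post = post$trajectory))
    }
    post <- settle(p, state_p + protocol$delta, t_max = protocol$t_max,
                   ...)
    if (!post$settled) {
      return(list(classification = "undecided", amp_pre = amp_pre,
                  amp_post = post$amplitude, amplitude_path = NULL,
                  pre = pre, post = post$trajectory))
    }
    cls <- if (jumped(amp_pre, post$amplitude)) "catastrophic" else
      "smooth"
    return(list(classification = cls, amp_pre = amp_pre,
                amp_post = post$amplitude, amplitude_path = NULL,
                pre = pre, post = post$trajectory))
  }
  ## parameter step: direct run ...
  p_new <- p
  p_new[[protocol$param]] <- protocol$new_value
  post <- settle(p_new, state_p, t_max = protocol$t_max, ...)
  if (!post$settled) {
    return(list(classification = "undecided", amp_pre = amp_pre,
                amp_post = post$amplitude, amplitude_path = NULL,
                pre = pre, post = post$trajectory))
  }
  ## ... plus a quasi-static walk to detect a discontinuous jump
  old_value <- p[[protocol$param]]
  path_vals <- seq(old_value, protocol$new_value,
                   length.out = n_steps + 1)[-1]
  state <- state_p
  amps <- amp_pre
  cls <- "smooth"
  for (v in path_vals) {
    pi <- p
    pi[[protocol$param]] <- v
    st <- settle(pi, state, window = 100, t_max = 600, ...)
    if (st$domain_exit || !st$settled) { cls <- "undecided"; break }
    amps <- c(amps, st$amplitude)
    state <- st$state
    if (jumped(amps[length(amps) - 1], amps[length(amps)])) {
      cls <- "catastrophic"
      break
    }
  }
  list(classification = cls, amp_pre = amp_pre,
       amp_post = post$amplitude, amplitude_path = amps, pre = pre,
       post = post$trajectory)
}

#' Which attractor does an initial condition converge to?
#'
#' For bistable (region III) parameters: integrates until the
#' trajectory is demonstrably near the stable equilibrium (trailing
#' amplitude below \code{eq_tol}) or on the stable cycle (trailing
#' amplitude within \code{cycle_rtol} of the cycle's amplitude).
#'
#' @param p parameter list.
#' @param state0 initial state.
#' @param eq the stable \code{equilibrium}.
#' @param cycle the stable \code{limit_cycle}.
#' @param t_max give up after this many years.
#' @param eq_tol,cycle_rtol decision tolerances.
#' @param ... forwarded to the integrator.
#' @return \code{"equilibrium"}, \code{"cycle"} or \code{"undecided"}.
#' @export
basin_membership <- function(p, state0, eq, cycle, t_max = 2000,
                             eq_tol = 1e-4, cycle_rtol = 0.05, ...) {
  state <- state0
  t_done <- 0
  while (t_done < t_max) {
    tr <- integrate_model(p, state, c(0, 100), n_out = 401, ...)
    if (isTRUE(attr(tr, "domain_exit"))) return("undecided")
    amp <- tail_amplitude(tr, 0.5)
    state <- as.numeric(tr[nrow(tr), c("f", "x")])
    t_done <- t_done + 100
    d_eq <- sqrt(sum((state - eq$state)^2))
    if (amp < eq_tol && d_eq < 0.05) return("equilibrium")
    if (abs(amp - cycle$amplitude) < cycle_rtol * cycle$amplitude) {
      return("cycle")
    }
  }
  "undecided"
}
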