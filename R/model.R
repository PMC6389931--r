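## Coupled forest-grassland / opinion model and its derivative tensors.
##
## State is (f, x): forest fraction and fraction of people preferring
## forest. Grassland is the derived quantity g = 1 - f. f = 1 is a
## singular limit of the recruitment switch (f/(1-f) diverges), so all
## evaluations are guarded at f <= 1 - 1e-9.

F_MAX <- 1 - 1e-9

check_f_domain <- function(f) {
  bad <- which(!is.finite(f) | f < 0 | f > F_MAX)
  if (length(bad) > 0) {
    stop("forest fraction out of domain [0, 1): f = ", f[bad[1]])
  }
  invisible(f)
}

#' Fire-mediated forest recruitment rate
#'
#' The sigmoidal switch \eqn{w(f) = c / (1 + e^{-k f/(1-f) + b})}: sparse
#' forest regenerates very slowly because fire suppresses saplings, while
#' dense forest shades out flammable grass and recruits at nearly the
#' maximum rate \code{c}. The transition is almost sharp, with steepness
#' controlled by \code{k} and offset by \code{b}.
#'
#' @param f forest fraction(s), in \eqn{[0, 1)}.
#' @param p a \code{\link{param_set}}.
#' @return recruitment rate(s), strictly increasing in \code{f} and
#'   bounded in \eqn{(0, c)}.
#' @examples
#' p <- param_set(k = 10.03)
#' recruitment_rate(0.5, p)  # = 1 / (1 + exp(0.97))
#' @export
recruitment_rate <- function(f, p) {
  check_f_domain(f)
  p$c * stats::plogis(p$k * f / (1 - f) - p$b)
}

#' Perceived value of forest relative to grassland
#'
#' \eqn{u(f) = r (1-f)^m - q f^n}. Positive when forest is rare (scarcity
#' raises its perceived value), negative when abundant. With the default
#' gains and exponents this is \eqn{1 - 2f}.
#'
#' @param f forest fraction(s), in \eqn{[0, 1]}.
#' @param p a \code{\link{param_set}}.
#' @return signed perceived value(s).
#' @export
perceived_value <- function(f, p) {
  if (any(!is.finite(f) | f < 0 | f > 1)) {
    stop("forest fraction out of domain [0, 1]: f = ",
         f[which(!is.finite(f) | f < 0 | f > 1)[1]])
  }
  p$r * (1 - f)^p$m - p$q * f^p$n
}

#' Human feedback on the landscape
#'
#' \eqn{J(x) = h (1 - 2x)}. The feedback enters the forest equation with a
#' minus sign, so a forest-preferring majority (x > 1/2) gives -J(x) > 0,
#' i.e. net reforestation; a grassland-preferring majority deforests.
#'
#' @param x fraction(s) of people preferring forest, in \eqn{[0, 1]}.
#' @param p a \code{\link{param_set}}.
#' @return feedback rate(s) (per year).
#' @export
human_feedback <- function(x, p) {
  p$h * (1 - 2 * x)
}

#' Right-hand side of the coupled model
#'
#' \deqn{df/dt = w(f) (1-f) f - \nu f - J(x)}
#' \deqn{dx/dt = s x (1-x) u(f)}
#'
#' @param state numeric 2-vector \code{c(f, x)}.
#' @param p a \code{\link{param_set}}.
#' @return numeric 2-vector of time derivatives (per year).
#' @examples
#' p <- param_set(k = 9.946, nu = 1.906)
#' mosaic_rhs(c(0.5, 0.722), p)  # near zero: a printed Bautin point
#' @export
mosaic_rhs <- function(state, p) {
  f <- state[1]; x <- state[2]
  w <- recruitment_rate(f, p)
  c(w * (1 - f) * f - p$nu * f - human_feedback(x, p),
    p$s * x * (1 - x) * perceived_value(f, p))
}

#' Uncoupled 1D forest model
#'
#' \eqn{df/dt = w(f) f (1-f) - \nu f}: the forest equation without the
#' human feedback term. \code{mosaic_rhs} with h = 0 has this as its
#' first component.
#'
#' @param f forest fraction(s), in \eqn{[0, 1)}.
#' @param p a \code{\link{param_set}}.
#' @return time derivative(s) of the forest fraction.
#' @export
forest_only_rhs <- function(f, p) {
  recruitment_rate(f, p) * f * (1 - f) - p$nu * f
}

## Derivatives of the logistic sigmoid S(z) = 1/(1+exp(-z)) wrt z.
sigmoid_derivs <- function(z) {
  S <- stats::plogis(z)
  s1 <- S * (1 - S)
  list(S = S, d1 = s1, d2 = s1 * (1 - 2 * S),
       d3 = s1 * (1 - 6 * S + 6 * S^2))
}

#' Analytic derivative bundle of the coupled model
#'
#' Value, Jacobian, and the symmetric second- and third-order derivative
#' tensors of \code{\link{mosaic_rhs}} at a state. The tensors are exact
#' closed forms (chain rule through the sigmoid switch); they feed the
#' first-Lyapunov-coefficient computation, where third-order accuracy
#' decides the criticality sign near Bautin points.
#'
#' @param state numeric 2-vector \code{c(f, x)}, interior
#'   (\eqn{0 < f < 1}, \eqn{0 \le x \le 1}).
#' @param p a \code{\link{param_set}}.
#' @return an object of class \code{derivative_bundle}: list with
#'   \code{value} (2-vector), \code{jacobian} (2 x 2), \code{second}
#'   (2 x 2 x 2 array, \code{second[i, j, l]} = d2 F_i / d u_j d u_l) and
#'   \code{third} (2 x 2 x 2 x 2 array), both symmetric in their trailing
#'   indices.
#' @export
mosaic_derivatives <- function(state, p) {
  f <- state[1]; x <- state[2]
  check_f_domain(f)
  omf <- 1 - f
  sg <- sigmoid_derivs(p$k * f / omf - p$b)
  z1 <- p$k / omf^2
  z2 <- 2 * p$k / omf^3
  z3 <- 6 * p$k / omf^4
  w  <- p$c * sg$S
  w1 <- p$c * sg$d1 * z1
  w2 <- p$c * (sg$d2 * z1^2 + sg$d1 * z2)
  w3 <- p$c * (sg$d3 * z1^3 + 3 * sg$d2 * z1 * z2 + sg$d1 * z3)
  ## phi(f) = w(f) f (1 - f)
  pp <- f * omf; p1 <- 1 - 2 * f; p2 <- -2
  phi1 <- w1 * pp + w * p1
  phi2 <- w2 * pp + 2 * w1 * p1 + w * p2
  phi3 <- w3 * pp + 3 * w2 * p1 + 3 * w1 * p2
  ## u(f) = r (1-f)^m - q f^n and derivatives (terms with a vanishing
  ## factorial coefficient are dropped to avoid 0 * Inf at the ends)
  pw <- function(base, e) if (e < 0 && base <= 0) 0 else base^e
  m <- p$m; n <- p$n
  u  <- p$r * pw(omf, m) - p$q * pw(f, n)
  u1 <- -p$r * m * pw(omf, m - 1) - p$q * n * pw(f, n - 1)
  u2 <- p$r * m * (m - 1) * pw(omf, m - 2) -
    p$q * n * (n - 1) * pw(f, n - 2)
  u3 <- -p$r * m * (m - 1) * (m - 2) * pw(omf, m - 3) -
    p$q * n * (n - 1) * (n - 2) * pw(f, n - 3)
  X <- x * (1 - x); X1 <- 1 - 2 * x; X2 <- -2
  s <- p$s
  value <- c(w * pp - p$nu * f - p$h * (1 - 2 * x), s * X * u)
  jac <- matrix(c(phi1 - p$nu, 2 * p$h,
                  s * X * u1,  s * X1 * u), 2, 2, byrow = TRUE)
  B <- array(0, c(2, 2, 2))
  B[1, 1, 1] <- phi2
  B[2, 1, 1] <- s * X * u2
  B[2, 1, 2] <- B[2, 2, 1] <- s * X1 * u1
  B[2, 2, 2] <- s * X2 * u
  C3 <- array(0, c(2, 2, 2, 2))
  C3[1, 1, 1, 1] <- phi3
  C3[2, 1, 1, 1] <- s * X * u3
  C3[2, 1, 1, 2] <- C3[2, 1, 2, 1] <- C3[2, 2, 1, 1] <- s * X1 * u2
  C3[2, 1, 2, 2] <- C3[2, 2, 1, 2] <- C3[2, 2, 2, 1] <- s * X2 * u1
  derivative_bundle(value, jac, B, C3)
}

derivative_bundle <- function(value, jacobian, second, third) {
  structure(list(value = value, jacobian = jacobian,
                 second = second, third = third),
            class = "derivative_bundle")
}

#' Apply the second-order derivative form B(u, v)
#'
#' @param d a \code{derivative_bundle}.
#' @param u,v numeric 2-vectors.
#' @return numeric 2-vector, component i equal to
#'   \eqn{\sum_{jl} B_{ijl} u_j v_l}.
#' @export
bilinear_form <- function(d, u, v) {
  o <- outer(u, v)
  c(sum(d$second[1, , ] * o), sum(d$second[2, , ] * o))
}

#' Apply the third-order derivative form C(u, v, w)
#'
#' @param d a \code{derivative_bundle}.
#' @param u,v,w numeric 2-vectors.
#' @return numeric 2-vector.
#' @export
trilinear_form <- function(d, u, v, w) {
  o <- outer(outer(u, v), w)
  c(sum(d$third[1, , , ] * o), sum(d$third[2, , , ] * o))
}

## ---- planar ODE system abstraction ------------------------------------
## A system bundles the rhs, its analytic derivative bundle, a default
## Poincare section builder and an optional state-domain guard, so the
## continuation / cycle machinery is agnostic of whether it runs on the
## mosaic model or on a normal-form benchmark.

new_ode_system <- function(name, rhs, derivs, section,
                           domain_margin = NULL, vj = NULL,
                           truth = NULL) {
  if (is.null(vj)) {
    vj <- function(state, p) {
      d <- derivs(state, p)
      list(value = d$value, jacobian = d$jacobian)
    }
  }
  structure(list(name = name, rhs = rhs, derivs = derivs,
                 section = section, domain_margin = domain_margin,
                 vj = vj, truth = truth),
            class = "ode_system")
}

## continuous signed distance to the state domain boundary (> 0 inside);
## systems without a guard are unbounded
sys_margin <- function(sys, state) {
  if (is.null(sys$domain_margin)) 1 else sys$domain_margin(state)
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> ", x$name, "\n", sep = "")
  invisible(x)
}

#' The forest-grassland mosaic model as a continuable system
#'
#' Wraps \code{\link{mosaic_rhs}} and \code{\link{mosaic_derivatives}}
#' into the planar-system interface shared with the normal-form
#' benchmarks, including the default Poincare section (the vertical line
#' f = 1/2 through the interior equilibrium, crossed upwards in f).
#'
#' @return an \code{ode_system}.
#' @export
mosaic_system <- function() {
  new_ode_system(
    name = "mosaic",
    rhs = mosaic_rhs,
    derivs = mosaic_derivatives,
    vj = mosaic_vj,
    section = function(p) {
      eq <- interior_equilibrium(p)
      if (is.null(eq)) stop("no interior equilibrium at these parameters")
      poincare_section(center = eq$state, normal = c(1, 0),
                       direction = c(0, 1))
    },
    domain_margin = function(state) {
      min(state[1] + 0.05, (1 - 1e-6) - state[1])
    }
  )
}

## Value and Jacobian only, tolerant of slight domain excursions: used
## inside integrators, whose root-bracketing may probe marginally
## outside [0, 1) before the domain-exit event is located.
mosaic_vj <- function(state, p) {
  f <- min(state[1], F_MAX)
  x <- state[2]
  omf <- 1 - f
  sg <- sigmoid_derivs(p$k * f / omf - p$b)
  z1 <- p$k / omf^2
  w <- p$c * sg$S
  w1 <- p$c * sg$d1 * z1
  pp <- f * omf; p1 <- 1 - 2 * f
  phi1 <- w1 * pp + w * p1
  fu <- min(max(f, 0), 1); omfu <- 1 - fu   # u(f) only defined on [0,1]
  pw <- function(base, e) if (e < 0 && base <= 0) 0 else base^e
  u <- p$r * pw(omfu, p$m) - p$q * pw(fu, p$n)
  u1 <- -p$r * p$m * pw(omfu, p$m - 1) - p$q * p$n * pw(fu, p$n - 1)
  X <- x * (1 - x); X1 <- 1 - 2 * x
  list(value = c(w * pp - p$nu * f - p$h * (1 - 2 * x), p$s * X * u),
       jacobian = matrix(c(phi1 - p$nu, 2 * p$h,
                           p$s * X * u1, p$s * X1 * u),
                         2, 2, byrow = TRUE))
}
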