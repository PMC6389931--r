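## Normal-form benchmark systems with analytically known bifurcation
## structure. They expose the same interface as the mosaic model so every
## numerical stage (continuation, Hopf detection, l1, cycle continuation,
## LPC detection) can be validated against closed forms.

#' Hopf normal-form benchmark system
#'
#' The planar system
#' \deqn{\dot x = \mu x - \omega y + a\, x (x^2 + y^2)}
#' \deqn{\dot y = \omega x + \mu y + a\, y (x^2 + y^2)}
#' with cubic radial coefficient \code{a = cubic_sign}. The origin is an
#' equilibrium with eigenvalues \eqn{\mu \pm i\omega}; the Hopf point sits
#' exactly at \eqn{\mu = 0} with first Lyapunov coefficient of sign
#' \code{cubic_sign}. For \code{cubic_sign = -1} and \eqn{\mu > 0} the
#' stable limit cycle is the circle of radius \eqn{\sqrt\mu}, period
#' \eqn{2\pi/\omega}.
#'
#' Ground truths are attached under \code{$truth}: \code{l1_sign},
#' \code{cycle_radius(mu)}, \code{period}.
#'
#' @param omega angular frequency, > 0.
#' @param cubic_sign -1 (supercritical) or +1 (subcritical).
#' @return an \code{ode_system}; its parameter list is
#'   \code{list(mu = ..., omega = ..., a = cubic_sign)}.
#' @export
hopf_normal_form <- function(omega = 1, cubic_sign = -1) {
  stopifnot(omega > 0, cubic_sign %in% c(-1, 1))
  truth <- list(
    l1_sign = cubic_sign,
    cycle_radius = function(mu) {
      if (cubic_sign * mu < 0) sqrt(-mu / cubic_sign) else NA_real_
    },
    period = 2 * pi / omega,
    hopf_mu = 0
  )
  new_ode_system(
    name = "hopf_nf",
    rhs = function(state, p) {
      x <- state[1]; y <- state[2]; rho <- x^2 + y^2
      c(p$mu * x - p$omega * y + p$a * x * rho,
        p$omega * x + p$mu * y + p$a * y * rho)
    },
    derivs = function(state, p) {
      x <- state[1]; y <- state[2]; a <- p$a; rho <- x^2 + y^2
      value <- c(p$mu * x - p$omega * y + a * x * rho,
                 p$omega * x + p$mu * y + a * y * rho)
      jac <- matrix(c(p$mu + a * (3 * x^2 + y^2), -p$omega + 2 * a * x * y,
                      p$omega + 2 * a * x * y,  p$mu + a * (x^2 + 3 * y^2)),
                    2, 2, byrow = TRUE)
      B <- array(0, c(2, 2, 2))
      B[1, 1, 1] <- 6 * a * x
      B[1, 1, 2] <- B[1, 2, 1] <- 2 * a * y
      B[1, 2, 2] <- 2 * a * x
      B[2, 1, 1] <- 2 * a * y
      B[2, 1, 2] <- B[2, 2, 1] <- 2 * a * x
      B[2, 2, 2] <- 6 * a * y
      C3 <- array(0, c(2, 2, 2, 2))
      C3[1, 1, 1, 1] <- 6 * a
      C3[1, 1, 2, 2] <- C3[1, 2, 1, 2] <- C3[1, 2, 2, 1] <- 2 * a
      C3[2, 1, 1, 2] <- C3[2, 1, 2, 1] <- C3[2, 2, 1, 1] <- 2 * a
      C3[2, 2, 2, 2] <- 6 * a
      derivative_bundle(value, jac, B, C3)
    },
    section = function(p) {
      poincare_section(center = c(0, 0), normal = c(0, 1),
                       direction = c(1, 0))
    },
    truth = truth
  )
}

#' Bautin normal-form benchmark system
#'
#' The planar system whose radial part is
#' \eqn{\dot r = \beta_1 r + \beta_2 r^3 - r^5} (angular speed 1):
#' \deqn{\dot x = \beta_1 x - y + \beta_2 x \rho - x \rho^2, \quad
#'       \dot y = x + \beta_1 y + \beta_2 y \rho - y \rho^2}
#' with \eqn{\rho = x^2 + y^2}. The Hopf line is \eqn{\beta_1 = 0}, the
#' first Lyapunov coefficient there has the sign of \eqn{\beta_2}, the
#' Bautin point sits at the origin of the \eqn{(\beta_1, \beta_2)} plane,
#' cycles have radii \eqn{r^2 = (\beta_2 \pm \sqrt{\beta_2^2 +
#' 4\beta_1})/2}, and the fold-of-cycles (LPC) curve is
#' \eqn{\beta_1 = -\beta_2^2/4} for \eqn{\beta_2 > 0}.
#'
#' @return an \code{ode_system}; parameter list
#'   \code{list(beta1 = ..., beta2 = ...)}. Ground-truth closed forms are
#'   attached under \code{$truth}.
#' @export
bautin_normal_form <- function() {
  truth <- list(
    hopf_beta1 = 0,
    bautin = c(beta1 = 0, beta2 = 0),
    lpc_beta1 = function(beta2) -beta2^2 / 4,
    cycle_radius2 = function(beta1, beta2) {
      disc <- beta2^2 + 4 * beta1
      if (disc < 0) return(c(NA_real_, NA_real_))
      r2 <- c((beta2 - sqrt(disc)) / 2, (beta2 + sqrt(disc)) / 2)
      r2[r2 <= 0] <- NA_real_
      r2  # (inner/unstable, outer/stable) where defined
    },
    fold_radius2 = function(beta2) beta2 / 2
  )
  new_ode_system(
    name = "bautin_nf",
    rhs = function(state, p) {
      x <- state[1]; y <- state[2]; rho <- x^2 + y^2
      rad <- p$beta1 + p$beta2 * rho - rho^2
      c(rad * x - y, x + rad * y)
    },
    derivs = function(state, p) {
      x <- state[1]; y <- state[2]
      b1 <- p$beta1; b2 <- p$beta2
      rho <- x^2 + y^2
      rad <- b1 + b2 * rho - rho^2
      value <- c(rad * x - y, x + rad * y)
      ## d(x*rho)/d..., d(x*rho^2)/d... assembled termwise
      jac <- matrix(c(
        b1 + b2 * (3 * x^2 + y^2) - (5 * x^4 + 6 * x^2 * y^2 + y^4),
        -1 + 2 * b2 * x * y - (4 * x^3 * y + 4 * x * y^3),
        1 + 2 * b2 * x * y - (4 * x^3 * y + 4 * x * y^3),
        b1 + b2 * (x^2 + 3 * y^2) - (x^4 + 6 * x^2 * y^2 + 5 * y^4)),
        2, 2, byrow = TRUE)
      B <- array(0, c(2, 2, 2))
      B[1, 1, 1] <- 6 * b2 * x - (20 * x^3 + 12 * x * y^2)
      B[1, 1, 2] <- B[1, 2, 1] <- 2 * b2 * y - (12 * x^2 * y + 4 * y^3)
      B[1, 2, 2] <- 2 * b2 * x - (4 * x^3 + 12 * x * y^2)
      B[2, 1, 1] <- 2 * b2 * y - (12 * x^2 * y + 4 * y^3)
      B[2, 1, 2] <- B[2, 2, 1] <- 2 * b2 * x - (4 * x^3 + 12 * x * y^2)
      B[2, 2, 2] <- 6 * b2 * y - (20 * y^3 + 12 * x^2 * y)
      C3 <- array(0, c(2, 2, 2, 2))
      c111 <- 6 * b2 - (60 * x^2 + 12 * y^2)      # d3(F1)/dx3
      c112 <- -24 * x * y                          # d3(F1)/dx2 dy
      c122 <- 2 * b2 - (12 * x^2 + 12 * y^2)       # d3(F1)/dx dy2
      c222 <- -(24 * x * y)                        # d3(F1)/dy3
      C3[1, 1, 1, 1] <- c111
      C3[1, 1, 1, 2] <- C3[1, 1, 2, 1] <- C3[1, 2, 1, 1] <- c112
      C3[1, 1, 2, 2] <- C3[1, 2, 1, 2] <- C3[1, 2, 2, 1] <- c122
      C3[1, 2, 2, 2] <- c222
      ## F2 is F1 with x <-> y by symmetry of the radial construction
      d111 <- -24 * x * y
      d112 <- 2 * b2 - (12 * x^2 + 12 * y^2)
      d122 <- -24 * x * y
      d222 <- 6 * b2 - (60 * y^2 + 12 * x^2)
      C3[2, 1, 1, 1] <- d111
      C3[2, 1, 1, 2] <- C3[2, 1, 2, 1] <- C3[2, 2, 1, 1] <- d112
      C3[2, 1, 2, 2] <- C3[2, 2, 1, 2] <- C3[2, 2, 2, 1] <- d122
      C3[2, 2, 2, 2] <- d222
      derivative_bundle(value, jac, B, C3)
    },
    section = function(p) {
      poincare_section(center = c(0, 0), normal = c(0, 1),
                       direction = c(1, 0))
    },
    truth = truth
  )
}
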