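## Base-graphics displays following the field's plotting conventions:
## solid/dashed lines for stable/unstable equilibria, filled/empty
## markers for stable/unstable limit cycles.

#' @export
plot.equilibrium_branch <- function(x, var = c("x", "f"), ...) {
  var <- match.arg(var)
  pts <- x$points
  plot(pts$param, pts[[var]], type = "n", xlab = x$param_name,
       ylab = var, ...)
  stable <- pts$stability == "stable"
  runs <- rle(stable)
  i0 <- 1
  for (j in seq_along(runs$lengths)) {
    idx <- i0:(i0 + runs$lengths[j] - 1)
    graphics::lines(pts$param[idx], pts[[var]][idx],
                    lty = if (runs$values[j]) 1 else 2, lwd = 2)
    i0 <- i0 + runs$lengths[j]
  }
  invisible(x)
}

#' @export
plot.cycle_branch <- function(x, ...) {
  pts <- x$points
  plot(pts$param, pts$amplitude_f, type = "n", xlab = x$param_name,
       ylab = "cycle amplitude (f)", ...)
  st <- pts$stability == "stable"
  graphics::points(pts$param[st], pts$amplitude_f[st], pch = 19,
                   cex = 0.5)
  graphics::points(pts$param[!st], pts$amplitude_f[!st], pch = 1,
                   cex = 0.5)
  invisible(x)
}

#' @export
plot.limit_cycle <- function(x, add = FALSE, ...) {
  lty <- if (x$stability == "stable") 1 else 2
  if (!add) {
    plot(x$mesh$f, x$mesh$x, type = "l", lty = lty, lwd = 2,
         col = "darkgreen", xlab = "f", ylab = "x", ...)
  } else {
    graphics::lines(x$mesh$f, x$mesh$x, lty = lty, lwd = 2,
                    col = "darkgreen")
  }
  invisible(x)
}

#' @export
plot.trajectory <- function(x, phase = FALSE, ...) {
  if (phase) {
    plot(x$f, x$x, type = "l", xlab = "f", ylab = "x", ...)
  } else {
    plot(x$t, x$f, type = "l", xlab = "t (years)", ylab = "f",
         ylim = range(c(x$f, x$x)), ...)
    graphics::lines(x$t, x$x, col = "grey40")
    graphics::legend("topright", legend = c("f", "x"),
                     col = c("black", "grey40"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
plot.regime_map <- function(x, ...) {
  plot(NA, xlim = x$k_range, ylim = x$nu_range, xlab = "k",
       ylab = expression(nu), ...)
  hp <- x$hopf_curve$points
  inside <- hp$nu >= x$nu_range[1] & hp$nu <= x$nu_range[2]
  graphics::lines(hp$k[inside], hp$nu[inside], lwd = 2)
  for (cv in x$lpc_curves) {
    graphics::lines(cv$points$k, cv$points$nu, lwd = 2, col = "blue")
  }
  for (g in Filter(Negate(is.null), x$bautin)) {
    graphics::points(g$k, g$nu, pch = 17, cex = 1.3, col = "red")
  }
  if (!is.null(x$grid)) {
    cols <- c(I = NA, II = "grey80", III = "lightblue",
              boundary = "orange", other = "pink")
    graphics::points(x$grid$k, x$grid$nu, pch = 15, cex = 0.4,
                     col = cols[x$grid$label])
  }
  invisible(x)
}
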