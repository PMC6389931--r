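#' Model parameter set
#'
#' Bundles the constants of the coupled forest-grassland / opinion model.
#' The forest recruitment switch is \eqn{w(f) = c / (1 + e^{-k f/(1-f) + b})},
#' the perceived-value function is \eqn{u(f) = r (1-f)^m - q f^n}, and the
#' human feedback term is \eqn{J(x) = h (1 - 2x)}.
#'
#' @param b sharpness offset of the recruitment switch (dimensionless).
#' @param c maximum forest recruitment rate (per year); must be positive.
#' @param k fire-mediated activation steepness (dimensionless); must be
#'   positive.
#' @param nu natural forest-to-grassland conversion rate (per year);
#'   non-negative.
#' @param s social learning rate (per year); non-negative.
#' @param h magnitude of human influence on the landscape (per year);
#'   non-negative.
#' @param r,q gains for the perceived value of forest and grassland
#'   (dimensionless, non-negative).
#' @param m,n shape exponents of the perceived-value function; both at
#'   least 1.
#'
#' @return An object of class \code{param_set}: a named list with the ten
#'   model constants.
#' @examples
#' p <- param_set(k = 10, nu = 0.5)
#' p$k
#' @export
param_set <- function(b = 11, c = 1, k = 10, nu = 1, s = 10, h = 2,
                      r = 1, q = 1, m = 1, n = 1) {
  p <- list(b = b, c = c, k = k, nu = nu, s = s, h = h,
            r = r, q = q, m = m, n = n)
  validate_param_set(p)
}

param_names <- c("b", "c", "k", "nu", "s", "h", "r", "q", "m", "n")

validate_param_set <- function(p) {
  if (!all(param_names %in% names(p))) {
    stop("missing parameter(s): ",
         paste(setdiff(param_names, names(p)), collapse = ", "))
  }
  extra <- setdiff(names(p), param_names)
  if (length(extra) > 0) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  }
  p <- p[param_names]
  for (nm in param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number")
    }
  }
  if (p$c <= 0) stop("c must be > 0 (got ", p$c, ")")
  if (p$k <= 0) stop("k must be > 0 (got ", p$k, ")")
  if (p$nu < 0) stop("nu must be >= 0 (got ", p$nu, ")")
  if (p$s < 0) stop("s must be >= 0 (got ", p$s, ")")
  if (p$h < 0) stop("h must be >= 0 (got ", p$h, ")")
  if (p$r < 0 || p$q < 0) stop("r and q must be >= 0")
  if (p$m < 1 || p$n < 1) stop("m and n must be >= 1")
  class(p) <- "param_set"
  p
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>\n")
  cat(sprintf("  recruitment: b = %g, c = %g, k = %g\n", x$b, x$c, x$k))
  cat(sprintf("  conversion:  nu = %g\n", x$nu))
  cat(sprintf("  social:      s = %g, h = %g\n", x$s, x$h))
  cat(sprintf("  perception:  r = %g, q = %g, m = %g, n = %g", x$r, x$q,
              x$m, x$n))
  if (has_default_u(x)) cat("  [u(f) = 1 - 2f]")
  cat("\n")
  invisible(x)
}

#' Modify one parameter, revalidating the set
#'
#' @param p a \code{param_set}.
#' @param name parameter name.
#' @param value new value.
#' @return the modified, revalidated \code{param_set}.
#' @export
set_param <- function(p, name, value) {
  if (!name %in% param_names) stop("unknown parameter: ", name)
  p[[name]] <- value
  validate_param_set(unclass(p))
}

#' Does the parameter set use the default perceived-value shape?
#'
#' With r = q = 1 and m = n = 1 the perceived value reduces to
#' u(f) = 1 - 2f, so the interior equilibrium family sits exactly at
#' f = 1/2. Several closed forms (Hopf locus, interior equilibrium) are
#' only available in that case.
#'
#' @param p a \code{param_set}.
#' @return logical.
#' @export
has_default_u <- function(p) {
  p$r == 1 && p$q == 1 && p$m == 1 && p$n == 1
}

#' Read a parameter set from a YAML or JSON config file
#'
#' The file must contain a flat key-value mapping; keys not naming a model
#' parameter are rejected. Missing keys fall back to the defaults of
#' \code{\link{param_set}}.
#'
#' @param path file path; format chosen by extension (\code{.json} reads
#'   JSON, anything else YAML).
#' @return a \code{param_set}.
#' @export
read_param_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) raw <- as.list(raw)
  extra <- setdiff(names(raw), param_names)
  if (length(extra) > 0) {
    stop("unknown key(s) in parameter config: ",
         paste(extra, collapse = ", "))
  }
  do.call(param_set, raw)
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param p a \code{param_set}.
#' @param path output path; format chosen by extension as in
#'   \code{\link{read_param_config}}.
#' @return \code{path}, invisibly.
#' @export
write_param_config <- function(p, path) {
  stopifnot(inherits(p, "param_set"))
  x <- unclass(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
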