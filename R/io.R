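## Structured outputs (CSV branches, JSON bifurcation records) and the
## config-driven task runner behind the command-line script.

#' Write an equilibrium branch to CSV
#'
#' Columns: arclength, param, f, x, re_lambda1, im_lambda1, re_lambda2,
#' im_lambda2, stability.
#'
#' @param branch an \code{equilibrium_branch}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  cols <- c("arclength", "param", "f", "x", "re_lambda1", "im_lambda1",
            "re_lambda2", "im_lambda2", "stability")
  utils::write.csv(branch$points[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a cycle branch to CSV
#'
#' Columns: param, period, amplitude_f, amplitude_x, stability.
#'
#' @param branch a \code{cycle_branch}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_cycle_branch_csv <- function(branch, path) {
  cols <- c("param", "period", "amplitude_f", "amplitude_x", "stability")
  utils::write.csv(branch$points[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write one orbit to CSV (t, f, x)
#'
#' @param x a \code{limit_cycle} (its mesh) or a \code{trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_orbit_csv <- function(x, path) {
  df <- if (inherits(x, "limit_cycle")) x$mesh else
    as.data.frame(x)[, c("t", "f", "x")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

bif_record <- function(x) {
  pr <- function(v) as.numeric(signif(v, 4))
  if (inherits(x, "hopf_point")) {
    list(type = "hopf", f = x$state[[1]], x = x$state[[2]],
         k = x$params$k, nu = x$params$nu, omega = x$omega, l1 = x$l1,
         criticality = x$criticality,
         printed = list(k = pr(x$params$k), nu = pr(x$params$nu),
                        x = pr(x$state[[2]])))
  } else if (inherits(x, "bautin_point")) {
    list(type = "bautin", f = x$f, x = x$x, k = x$k, nu = x$nu,
         omega = x$omega, l1 = x$l1_residual,
         printed = list(k = pr(x$k), nu = pr(x$nu), x = pr(x$x)))
  } else if (inherits(x, "lpc_point")) {
    list(type = "lpc", param_name = x$param_name, param = x$param,
         period = x$period, amplitude_f = x$cycle$amplitude,
         multiplier = x$multiplier,
         printed = list(param = pr(x$param)))
  } else {
    stop("no JSON record for class ", paste(class(x), collapse = "/"))
  }
}

#' Write bifurcation points to JSON
#'
#' Serializes Hopf, Bautin and LPC points as an array of records
#' \code{\{type, f, x, k, nu, omega, l1, criticality, ...\}} at full
#' precision, plus a \code{printed} field rounded to 4 significant
#' figures.
#'
#' @param points list of \code{hopf_point} / \code{bautin_point} /
#'   \code{lpc_point} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bif_points_json <- function(points, path) {
  jsonlite::write_json(lapply(points, bif_record), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a regime-map classification grid to CSV
#'
#' @param map a \code{regime_map} (uses its curve-based classifier).
#' @param path output file.
#' @param n grid resolution per axis.
#' @return the grid data frame, invisibly.
#' @export
write_regime_csv <- function(map, path, n = 60) {
  ks <- seq(map$k_range[1], map$k_range[2], length.out = n)
  nus <- seq(map$nu_range[1], map$nu_range[2], length.out = n)
  grid <- expand.grid(k = ks, nu = nus)
  grid$label <- mapply(map$classify, grid$k, grid$nu)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(grid)
}

## ---- task runner -------------------------------------------------------

run_tasks <- c("equilibria", "branch1d", "diagram2d", "cycles", "regime",
               "simulate", "shift")

#' Validate a run configuration
#'
#' A run config is a list (typically read from YAML) with fields:
#' \code{task} (one of equilibria, branch1d, diagram2d, cycles, regime,
#' simulate, shift), \code{params} (model parameter overrides),
#' \code{options} (task-specific settings), \code{out_dir} and
#' \code{seed}. Unknown fields are rejected.
#'
#' @param config list or path to a YAML/JSON file.
#' @return the validated config (class \code{run_config}).
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  known <- c("task", "params", "options", "out_dir", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  }
  if (is.null(config$task) || !config$task %in% run_tasks) {
    stop("config$task must be one of: ", paste(run_tasks, collapse = ", "))
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  config$params <- do.call(param_set,
                           as.list(config$params %||% list()))
  config$options <- config$options %||% list()
  config$seed <- config$seed %||% 1L
  structure(config, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

opt <- function(cfg, name, default) cfg$options[[name]] %||% default

#' Execute a configured analysis task
#'
#' Runs the named task and writes its artifacts (CSV branches, JSON
#' bifurcation records, regime grids, trajectories) into
#' \code{out_dir}, along with the fully resolved configuration
#' (\code{resolved_config.yaml}) for reproducibility. All randomness
#' (only used for sampled initial conditions) is seeded from
#' \code{config$seed}, so re-running an identical config reproduces the
#' outputs byte for byte.
#'
#' @param config a \code{\link{run_config}} (or list / file path
#'   coercible to one).
#' @return character vector of the files written, invisibly.
#' @export
run_analysis <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  p <- cfg$params
  sys <- mosaic_system()
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  out <- function(name) file.path(cfg$out_dir, name)

  if (cfg$task == "equilibria") {
    eqs <- c(list(interior_equilibrium(p)), boundary_equilibria(p))
    eqs <- Filter(Negate(is.null), eqs)
    recs <- lapply(eqs, function(e) {
      list(type = e$type, f = e$state[[1]], x = e$state[[2]],
           stability = e$stability,
           eigenvalues = list(re = Re(e$eigenvalues),
                              im = Im(e$eigenvalues)))
    })
    jsonlite::write_json(recs, out("equilibria.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    emit(out("equilibria.json"))
  } else if (cfg$task == "branch1d") {
    range <- opt(cfg, "range", c(5, 20))
    if (length(range) != 2 || range[1] >= range[2]) {
      stop("options$range must be an increasing length-2 interval")
    }
    pname <- opt(cfg, "param", "k")
    eq <- interior_equilibrium(p)
    if (is.null(eq)) stop("no interior equilibrium at the base parameters")
    br <- continue_branch(sys, p, eq$state, pname, range,
                          step = opt(cfg, "step", 0.05),
                          max_step = opt(cfg, "max_step", 0.2))
    write_branch_csv(br, out("branch.csv")); emit(out("branch.csv"))
    hps <- detect_hopf(br)
    pts <- hps
    if (isTRUE(opt(cfg, "cycles", FALSE)) && length(hps) > 0) {
      c0 <- initial_cycle_from_hopf(hps[[1]], sys)
      cb <- continue_cycle_branch(sys, c0, pname, range)
      write_cycle_branch_csv(cb, out("cycle_branch.csv"))
      emit(out("cycle_branch.csv"))
      pts <- c(pts, detect_lpc(cb))
    }
    write_bif_points_json(pts, out("bifpoints.json"))
    emit(out("bifpoints.json"))
  } else if (cfg$task == "diagram2d") {
    k_range <- opt(cfg, "k_range", c(5, 20))
    curve <- trace_hopf_curve(p, k_range)
    utils::write.csv(curve$points, out("hopf_curve.csv"),
                     row.names = FALSE)
    emit(out("hopf_curve.csv"))
    ghs <- Filter(Negate(is.null),
                  list(find_bautin(p, "low_k"), find_bautin(p, "high_k")))
    write_bif_points_json(ghs, out("bifpoints.json"))
    emit(out("bifpoints.json"))
  } else if (cfg$task == "cycles") {
    range <- opt(cfg, "range", c(0.5, 40))
    hps <- hopf_points_on_slice(p, k_range = range)
    if (length(hps) == 0) stop("no Hopf point on this slice")
    c0 <- initial_cycle_from_hopf(hps[[1]], sys)
    cb <- continue_cycle_branch(sys, c0, "k", range)
    write_cycle_branch_csv(cb, out("cycle_branch.csv"))
    emit(out("cycle_branch.csv"))
    write_bif_points_json(c(hps, detect_lpc(cb)), out("bifpoints.json"))
    emit(out("bifpoints.json"))
  } else if (cfg$task == "regime") {
    map <- build_regime_map(
      p, k_range = opt(cfg, "k_range", c(5, 20)),
      nu_range = opt(cfg, "nu_range", c(0.05, 3)),
      with_lpc = opt(cfg, "with_lpc", TRUE),
      verify_n = opt(cfg, "verify_n", 0))
    grid <- write_regime_csv(map, out("regime_grid.csv"),
                             n = opt(cfg, "resolution", 60))
    emit(out("regime_grid.csv"))
    curves <- list(hopf = map$hopf_curve$points,
                   lpc = lapply(map$lpc_curves, function(cv) cv$points),
                   bautin = lapply(Filter(Negate(is.null), map$bautin),
                                   function(g) list(k = g$k, nu = g$nu,
                                                    x = g$x)))
    jsonlite::write_json(curves, out("curves.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    emit(out("curves.json"))
  } else if (cfg$task == "simulate") {
    state0 <- as.numeric(opt(cfg, "state0", c(0.4, 0.6)))
    t_span <- as.numeric(opt(cfg, "t_span", c(0, 500)))
    tr <- integrate_model(p, state0, t_span)
    write_orbit_csv(tr, out("trajectory.csv"))
    emit(out("trajectory.csv"))
  } else if (cfg$task == "shift") {
    proto <- shift_protocol(
      t_perturb = opt(cfg, "t_perturb", 100),
      delta = opt(cfg, "delta", NULL),
      param = opt(cfg, "param", NULL),
      new_value = opt(cfg, "new_value", NULL),
      t_max = opt(cfg, "t_max", 2000))
    res <- shift_experiment(p, as.numeric(opt(cfg, "state0", c(0.5, 0.6))),
                            proto)
    jsonlite::write_json(
      list(classification = res$classification, amp_pre = res$amp_pre,
           amp_post = res$amp_post, amplitude_path = res$amplitude_path),
      out("shift.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(out("shift.json"))
    write_orbit_csv(res$post, out("post_trajectory.csv"))
    emit(out("post_trajectory.csv"))
  }

  resolved <- unclass(cfg)
  resolved$params <- unclass(resolved$params)
  yaml::write_yaml(resolved, out("resolved_config.yaml"))
  emit(out("resolved_config.yaml"))
  invisible(files)
}
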