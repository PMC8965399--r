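CONFIG_KEYS <- c(
  "beta", "sigma", "rho", "alpha_T", "alpha_D", "lambda", "omega", "d",
  "K", "N",
  "seed_density", "t_max", "end_threshold", "rtol", "atol",
  "rho_grid", "d_grid", "peak_threshold", "analytic_overlay",
  "wide_trajectory", "out_dir", "prefix", "verbose"
)

#' Build a validated run configuration
#'
#' Collects model parameters and run options into a single validated list, as
#' used by the command-line entry points [cmd_simulate()], [cmd_phase()] and
#' [cmd_critical_curve()]. Unknown keys are rejected; all model-parameter
#' invariants are checked (via [aware_params()]) before any computation.
#'
#' @param ... Named configuration values. Model parameters (`beta`, `sigma`,
#'   `rho`, `alpha_T`, `alpha_D`, `lambda`, `omega`, `d`, optionally `K`,
#'   `N`) plus run options: `seed_density`, `t_max`, `end_threshold`, `rtol`,
#'   `atol`, `peak_threshold`, `rho_grid` / `d_grid` (numeric vectors or
#'   lists with `from`, `to` and `n` or `by`), `analytic_overlay`,
#'   `wide_trajectory`, `out_dir`, `prefix`, `verbose`.
#' @return A list of class `run_config` with element `params` holding the
#'   validated [aware_params()].
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all configuration entries must be named", call. = FALSE)
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  defaults <- list(seed_density = 5e-6, t_max = 1000, end_threshold = 1e-7,
                   rtol = 1e-8, peak_threshold = 1e-4,
                   analytic_overlay = TRUE, wide_trajectory = FALSE,
                   out_dir = ".", prefix = "awaresir", verbose = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  par_names <- c("beta", "sigma", "rho", "alpha_T", "alpha_D", "lambda",
                 "omega", "d", "K", "N")
  missing <- setdiff(setdiff(par_names, c("K", "N")), names(cfg))
  if (length(missing))
    stop("missing model parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg$params <- do.call(aware_params, cfg[intersect(par_names, names(cfg))])
  if (is.null(cfg$atol)) cfg$atol <- 1e-12 * cfg$params$N
  cfg$rho_grid <- parse_grid(cfg$rho_grid, "rho_grid")
  cfg$d_grid <- parse_grid(cfg$d_grid, "d_grid")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [run_config()].
#' @param ... Overrides applied on top of the file values (e.g. from CLI
#'   flags).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key-value mapping",
                          call. = FALSE)
  cfg <- utils::modifyList(cfg, list(...))
  do.call(run_config, cfg)
}

parse_grid <- function(g, name) {
  if (is.null(g)) return(NULL)
  if (is.numeric(g)) {
    if (!length(g)) stop(sprintf("`%s` must be non-empty", name), call. = FALSE)
    return(as.numeric(g))
  }
  if (is.list(g) && all(c("from", "to") %in% names(g))) {
    if (!is.null(g$n)) return(seq(g$from, g$to, length.out = g$n))
    if (!is.null(g$by)) return(seq(g$from, g$to, by = g$by))
  }
  stop(sprintf("`%s` must be a numeric vector or a list with from/to and n or by",
               name), call. = FALSE)
}

out_path <- function(cfg, suffix) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  file.path(cfg$out_dir, paste0(cfg$prefix, "_", suffix))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run a single simulation and write its outputs
#'
#' Writes the tidy trajectory (`time`, `S`, `I`, `R`, `beta_eff`, `R_e`) as
#' CSV, optionally the full per-compartment matrix as a wide CSV, and the
#' epidemic summary as JSON. Outputs are deterministic: rerunning the same
#' configuration reproduces the files byte for byte.
#'
#' @param config A [run_config()] (or the path to a YAML config file).
#' @return Invisibly, the named vector of files written.
#' @export
cmd_simulate <- function(config) {
  cfg <- as_run_config(config)
  traj <- simulate_epidemic(cfg$params, seed_density = cfg$seed_density,
                            t_max = cfg$t_max, end_threshold = cfg$end_threshold,
                            rtol = cfg$rtol, atol = cfg$atol)
  files <- c(trajectory = out_path(cfg, "trajectory.csv"),
             summary = out_path(cfg, "summary.json"))
  readr::write_csv(tidy(traj), files[["trajectory"]])
  s <- summarize_epidemic(traj)
  write_json_file(
    list(peak_I = s$peak_I, t_peak = s$t_peak, final_S = s$final_S,
         duration = s$duration, total_infected = s$total_infected,
         converged = s$converged,
         regime = classify_regime(s, cfg$params, cfg$peak_threshold)),
    files[["summary"]])
  if (isTRUE(cfg$wide_trajectory)) {
    files <- c(files, compartments = out_path(cfg, "compartments.csv"))
    wide <- as.data.frame(traj$states)
    names(wide) <- compartment_names(cfg$params$K)
    wide <- cbind(time = traj$times, wide)
    readr::write_csv(wide, files[["compartments"]])
  }
  invisible(files)
}

compartment_names <- function(K) {
  dn <- state_dimnames(K)
  idx <- expand.grid(level = dn$level, disease = dn$disease, group = dn$group,
                     stringsAsFactors = FALSE)
  paste0(idx$disease, "_", idx$group, "_", idx$level)
}

#' Run a phase-diagram scan and write its outputs
#'
#' Writes the long-format grid (`rho`, `d`, `t_peak`, `peak_I`, `final_S`,
#' `duration`, `regime`) as CSV and a JSON boundary file holding, per `d`,
#' the numeric boundary estimate and (optionally) the analytic
#' fast-information threshold, plus the critical density `d_M`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the named vector of files written.
#' @export
cmd_phase <- function(config) {
  cfg <- as_run_config(config)
  if (is.null(cfg$rho_grid) || is.null(cfg$d_grid))
    stop("`rho_grid` and `d_grid` are required for a phase scan", call. = FALSE)
  grid <- phase_diagram(cfg$params, rho = cfg$rho_grid, d = cfg$d_grid,
                        peak_threshold = cfg$peak_threshold,
                        seed_density = cfg$seed_density, t_max = cfg$t_max,
                        rtol = cfg$rtol, atol = cfg$atol,
                        verbose = isTRUE(cfg$verbose))
  files <- c(grid = out_path(cfg, "phase_grid.csv"),
             boundary = out_path(cfg, "boundary.json"))
  readr::write_csv(tibble::as_tibble(grid), files[["grid"]])
  bnd <- attr(grid, "boundary")
  out <- list(d = bnd$d, rho_c_numeric = bnd$rho_c_numeric,
              d_M = critical_density(cfg$params))
  if (isTRUE(cfg$analytic_overlay)) {
    ana <- critical_rho_analytic(bnd$d, cfg$params)
    out$rho_c_analytic <- ifelse(ana$achievable, ana$rho_c, "unachievable")
  }
  write_json_file(out, files[["boundary"]])
  invisible(files)
}

#' Tabulate the analytic critical curve and write its outputs
#'
#' Writes the fast-information-limit threshold `rho_c(d)` over the `d` grid
#' as CSV (`d`, `rho_c`, `achievable`, `suppression_at_any_rho`) and a JSON
#' header with the critical density `d_M`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the named vector of files written.
#' @export
cmd_critical_curve <- function(config) {
  cfg <- as_run_config(config)
  d_grid <- if (is.null(cfg$d_grid)) seq(0, 0.95, by = 0.01) else cfg$d_grid
  curve <- critical_curve(cfg$params, d = d_grid)
  files <- c(curve = out_path(cfg, "critical_curve.csv"),
             meta = out_path(cfg, "critical_curve.json"))
  readr::write_csv(dplyr::select(tibble::as_tibble(curve), -"x"),
                   files[["curve"]])
  write_json_file(list(d_M = critical_density(cfg$params),
                       R0 = cfg$params$R0,
                       n_d = length(d_grid)),
                  files[["meta"]])
  invisible(files)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1L)
    return(read_run_config(config))
  stop("`config` must be a run_config or the path to a YAML file",
       call. = FALSE)
}
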