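#' Modify a parameter set
#'
#' Rebuilds an [aware_params()] object with some fields replaced, re-running
#' all validation. Note that the truncation `K` is carried over unchanged
#' unless given explicitly: when scanning `rho` upwards choose a `K` adequate
#' for the largest value scanned (or rebuild with `K = NULL` to re-apply the
#' default rule).
#'
#' @param params An [aware_params()] object.
#' @param ... Named fields to replace (any argument of [aware_params()]).
#' @return A new `aware_params` object.
#' @export
update_params <- function(params, ...) {
  params <- as_aware_params(params)
  fields <- params[c("beta", "sigma", "rho", "alpha_T", "alpha_D",
                     "lambda", "omega", "d", "K", "N")]
  dots <- list(...)
  bad <- setdiff(names(dots), names(fields))
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(aware_params, utils::modifyList(fields, dots))
}

#' Classify an epidemic as suppressed or mitigated
#'
#' An epidemic is labelled `"suppression"` when its infection peak stays
#' strictly below `peak_threshold * N` (behavioural feedback extinguishes the
#' outbreak while it is still small) and `"mitigation"` otherwise (the
#' outbreak runs its course with a reduced, delayed peak). A peak exactly at
#' the threshold counts as mitigation. Simulations that did not reach the end
#' of the epidemic are labelled `"undetermined"`.
#'
#' @param summary A one-row tibble from [summarize_epidemic()].
#' @param params The [aware_params()] used for the simulation (supplies `N`).
#' @param peak_threshold Peak infected density separating the regimes;
#'   default `1e-4`, ten times the standard total seeding `2 * 5e-6`.
#' @return `"suppression"`, `"mitigation"` or `"undetermined"`.
#' @export
classify_regime <- function(summary, params, peak_threshold = 1e-4) {
  params <- as_aware_params(params)
  if (!all(c("peak_I", "converged") %in% names(summary)))
    stop("`summary` must come from summarize_epidemic()", call. = FALSE)
  if (!isTRUE(summary$converged[[1]])) return("undetermined")
  if (summary$peak_I[[1]] / params$N < peak_threshold) "suppression"
  else "mitigation"
}

# t_peak of a single simulation, NA on solver failure
peak_time_at <- function(rho, d, params, seed_density, t_max, ...) {
  p <- update_params(params, rho = rho, d = d)
  tryCatch({
    traj <- simulate_epidemic(p, seed_density = seed_density, t_max = t_max, ...)
    summarize_epidemic(traj)$t_peak
  }, error = function(e) NA_real_)
}

#' Numeric suppression-mitigation boundary at fixed distrusting density
#'
#' Locates the critical intervention effectiveness by maximising the
#' time-to-peak `t_peak(rho)`: at the boundary the behavioural feedback just
#' balances new infections, the infection level plateaus, and the epidemic
#' (and hence the time to its peak) is longest. A coarse grid scan brackets
#' the maximum, then golden-section search refines it. If the maximum sits at
#' the upper end of the search interval, no interior boundary exists there
#' (the regime is mitigation throughout, as for `d > d_M`) and the threshold
#' is reported as unachievable.
#'
#' @param d Distrusting density.
#' @param params An [aware_params()] object (its `rho` and `d` are ignored;
#'   its `K` is used as-is, see [update_params()]).
#' @param interval Search interval for `rho`, within `(0, 1)`.
#' @param coarse_n Number of coarse grid points.
#' @param tol Absolute tolerance on the returned `rho_c`.
#' @param seed_density,t_max Passed to [simulate_epidemic()].
#' @param ... Further arguments to [simulate_epidemic()] (e.g. solver
#'   tolerances).
#' @return A one-row tibble: `d`, `rho_c` (`NA` when unachievable),
#'   `achievable`, `t_peak` at the boundary.
#' @export
critical_rho_numeric <- function(d, params, interval = c(0.02, 0.98),
                                 coarse_n = 13, tol = 0.005,
                                 seed_density = 5e-6, t_max = 1000, ...) {
  params <- as_aware_params(params)
  if (length(interval) != 2L || interval[1] <= 0 || interval[2] >= 1 ||
      interval[1] >= interval[2])
    stop("`interval` must be an increasing pair within (0, 1)", call. = FALSE)
  f <- function(rho) peak_time_at(rho, d, params, seed_density, t_max, ...)

  grid <- seq(interval[1], interval[2], length.out = coarse_n)
  tp <- vapply(grid, f, numeric(1))
  if (all(is.na(tp)))
    stop("all simulations failed on the coarse grid", call. = FALSE)
  idx <- which.max(tp)
  if (idx == length(grid))
    return(tibble::tibble(d = d, rho_c = NA_real_, achievable = FALSE,
                          t_peak = tp[idx]))

  lo <- grid[max(idx - 1L, 1L)]
  hi <- grid[min(idx + 1L, length(grid))]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (is.na(f1) || is.na(f2)) break
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  rho_c <- (lo + hi) / 2
  tibble::tibble(d = d, rho_c = rho_c, achievable = TRUE,
                 t_peak = max(f1, f2, na.rm = TRUE))
}

#' Suppression-mitigation phase diagram over a (rho, d) grid
#'
#' Simulates the full model at every grid cell, summarises each epidemic and
#' labels its regime. The per-column (fixed `d`) numeric boundary estimate —
#' the grid `rho` with the largest time-to-peak, when interior — is attached
#' as the `boundary` attribute.
#'
#' @param params Base [aware_params()] object; `rho` and `d` are overridden
#'   cell by cell (its `K` is used as-is, see [update_params()]).
#' @param rho,d Grid vectors within `(0, 1)` and `[0, 1)`.
#' @param peak_threshold Passed to [classify_regime()].
#' @param seed_density,t_max,... Passed to [simulate_epidemic()].
#' @param verbose Print a progress line per grid column?
#' @return A `phase_grid` tibble with columns `rho`, `d`, `peak_I`, `t_peak`,
#'   `final_S`, `duration`, `regime`, and attribute `boundary` (a tibble of
#'   `d`, `rho_c_numeric`). Plot with [ggplot2::autoplot()].
#' @export
phase_diagram <- function(params, rho = seq(0.05, 0.95, by = 0.05),
                          d = seq(0, 0.9, by = 0.1),
                          peak_threshold = 1e-4, seed_density = 5e-6,
                          t_max = 1000, verbose = FALSE, ...) {
  params <- as_aware_params(params)
  if (!length(rho) || !length(d))
    stop("`rho` and `d` grids must be non-empty", call. = FALSE)
  if (any(rho <= 0 | rho >= 1)) stop("`rho` grid must lie in (0, 1)", call. = FALSE)
  if (any(d < 0 | d >= 1)) stop("`d` grid must lie in [0, 1)", call. = FALSE)

  cells <- purrr::map_dfr(d, function(dd) {
    if (verbose) message(sprintf("phase column d = %g", dd))
    purrr::map_dfr(rho, function(rr) {
      res <- tryCatch({
        p <- update_params(params, rho = rr, d = dd)
        traj <- simulate_epidemic(p, seed_density = seed_density,
                                  t_max = t_max, ...)
        s <- summarize_epidemic(traj)
        tibble::tibble(rho = rr, d = dd, peak_I = s$peak_I,
                       t_peak = s$t_peak, final_S = s$final_S,
                       duration = s$duration,
                       regime = classify_regime(s, p, peak_threshold))
      }, error = function(e) {
        tibble::tibble(rho = rr, d = dd, peak_I = NA_real_,
                       t_peak = NA_real_, final_S = NA_real_,
                       duration = NA_real_, regime = "error")
      })
      res
    })
  })

  boundary <- cells |>
    dplyr::filter(!is.na(.data$t_peak)) |>
    dplyr::group_by(.data$d) |>
    dplyr::summarise(
      rho_c_numeric = {
        i <- which.max(.data$t_peak)
        if (i > 1 && i < dplyr::n()) .data$rho[i] else NA_real_
      },
      .groups = "drop")

  structure(cells, boundary = boundary, params = params,
            class = c("phase_grid", class(cells)))
}

#' @export
autoplot.phase_grid <- function(object, ...) {
  bnd <- attr(object, "boundary")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$d, y = .data$rho,
                                    fill = log10(.data$t_peak))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10]~t[peak])) +
    ggplot2::labs(x = "distrusting density d", y = expression(rho),
                  title = "Time to infection peak: suppression vs mitigation") +
    ggplot2::theme_minimal()
  if (!is.null(bnd) && any(!is.na(bnd$rho_c_numeric)))
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(bnd, !is.na(.data$rho_c_numeric)),
      ggplot2::aes(x = .data$d, y = .data$rho_c_numeric),
      inherit.aes = FALSE, colour = "white", linetype = "dashed")
  p
}
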