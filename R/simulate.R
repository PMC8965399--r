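#' Simulate an epidemic with awareness feedback
#'
#' Integrates the full coupled disease-awareness system from a standard
#' outbreak initial condition (or a user-supplied state) and returns the
#' trajectory together with the aggregated `S`, `I`, `R` totals, the
#' effective transmission rate and the effective reproduction number at every
#' output time.
#'
#' If the infected density is still above `end_threshold` at `t_max` the
#' integration horizon is doubled (up to `t_max_cap`): near the
#' suppression-mitigation boundary epidemics plateau and can last far longer
#' than a typical outbreak.
#'
#' @param params An [aware_params()] object.
#' @param seed_density Initial infected density per behavioural group
#'   (see [make_initial_state()]). Ignored when `init` is given.
#' @param init Optional initial population state array; defaults to
#'   `make_initial_state(params, seed_density)`.
#' @param t_max Integration horizon in days.
#' @param n_out Number of output points per integration segment.
#' @param end_threshold Infected density below which the epidemic is
#'   considered over; also the horizon-extension trigger.
#' @param extend Logical: double the horizon while the epidemic is ongoing?
#' @param t_max_cap Largest horizon allowed by extension.
#' @param rtol,atol Relative and absolute solver tolerances. `atol` defaults
#'   to `1e-12 * N`.
#' @param method `deSolve` integration method; `"lsoda"` copes with the very
#'   stiff fast-information regime (large `alpha_T`, `alpha_D`).
#' @param compiled Use the compiled right-hand side (default)? The pure-R
#'   rhs ([full_rhs()]) gives identical derivatives and is kept as the
#'   readable reference; set `FALSE` to integrate through it.
#' @return An object of class `aware_trajectory`: a list with `times`,
#'   the compartment matrix `states` (rows = times), the aggregate tibble
#'   (`time`, `S`, `I`, `R`, `beta_eff`, `R_e`) retrievable with [tidy()],
#'   and the call parameters. [glance()] returns the epidemic summary.
#' @examples
#' p <- aware_params(beta = 0.667, sigma = 0.133, rho = 0.8,
#'                   alpha_T = 5, alpha_D = 5, lambda = 0.2,
#'                   omega = 0.333, d = 0.1)
#' traj <- simulate_epidemic(p, t_max = 300)
#' glance(traj)
#' @export
simulate_epidemic <- function(params, seed_density = 5e-6, init = NULL,
                              t_max = 1000, n_out = 801,
                              end_threshold = 1e-7, extend = TRUE,
                              t_max_cap = 16000,
                              rtol = 1e-8, atol = 1e-12 * params$N,
                              method = "lsoda", compiled = TRUE) {
  params <- as_aware_params(params)
  if (is.null(init)) init <- make_initial_state(params, seed_density)
  x0 <- as_state_array(init, params)
  if (any(x0 < 0)) stop("initial state entries must be non-negative",
                        call. = FALSE)
  check_scalar(t_max, "t_max", lower = 0, strict_lower = TRUE)

  dims <- dim(x0)
  func <- function(t, y, p) {
    dim(y) <- dims
    list(as.numeric(full_core(y, params)))
  }
  i_cols <- i_columns(params$K)
  # stop integrating once the epidemic is over: chasing the exponentially
  # decaying infected compartments into the denormal range serves nothing
  # and breaks the step-size control
  stop_thr <- 0.5 * end_threshold * params$N
  use_root <- sum(x0[, 2L, ]) > stop_thr
  cpar <- with(params, c(beta, sigma, rho, alpha_T, alpha_D,
                         lambda, omega, N, K, stop_thr))
  root_fun <- function(t, y, p) sum(y[i_cols]) - stop_thr

  times <- numeric(0)
  states <- NULL
  y <- as.numeric(x0)
  t0 <- 0
  t1 <- t_max
  run_segment <- function(y, tt, m) {
    rootable <- use_root && m %in% c("lsoda", "lsodar", "radau")
    if (rootable && m == "lsoda") m <- "lsodar"
    base_args <- list(y = y, times = tt, method = m, rtol = rtol,
                      atol = atol, maxsteps = 20000)
    args <- if (compiled)
      c(base_args, list(func = "aware_derivs", dllname = "awaresir",
                        initfunc = "aware_initmod", parms = cpar))
    else
      c(base_args, list(func = func, parms = NULL))
    if (rootable)
      args <- c(args, if (compiled) list(rootfunc = "aware_root", nroot = 1L)
                else list(rootfunc = root_fun))
    do.call(deSolve::ode, args)
  }
  repeat {
    tt <- seq(t0, t1, length.out = n_out)
    sol <- suppressWarnings(run_segment(y, tt, method))
    if (attr(sol, "istate")[1] < 0 && !identical(method, "bdf")) {
      # lsoda occasionally underflows its step size when near-empty
      # compartments meet very fast information exchange; BDF with a tight
      # absolute tolerance is robust there
      atol <- min(atol, 1e-16)
      sol <- suppressWarnings(run_segment(y, tt, "bdf"))
    }
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE solver failed near t = %.3f", max(sol[, 1])),
           call. = FALSE)
    keep <- if (length(times) == 0) seq_len(nrow(sol)) else -1L
    times <- c(times, sol[keep, 1])
    states <- rbind(states, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
    I_end <- sum(y[i_cols])
    if (!extend || I_end <= end_threshold * params$N || t1 >= t_max_cap) break
    t0 <- t1
    t1 <- min(2 * t1, t_max_cap)
  }

  states[states < 0 & states > -atol * 10] <- 0   # post-processing clip only

  structure(
    list(times = times, states = states,
         aggregates = aggregate_series(times, states, params),
         params = params, seed_density = seed_density,
         end_threshold = end_threshold, t_max = max(times)),
    class = "aware_trajectory"
  )
}

# column indices of the flattened state holding infected compartments
i_columns <- function(K) {
  n <- K + 1L
  c(n + seq_len(n), 4L * n + seq_len(n))   # I block of group T then group D
}

aggregate_series <- function(times, states, params) {
  n <- params$K + 1L
  pf <- protection_vector(params$rho, params$K)
  blk <- function(g, dis) states[, (g - 1L) * 3L * n + (dis - 1L) * n + seq_len(n),
                                 drop = FALSE]
  S_lev <- blk(1L, 1L) + blk(2L, 1L)
  I_lev <- blk(1L, 2L) + blk(2L, 2L)
  R_lev <- blk(1L, 3L) + blk(2L, 3L)
  S <- rowSums(S_lev)
  I <- rowSums(I_lev)
  R <- rowSums(R_lev)
  wS <- as.numeric(S_lev %*% pf)
  wI <- as.numeric(I_lev %*% pf)
  beta_eff <- ifelse(S > 0 & I > 0,
                     params$beta * (wI / pmax(I, .Machine$double.xmin)) *
                       (wS / pmax(S, .Machine$double.xmin)),
                     params$beta)
  tibble::tibble(time = times, S = S, I = I, R = R,
                 beta_eff = beta_eff, R_e = beta_eff / params$sigma)
}

#' @export
print.aware_trajectory <- function(x, ...) {
  cat(sprintf("<aware_trajectory> %d time points over [0, %.6g] days (N = %g)\n",
              length(x$times), x$t_max, x$params$N))
  s <- summarize_epidemic(x)
  cat(sprintf("  peak I = %.4g at t = %.4g; final S = %.4g\n",
              s$peak_I, s$t_peak, s$final_S))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname simulate_epidemic
#' @param x An `aware_trajectory` object.
#' @param ... Unused.
#' @export
tidy.aware_trajectory <- function(x, ...) x$aggregates

#' @rdname simulate_epidemic
#' @export
glance.aware_trajectory <- function(x, ...) summarize_epidemic(x)

#' @export
as_tibble.aware_trajectory <- function(x, ...) x$aggregates

#' Summary statistics of a simulated epidemic
#'
#' Extracts the quantities used throughout the phase analysis: the peak
#' infected population and its timing (refined by a local quadratic fit
#' around the discrete maximum, since near the phase boundary `I(t)`
#' plateaus), the final susceptible population, the total ever infected, and
#' the epidemic duration (first time after the peak at which the infected
#' density drops below `end_threshold`).
#'
#' @param traj An `aware_trajectory` from [simulate_epidemic()].
#' @param end_threshold Infected density defining the end of the epidemic;
#'   defaults to the value used in the simulation.
#' @return A one-row tibble with columns `peak_I`, `t_peak`, `final_S`,
#'   `duration`, `total_infected` and `converged` (`TRUE` when the epidemic
#'   was over by the end of the integration).
#' @export
summarize_epidemic <- function(traj, end_threshold = traj$end_threshold) {
  if (!inherits(traj, "aware_trajectory"))
    stop("`traj` must be an `aware_trajectory`", call. = FALSE)
  agg <- traj$aggregates
  if (nrow(agg) == 0) stop("empty trajectory", call. = FALSE)
  N <- traj$params$N
  I <- agg$I
  tt <- agg$time
  idx <- which.max(I)
  if (idx == 1L) {
    t_peak <- 0
    peak_I <- I[1L]
  } else if (idx == length(I)) {
    warning("infected still rising at the end of the trajectory; ",
            "the peak may not be covered", call. = FALSE)
    t_peak <- tt[idx]
    peak_I <- I[idx]
  } else {
    q <- quad_refine(tt[(idx - 1L):(idx + 1L)], I[(idx - 1L):(idx + 1L)])
    t_peak <- q[1L]
    peak_I <- q[2L]
  }
  after <- which(tt > t_peak & I < end_threshold * N)
  duration <- if (length(after)) tt[after[1L]] else tt[length(tt)]
  tibble::tibble(
    peak_I = peak_I,
    t_peak = t_peak,
    final_S = agg$S[nrow(agg)],
    duration = duration,
    total_infected = N - agg$S[nrow(agg)],
    converged = I[length(I)] < end_threshold * N
  )
}

# vertex of the parabola through three points (Newton form); falls back to
# the middle point for degenerate (flat) configurations
quad_refine <- function(t3, y3) {
  d1 <- (y3[2] - y3[1]) / (t3[2] - t3[1])
  d2 <- (y3[3] - y3[2]) / (t3[3] - t3[2])
  a <- (d2 - d1) / (t3[3] - t3[1])
  if (!is.finite(a) || a >= 0) return(c(t3[2], y3[2]))
  tv <- (t3[1] + t3[2]) / 2 - d1 / (2 * a)
  tv <- min(max(tv, t3[1]), t3[3])
  yv <- y3[1] + d1 * (tv - t3[1]) + a * (tv - t3[1]) * (tv - t3[2])
  c(tv, yv)
}

#' @rdname simulate_epidemic
#' @param object An `aware_trajectory` object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.aware_trajectory <- function(object, ...) {
  df <- tidy(object)
  long <- tibble::tibble(
    time = rep(df$time, 3L),
    compartment = factor(rep(c("S", "I", "R"), each = nrow(df)),
                         levels = c("S", "I", "R")),
    value = c(df$S, df$I, df$R)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "population",
                  colour = NULL,
                  title = "Epidemic with awareness feedback") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
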