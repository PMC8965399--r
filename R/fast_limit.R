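#' Reduced model in the fast-information limit: time derivatives
#'
#' When information spreads much faster than the disease
#' (`alpha_T, alpha_D -> Inf`), the trusting population concentrates at
#' awareness levels 0 and 1 and the distrusting population stays unaware, so
#' the dynamics collapse to five compartments: `S1` (trusting susceptibles at
#' level 1), `Sinf` (distrusting, unaware susceptibles), and infecteds `I0`,
#' `I1` (trusting, levels 0 and 1) and `Iinf` (distrusting, unaware).
#'
#' @param state Named (or positional) numeric vector
#'   `c(S1, Sinf, I0, I1, Iinf)`, non-negative.
#' @param params An [aware_params()] object (uses `beta`, `sigma`, `rho`,
#'   `lambda`, `omega`, `N`).
#' @return Numeric vector of derivatives in the same order.
#' @export
fast_limit_rhs <- function(state, params) {
  params <- as_aware_params(params)
  if (!is.numeric(state) || length(state) != 5L)
    stop("`state` must be a numeric vector c(S1, Sinf, I0, I1, Iinf)",
         call. = FALSE)
  if (any(state < 0)) stop("state entries must be non-negative", call. = FALSE)
  S1 <- state[[1]]; Sinf <- state[[2]]
  I0 <- state[[3]]; I1 <- state[[4]]; Iinf <- state[[5]]
  x <- 1 - params$rho
  force_inf <- (x * I1 + Iinf) * params$beta / params$N
  c(S1   = -S1 * x * force_inf,
    Sinf = -Sinf * force_inf,
    I0   = -params$sigma * I0 + params$omega * I1 - params$lambda * I0,
    I1   = -params$sigma * I1 - params$omega * I1 + params$lambda * I0 +
           S1 * x * force_inf,
    Iinf = -params$sigma * Iinf + Sinf * force_inf)
}

#' Integrate the reduced fast-information model
#'
#' @param params An [aware_params()] object.
#' @param init Initial `c(S1, Sinf, I0, I1, Iinf)` vector; defaults to a
#'   nearly susceptible population split `1 - d` trusting (level 1) and `d`
#'   distrusting (unaware), seeded with `seed_density * N` infected in `I0`
#'   and `Iinf`.
#' @param t_max Integration horizon (days).
#' @param n_out Number of output times.
#' @param seed_density Infected seed per group when `init` is `NULL`.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time`, `S1`, `Sinf`, `I0`, `I1`, `Iinf`
#'   and the total `I = I0 + I1 + Iinf`.
#' @export
integrate_fast_limit <- function(params, init = NULL, t_max = 1000,
                                 n_out = 2001, seed_density = 5e-6,
                                 rtol = 1e-8, atol = 1e-12 * params$N) {
  params <- as_aware_params(params)
  if (is.null(init)) {
    seed <- seed_density * params$N
    init <- c(S1 = (1 - params$d) * params$N - seed,
              Sinf = params$d * params$N - seed,
              I0 = seed, I1 = 0, Iinf = seed)
  }
  func <- function(t, y, p) list(fast_limit_rhs(pmax(y, 0), params))
  sol <- deSolve::ode(y = as.numeric(init), times = seq(0, t_max, length.out = n_out),
                      func = func, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  tibble::tibble(time = sol[, 1], S1 = sol[, 2], Sinf = sol[, 3],
                 I0 = sol[, 4], I1 = sol[, 5], Iinf = sol[, 6],
                 I = sol[, 4] + sol[, 5] + sol[, 6])
}

#' Quasi-steady-state ratios of the infected compartments
#'
#' At the suppression-mitigation boundary the infected compartments are
#' metastable; setting their derivatives to zero gives
#' `I0/I1 = omega / (sigma + lambda)` and
#' `Iinf/I1 = beta * d * (1 - rho) / (sigma - beta * d)`. The second ratio is
#' only physical for `d < sigma / beta`; beyond that the stationary unaware
#' infected population would be negative.
#'
#' @param params An [aware_params()] object.
#' @return A named list with `I0_over_I1` and `Iinf_over_I1`.
#' @export
quasi_steady_ratios <- function(params) {
  params <- as_aware_params(params)
  if (params$beta > 0 && params$d >= params$sigma / params$beta)
    stop("d >= sigma/beta: the quasi-steady unaware infected population ",
         "would be negative (suppression is not achievable here)",
         call. = FALSE)
  list(
    I0_over_I1 = params$omega / (params$sigma + params$lambda),
    Iinf_over_I1 = params$beta * params$d * (1 - params$rho) /
      (params$sigma - params$beta * params$d)
  )
}

#' Coefficients of the critical-threshold quadratic
#'
#' The metastability conditions of the reduced model yield a quadratic for
#' `x = 1 - rho` at the phase boundary:
#' `a x^2 + b x + c = 0` with, writing `y = beta / (sigma - beta d)` and
#' `R0 = beta / sigma`,
#' `a = (1 - d)(1 + d y)`, `b = d (1 + d y - y / R0)`,
#' `c = -(1 / R0)(1 + omega / (sigma + lambda))`.
#' (Algebraically `1 + d y - y / R0 = 0`, so `b` vanishes identically; the
#' printed form is kept and the identity is exercised by the tests.)
#'
#' @param d Distrusting density, must satisfy `0 <= d < sigma / beta`.
#' @param params An [aware_params()] object (its own `d` is ignored).
#' @return Named numeric vector `c(a =, b =, c =)`.
#' @export
critical_quadratic_coeffs <- function(d, params) {
  params <- as_aware_params(params)
  check_scalar(d, "d", lower = 0, upper = 1)
  if (params$beta <= 0)
    stop("beta must be positive for the critical threshold", call. = FALSE)
  d_M <- params$sigma / params$beta
  if (d >= d_M)
    stop(sprintf("d = %g is at or above the critical density d_M = %g", d, d_M),
         call. = FALSE)
  y <- params$beta / (params$sigma - params$beta * d)
  R0 <- params$R0
  c(a = (1 - d) * (1 + d * y),
    b = d * (1 + d * y - y / R0),
    c = -(1 / R0) * (1 + params$omega / (params$sigma + params$lambda)))
}

#' Critical distrusting density
#'
#' `d_M = sigma / beta = 1 / R0`: for distrusting densities at or above this
#' value no intervention effectiveness `rho < 1` can suppress the epidemic.
#' May exceed 1 (then suppression is achievable at every composition, in
#' particular whenever `R0 < 1`); `beta = 0` gives `Inf`.
#'
#' @param params An [aware_params()] object.
#' @return A positive scalar (possibly `Inf`).
#' @export
critical_density <- function(params) {
  params <- as_aware_params(params)
  if (params$beta == 0) return(Inf)
  params$sigma / params$beta
}

#' Analytic critical intervention effectiveness
#'
#' Solves the phase-boundary quadratic (see [critical_quadratic_coeffs()])
#' for its positive root `x+` and returns `rho_c = 1 - x+`, the intervention
#' effectiveness separating suppression (`rho > rho_c`) from mitigation
#' (`rho < rho_c`) in the fast-information limit. For `d >= d_M` the
#' threshold does not exist (suppression unachievable); when the root gives
#' `rho_c <= 0`, suppression occurs at every `rho` and 0 is reported with
#' `suppression_at_any_rho = TRUE`.
#'
#' @param d Distrusting density (vectorised).
#' @param params An [aware_params()] object (its own `d` and `rho` are
#'   ignored).
#' @return A tibble with one row per `d`: columns `d`, `rho_c` (`NA` when
#'   unachievable), `achievable`, `suppression_at_any_rho` and the root `x`.
#' @examples
#' p <- aware_params(beta = 0.333, sigma = 0.133, rho = 0.5,
#'                   alpha_T = 1e6, alpha_D = 1e6, lambda = 0.2,
#'                   omega = 0.33, d = 0)
#' critical_rho_analytic(c(0, 0.1, 0.2, 0.5), p)
#' @export
critical_rho_analytic <- function(d, params) {
  params <- as_aware_params(params)
  d_M <- critical_density(params)
  purrr::map_dfr(d, function(di) {
    if (di >= d_M || di > 1 || di < 0)
      return(tibble::tibble(d = di, rho_c = NA_real_, achievable = FALSE,
                            suppression_at_any_rho = FALSE, x = NA_real_))
    co <- critical_quadratic_coeffs(di, params)
    disc <- co[["b"]]^2 - 4 * co[["a"]] * co[["c"]]
    x_plus <- (-co[["b"]] + sqrt(disc)) / (2 * co[["a"]])
    rho_c <- 1 - x_plus
    always <- rho_c <= 0
    tibble::tibble(d = di, rho_c = max(rho_c, 0), achievable = TRUE,
                   suppression_at_any_rho = always, x = x_plus)
  })
}

#' Critical curve over a grid of distrusting densities
#'
#' Tabulates the analytic threshold [critical_rho_analytic()] on a grid of
#' `d` values, carrying the critical density `d_M` as an attribute.
#'
#' @param params An [aware_params()] object.
#' @param d Grid of distrusting densities.
#' @return A `critical_curve` tibble with attribute `d_M`; plot with
#'   [ggplot2::autoplot()].
#' @export
critical_curve <- function(params, d = seq(0, 0.95, by = 0.01)) {
  out <- critical_rho_analytic(d, params)
  structure(out, d_M = critical_density(params),
            class = c("critical_curve", class(out)))
}

#' @export
autoplot.critical_curve <- function(object, ...) {
  d_M <- attr(object, "d_M")
  df <- dplyr::filter(object, .data$achievable)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$rho_c)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "distrusting density d",
                  y = expression(rho[c]),
                  title = "Critical intervention effectiveness (fast-information limit)") +
    ggplot2::theme_minimal()
  if (is.finite(d_M) && d_M <= max(object$d))
    p <- p + ggplot2::geom_vline(xintercept = d_M, linetype = "dashed")
  p
}
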