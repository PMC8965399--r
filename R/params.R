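#' Model parameters for the coupled awareness-epidemic system
#'
#' Bundles all rates and population-composition parameters of the model in
#' which an SIR epidemic is coupled to contact-based spread of outbreak
#' awareness. Awareness is graded: level 0 is first-hand information, larger
#' indices are progressively degraded copies, and a reservoir at level
#' infinity holds fully unaware individuals. Trusting individuals accept
#' better-quality information from their contacts; distrusting individuals
#' accept worse-quality information.
#'
#' @param beta Baseline transmission rate (per day) in the absence of any
#'   protective measures. The basic reproduction number is
#'   `R0 = beta / sigma`.
#' @param sigma Recovery rate (per day); must be positive.
#' @param rho Effectiveness of non-pharmaceutical interventions, in `[0, 1)`.
#'   An individual at awareness level `i` reduces transmission by the factor
#'   `1 - rho^i` (so level 0 blocks transmission entirely).
#' @param alpha_T Information-encounter rate (per day) for trusting
#'   individuals.
#' @param alpha_D Information-encounter rate (per day) for distrusting
#'   individuals.
#' @param lambda Awareness fading rate (per day): information degrades by one
#'   level when not refreshed.
#' @param omega Rate (per day) at which infected individuals realise their
#'   condition and refresh their awareness to level 0.
#' @param d Initial density of distrusting individuals, in `[0, 1]`.
#' @param K Number of finite awareness levels `0 .. K-1` retained in the
#'   truncation; the level-infinity reservoir is kept in addition. Defaults to
#'   the smallest `K` with `rho^(K-1) < 1e-6`, so that protection at the last
#'   resolved level is numerically indistinguishable from none.
#' @param N Total population size. All dynamics are homogeneous of degree one
#'   in the compartments, so `N = 1` (densities) is the natural choice.
#'
#' @return An object of class `aware_params`: a named list of validated
#'   parameters with derived fields `R0 = beta/sigma` and `K`.
#' @examples
#' p <- aware_params(beta = 0.667, sigma = 0.133, rho = 0.8,
#'                   alpha_T = 5, alpha_D = 5, lambda = 0.2,
#'                   omega = 0.333, d = 0.1)
#' p$R0
#' @export
aware_params <- function(beta, sigma, rho, alpha_T, alpha_D, lambda, omega,
                         d, K = NULL, N = 1) {
  check_scalar(beta, "beta", lower = 0)
  check_scalar(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_scalar(rho, "rho", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(alpha_T, "alpha_T", lower = 0)
  check_scalar(alpha_D, "alpha_D", lower = 0)
  check_scalar(lambda, "lambda", lower = 0)
  check_scalar(omega, "omega", lower = 0)
  check_scalar(d, "d", lower = 0, upper = 1)
  check_scalar(N, "N", lower = 0, strict_lower = TRUE)
  if (is.null(K)) K <- default_truncation(rho)
  check_scalar(K, "K", lower = 2)
  if (K != round(K)) stop("`K` must be a whole number", call. = FALSE)
  K <- as.integer(K)

  structure(
    list(beta = beta, sigma = sigma, rho = rho,
         alpha_T = alpha_T, alpha_D = alpha_D,
         lambda = lambda, omega = omega,
         d = d, K = K, N = N, R0 = beta / sigma),
    class = "aware_params"
  )
}

#' Default awareness-level truncation for a given protection parameter
#'
#' Smallest number of finite levels `K` such that `rho^(K-1) < 1e-6`, i.e.
#' protection at the deepest resolved level differs from the unaware limit by
#' less than one part in a million. At least 3 levels are always kept.
#'
#' @param rho Intervention effectiveness in `[0, 1)`.
#' @param tol Truncation tolerance on the residual protection `rho^(K-1)`.
#' @return An integer number of finite levels.
#' @export
default_truncation <- function(rho, tol = 1e-6) {
  if (rho <= 0) return(3L)
  max(3L, as.integer(ceiling(log(tol) / log(rho))) + 1L)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (strict_upper && x >= upper)
    stop(sprintf("`%s` must be < %g", name, upper), call. = FALSE)
  if (!strict_upper && x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

#' @export
print.aware_params <- function(x, ...) {
  cat("<aware_params>\n")
  cat(sprintf("  transmission beta = %g, recovery sigma = %g (R0 = %.3f)\n",
              x$beta, x$sigma, x$R0))
  cat(sprintf("  NPI effectiveness rho = %g, distrusting density d = %g\n",
              x$rho, x$d))
  cat(sprintf("  information: alpha_T = %g, alpha_D = %g, fading lambda = %g, refresh omega = %g\n",
              x$alpha_T, x$alpha_D, x$lambda, x$omega))
  cat(sprintf("  truncation K = %d finite levels (+ unaware reservoir), N = %g\n",
              x$K, x$N))
  invisible(x)
}

as_aware_params <- function(x) {
  if (inherits(x, "aware_params")) return(x)
  stop("expected an `aware_params` object; see `aware_params()`", call. = FALSE)
}
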