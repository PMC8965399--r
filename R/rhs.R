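#' Per-level protection factor
#'
#' Transmission involving an individual at awareness level `i` is reduced by
#' the factor `1 - rho^i`: level 0 (first-hand information) blocks
#' transmission entirely, and the factor tends to 1 (no protection) as the
#' level grows, with the unaware reservoir (`Inf`) contributing exactly 1.
#'
#' @param level Awareness level(s): non-negative integers or `Inf`.
#' @param rho Intervention effectiveness in `[0, 1)`.
#' @return Numeric vector of factors in `[0, 1]`.
#' @examples
#' protection_factor(0, 0.8)    # 0: fully protective
#' protection_factor(Inf, 0.8)  # 1: unaware
#' @export
protection_factor <- function(level, rho) {
  check_scalar(rho, "rho", lower = 0, upper = 1, strict_upper = TRUE)
  if (any(!is.numeric(level)) || any(is.na(level)) || any(level < 0))
    stop("`level` must be non-negative (finite index or Inf)", call. = FALSE)
  ifelse(is.infinite(level), 1, 1 - rho^level)
}

# protection factors for levels 0..K-1 plus the unaware reservoir
protection_vector <- function(rho, K) c(1 - rho^(0:(K - 1)), 1)

# Information-exchange derivative for one disease slice of the trusting
# group. xfin: levels 0..K-1, xinf: unaware reservoir. nlev = per-level
# totals t_i + d_i of all possible sources; CS[m] = sum of nlev over levels
# 0..m-1. A trusting recipient at level j adopts information from any source
# at level i <= j-2, landing at level i+1; an unaware trusting recipient
# accepts any source at level i <= K-2 (a level-(K-1) source would hand on
# information below the resolved range, leaving the recipient unaware).
exchange_trusting <- function(xfin, xinf, nlev, CS, a) {
  K <- length(xfin)
  loss <- a * xfin * c(0, 0, CS[seq_len(K - 2)])
  loss_inf <- a * xinf * CS[K - 1]
  RT <- rev(cumsum(rev(xfin)))       # RT[m] = sum over levels >= m-1
  tail_gt <- c(RT[-1], 0)            # sum over levels > m-1
  gain <- c(0, a * nlev[seq_len(K - 1)] * (tail_gt[2:K] + xinf))
  list(fin = gain - loss, inf = -loss_inf)
}

# Distrusting counterpart: a recipient at level j adopts information from any
# source at level i >= j+1 (including the unaware reservoir), landing at
# level i+1, with "Inf + 1 = Inf"; unaware distrusting individuals never
# change by exchange.
exchange_distrusting <- function(xfin, xinf, nlev, n_inf, TS, a) {
  K <- length(xfin)
  loss <- a * xfin * (c(TS[-1], 0) + n_inf)
  BY <- cumsum(xfin)                 # BY[m] = sum over levels 0..m-1
  gain <- c(0, a * nlev[seq_len(K - 1)] * c(0, BY[seq_len(K - 2)]))
  gain_inf <- a * (nlev[K] * BY[K - 1] + n_inf * BY[K])
  list(fin = gain - loss, inf = gain_inf)
}

# fading: awareness degrades one level at rate lambda; level K-1 fades into
# the unaware reservoir, which does not fade further
fade <- function(xfin, lambda) {
  K <- length(xfin)
  list(fin = -lambda * xfin + lambda * c(0, xfin[seq_len(K - 1)]),
       inf = lambda * xfin[K])
}

# core of the information dynamics, shared by info_rhs and full_rhs;
# x is the (K+1) x 3 x 2 state array
info_core <- function(x, params) {
  K <- params$K
  fin <- seq_len(K)
  inf_row <- K + 1L
  aT <- params$alpha_T / params$N
  aD <- params$alpha_D / params$N

  t_all <- rowSums(x[, , 1L, drop = FALSE])
  d_all <- rowSums(x[, , 2L, drop = FALSE])
  nlev <- t_all[fin] + d_all[fin]
  n_inf <- t_all[inf_row] + d_all[inf_row]
  CS <- cumsum(nlev)
  TS <- rev(cumsum(rev(nlev)))

  dx <- array(0, dim = dim(x), dimnames = state_dimnames(K))
  for (s in 1:3) {
    eT <- exchange_trusting(x[fin, s, 1L], x[inf_row, s, 1L], nlev, CS, aT)
    fT <- fade(x[fin, s, 1L], params$lambda)
    dx[fin, s, 1L] <- eT$fin + fT$fin
    dx[inf_row, s, 1L] <- eT$inf + fT$inf

    eD <- exchange_distrusting(x[fin, s, 2L], x[inf_row, s, 2L],
                               nlev, n_inf, TS, aD)
    fD <- fade(x[fin, s, 2L], params$lambda)
    dx[fin, s, 2L] <- eD$fin + fD$fin
    dx[inf_row, s, 2L] <- eD$inf + fD$inf
  }
  dx
}

full_core <- function(x, params) {
  K <- params$K
  inf_row <- K + 1L
  dx <- info_core(x, params)

  pf <- protection_vector(params$rho, K)
  I_i <- x[, 2L, 1L] + x[, 2L, 2L]
  phi <- sum(I_i * pf)                       # awareness-weighted infectious pressure
  foi <- (params$beta / params$N) * pf * phi # per-level force of infection

  for (g in 1:2) {
    new_inf <- foi * x[, 1L, g]
    dx[, 1L, g] <- dx[, 1L, g] - new_inf
    dx[, 2L, g] <- dx[, 2L, g] + new_inf

    # infected individuals refresh their awareness to level 0 at rate omega
    refresh <- params$omega * x[-1L, 2L, g]
    dx[-1L, 2L, g] <- dx[-1L, 2L, g] - refresh
    dx[1L, 2L, g] <- dx[1L, 2L, g] + sum(refresh)

    recov <- params$sigma * x[, 2L, g]
    dx[, 2L, g] <- dx[, 2L, g] - recov
    dx[, 3L, g] <- dx[, 3L, g] + recov
  }
  dx
}

#' Information-only dynamics: time derivatives
#'
#' Right-hand side of the pure awareness dynamics (information exchange and
#' fading), applied independently to every disease state. Trusting
#' individuals adopt better information (source level `i < j - 1` moves a
#' level-`j` recipient to `i + 1`); distrusting individuals adopt worse
#' information (`i > j` moves the recipient to `i + 1`); all awareness fades
#' one level at rate `lambda`, with the last resolved level fading into the
#' unaware reservoir. For each disease-by-group slice the derivative entries
#' sum to zero: information exchange conserves people.
#'
#' @param state Population state array (or flattened vector).
#' @param params An [aware_params()] object.
#' @return Derivative array of the same shape as `state`.
#' @export
info_rhs <- function(state, params) {
  params <- as_aware_params(params)
  x <- as_state_array(state, params)
  if (any(x < 0)) stop("state entries must be non-negative", call. = FALSE)
  info_core(x, params)
}

#' Full coupled disease-awareness dynamics: time derivatives
#'
#' Right-hand side of the complete model: SIR disease dynamics with
#' awareness-graded transmission, plus all information-exchange and fading
#' terms of [info_rhs()]. A susceptible at level `k` is infected at rate
#' `(beta/N) * (1 - rho^k) * sum_i I_i (1 - rho^i)` (both parties' awareness
#' reduces transmission, and level-0 infecteds do not transmit at all);
#' infected individuals refresh their awareness to level 0 at rate `omega`
#' and recover at rate `sigma`. With the whole population unaware and
#' `omega = 0` the system is exactly the classical SIR model.
#'
#' @inheritParams info_rhs
#' @return Derivative array of the same shape as `state`; entries sum to zero.
#' @export
full_rhs <- function(state, params) {
  params <- as_aware_params(params)
  x <- as_state_array(state, params)
  if (any(x < 0)) stop("state entries must be non-negative", call. = FALSE)
  full_core(x, params)
}

#' Effective transmission rate of the aggregated epidemic
#'
#' The aggregated totals follow SIR dynamics with a time-varying effective
#' transmission rate
#' `beta_eff = beta * sum_{i,j} (1 - rho^i)(1 - rho^j) (I_i / I) (S_j / S)`,
#' the awareness-weighted average of the pairwise protection factors
#' (unaware individuals contribute factor 1). Always between 0 and `beta`,
#' with equality to `beta` exactly when all susceptible and infected mass is
#' unaware.
#'
#' @inheritParams info_rhs
#' @return The effective transmission rate, a scalar in `[0, beta]`. When
#'   there are no infected or no susceptible individuals the fresh-population
#'   convention `beta` is returned with a message.
#' @export
effective_beta <- function(state, params) {
  params <- as_aware_params(params)
  x <- as_state_array(state, params)
  if (any(x < 0)) stop("state entries must be non-negative", call. = FALSE)
  agg <- aggregate_state(x, params)
  if (agg$I <= 0 || agg$S <= 0) {
    rlang::inform(
      "no infected or no susceptible mass: returning the fresh-population limit beta",
      .frequency = "once", .frequency_id = "awaresir_beta_eff_empty")
    return(params$beta)
  }
  pf <- protection_vector(params$rho, params$K)
  params$beta * sum(pf * agg$I_i / agg$I) * sum(pf * agg$S_j / agg$S)
}

#' Effective reproduction number
#'
#' `R_e = beta_eff / sigma`, the awareness-adjusted analogue of
#' `R0 = beta / sigma`. For a fully unaware population `R_e = R0`. (No
#' susceptible-depletion factor is applied.)
#'
#' @inheritParams info_rhs
#' @return A non-negative scalar.
#' @export
effective_R <- function(state, params) {
  params <- as_aware_params(params)
  effective_beta(state, params) / params$sigma
}
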