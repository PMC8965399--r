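#' @importFrom tibble tibble as_tibble
NULL

DISEASES <- c("S", "I", "R")
GROUPS <- c("T", "D")

# Dimension layout used throughout: array [level, disease, group] with
# levels 1..K holding awareness levels 0..K-1 and row K+1 the unaware
# (level-infinity) reservoir.
state_dimnames <- function(K) {
  list(level = c(as.character(0:(K - 1)), "Inf"),
       disease = DISEASES,
       group = GROUPS)
}

#' Empty population state
#'
#' Creates the all-zero population state for a given parameter set: a numeric
#' array indexed by awareness level (`0 .. K-1` plus the unaware reservoir
#' `Inf`), disease state (`S`, `I`, `R`) and behavioural group (`T` trusting,
#' `D` distrusting).
#'
#' @param params An [aware_params()] object.
#' @return A numeric array of dimension `(K+1) x 3 x 2` with named dimnames.
#' @export
empty_state <- function(params) {
  params <- as_aware_params(params)
  array(0, dim = c(params$K + 1L, 3L, 2L), dimnames = state_dimnames(params$K))
}

as_state_array <- function(state, params) {
  K <- params$K
  n <- (K + 1L) * 6L
  if (is.array(state) && length(dim(state)) == 3L) {
    if (!all(dim(state) == c(K + 1L, 3L, 2L)))
      stop(sprintf("state has %d levels but params$K = %d implies %d rows",
                   dim(state)[1] - 1L, K, K + 1L), call. = FALSE)
    return(state)
  }
  if (is.numeric(state) && length(state) == n)
    return(array(state, dim = c(K + 1L, 3L, 2L),
                 dimnames = state_dimnames(K)))
  stop(sprintf("state must be a (K+1) x 3 x 2 array or a vector of length %d",
               n), call. = FALSE)
}

#' Initial condition: an almost fully susceptible, unaware population
#'
#' Places equal infected seeds in the unaware reservoir of both behavioural
#' groups (`I[T, Inf] = I[D, Inf] = seed_density * N`) and the remaining
#' population in the unaware susceptible compartments, split `1 - d` trusting
#' and `d` distrusting. This is the standard outbreak initial condition: no
#' awareness exists until the first infected individuals realise their
#' condition.
#'
#' @param params An [aware_params()] object.
#' @param seed_density Initial infected density per group, as a fraction of
#'   `N`. Default `5e-6`.
#' @return A population state array (see [empty_state()]) summing to `N`.
#' @examples
#' p <- aware_params(beta = 0.667, sigma = 0.133, rho = 0.8,
#'                   alpha_T = 5, alpha_D = 5, lambda = 0.2,
#'                   omega = 0.333, d = 0.3)
#' s <- make_initial_state(p)
#' sum(s) # == 1
#' @export
make_initial_state <- function(params, seed_density = 5e-6) {
  params <- as_aware_params(params)
  check_scalar(seed_density, "seed_density", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  seed <- seed_density * params$N
  s_T <- (1 - params$d) * params$N - seed
  s_D <- params$d * params$N - seed
  if (s_T < 0)
    stop("seed_density exceeds the trusting population share (1 - d)",
         call. = FALSE)
  if (s_D < 0)
    stop("seed_density exceeds the distrusting population share d",
         call. = FALSE)
  x <- empty_state(params)
  inf_row <- params$K + 1L
  x[inf_row, "S", "T"] <- s_T
  x[inf_row, "S", "D"] <- s_D
  x[inf_row, "I", "T"] <- seed
  x[inf_row, "I", "D"] <- seed
  x
}

#' Aggregate a population state over awareness levels and groups
#'
#' Collapses the compartment array to the marginals used in the aggregated
#' SIR form of the model: disease totals `S`, `I`, `R`; per-level group
#' totals `t_i` (trusting) and `d_i` (distrusting); and per-level infected
#' and susceptible totals `I_i`, `S_j` (summed over both groups). The final
#' entry of each per-level vector is the unaware reservoir.
#'
#' @param state A population state array or its flattened numeric vector.
#' @param params An [aware_params()] object (supplies the truncation `K`).
#' @return A list with elements `S`, `I`, `R` (scalars), `N`, and per-level
#'   vectors `t_i`, `d_i`, `I_i`, `S_j` of length `K + 1`.
#' @export
aggregate_state <- function(state, params) {
  params <- as_aware_params(params)
  x <- as_state_array(state, params)
  t_i <- rowSums(x[, , 1L, drop = FALSE])
  d_i <- rowSums(x[, , 2L, drop = FALSE])
  I_i <- x[, 2L, 1L] + x[, 2L, 2L]
  S_j <- x[, 1L, 1L] + x[, 1L, 2L]
  list(S = sum(S_j),
       I = sum(I_i),
       R = sum(x[, 3L, 1L] + x[, 3L, 2L]),
       N = sum(x),
       t_i = t_i, d_i = d_i, I_i = I_i, S_j = S_j)
}

#' @export
as_tibble.aware_state <- function(x, ...) state_to_tibble(unclass(x))

state_to_tibble <- function(x) {
  dn <- dimnames(x)
  grid <- expand.grid(level = dn$level, disease = dn$disease,
                      group = dn$group, stringsAsFactors = FALSE)
  tibble::tibble(disease = grid$disease, group = grid$group,
                 level = grid$level, value = as.numeric(x))
}
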