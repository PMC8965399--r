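# Shared parameter fixtures. The two standard sets mirror the regimes the
# package is about: a moderate-information epidemic with R0 = 5, and the
# fast-information regime (alpha = 1e6) where the analytic threshold applies.

fig1_params <- function(rho = 0.2, d = 0.1, ...) {
  update_params(
    aware_params(beta = 0.667, sigma = 0.133, rho = rho,
                 alpha_T = 5, alpha_D = 5, lambda = 0.2, omega = 0.333,
                 d = d),
    ...)
}

fast_params <- function(beta = 0.333, rho = 0.5, d = 0.1, K = 8, ...) {
  update_params(
    aware_params(beta = beta, sigma = 0.133, rho = rho,
                 alpha_T = 1e6, alpha_D = 1e6, lambda = 0.2, omega = 0.33,
                 d = d, K = K),
    ...)
}

# random admissible population state summing to N
random_state <- function(params) {
  x <- empty_state(params)
  x[] <- stats::runif(length(x))
  x / sum(x) * params$N
}

# classical SIR reference trajectory, integrated independently of the
# package's model code
reference_sir <- function(times, beta, sigma, S0, I0, rtol = 1e-10) {
  deSolve::ode(
    y = c(S = S0, I = I0, R = 0), times = times,
    func = function(t, y, p) {
      list(c(-beta * y[1] * y[2], beta * y[1] * y[2] - sigma * y[2],
             sigma * y[2]))
    },
    parms = NULL, method = "lsoda", rtol = rtol, atol = 1e-14)
}
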