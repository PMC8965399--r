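test_that("protection factor follows 1 - rho^level with unaware limit 1", {
  expect_equal(protection_factor(0, 0.8), 0)
  expect_equal(protection_factor(Inf, 0.8), 1)
  expect_equal(protection_factor(1, 0.5), 0.5)
  expect_equal(protection_factor(c(0, 2, Inf), 0.5), c(0, 0.75, 1))
  expect_error(protection_factor(-1, 0.5), "non-negative")
})

test_that("information dynamics are inert without interaction or fading", {
  p <- fig1_params(alpha_T = 0, alpha_D = 0, lambda = 0, K = 6)
  x <- empty_state(p)
  x[3, "S", "T"] <- 0.6   # everyone at one shared level
  x[3, "S", "D"] <- 0.4
  expect_equal(max(abs(info_rhs(x, p))), 0)
})

test_that("pure fading reproduces the Poisson cascade through the levels", {
  # linear chain dX_k/dt = lambda X_{k-1} - lambda X_k started at level 0 has
  # the closed-form occupancy exp(-lambda t) (lambda t)^k / k!
  p <- aware_params(beta = 0, sigma = 0.1, rho = 0.5, alpha_T = 0,
                    alpha_D = 0, lambda = 0.3, omega = 0, d = 0, K = 14)
  x <- empty_state(p)
  x[1, "S", "T"] <- 1
  f <- function(t, y, parms) {
    dim(y) <- dim(x)
    list(as.numeric(info_rhs(y, p)))
  }
  sol <- deSolve::ode(as.numeric(x), c(0, 4), f, NULL,
                      rtol = 1e-10, atol = 1e-14)
  occupancy <- sol[2, 1 + 1:10]
  expect_equal(unname(occupancy), dpois(0:9, 0.3 * 4), tolerance = 1e-8)
})

test_that("both right-hand sides conserve the population exactly", {
  set.seed(42)
  p <- fig1_params(K = 9)
  for (i in 1:25) {
    x <- random_state(p)
    expect_lt(abs(sum(info_rhs(x, p))), 1e-12 * p$N)
    expect_lt(abs(sum(full_rhs(x, p))), 1e-12 * p$N)
    # information exchange also conserves each disease-by-group slice
    dx <- info_rhs(x, p)
    expect_lt(max(abs(apply(dx, c(2, 3), sum))), 1e-12 * p$N)
  }
})

test_that("with everyone unaware and no refresh the field is classical SIR", {
  p <- fig1_params(omega = 0, K = 5)
  x <- empty_state(p)
  x[p$K + 1, "S", "T"] <- 0.9 - 5e-6
  x[p$K + 1, "S", "D"] <- 0.1 - 5e-6
  x[p$K + 1, "I", "T"] <- 5e-6
  x[p$K + 1, "I", "D"] <- 5e-6
  dx <- full_rhs(x, p)
  S <- sum(x[, "S", ]); I <- sum(x[, "I", ])
  expect_equal(sum(dx[, "S", ]), -p$beta * S * I / p$N)
  expect_equal(sum(dx[, "I", ]), p$beta * S * I / p$N - p$sigma * I)
  expect_equal(sum(dx[, "R", ]), p$sigma * I)
})

test_that("fully aware infecteds generate no new infections", {
  p <- fig1_params(K = 6)
  x <- empty_state(p)
  x[1, "I", "T"] <- 0.05                   # all infected at level 0
  x[p$K + 1, "S", "T"] <- 0.6
  x[3, "S", "D"] <- 0.35
  dx <- full_rhs(x, p)
  expect_equal(sum(dx[, "S", ]), 0)           # no susceptible is lost
  expect_equal(sum(dx[, "I", ]), -p$sigma * 0.05)
  expect_equal(effective_beta(x, p), 0)
})

test_that("aggregated derivatives follow the effective-rate SIR form", {
  set.seed(7)
  p <- fig1_params(K = 8)
  for (i in 1:25) {
    x <- random_state(p)
    dx <- full_rhs(x, p)
    agg <- aggregate_state(x, p)
    bt <- effective_beta(x, p)
    expect_lt(abs(sum(dx[, "S", ]) + bt * agg$S * agg$I / p$N), 1e-10 * p$N)
    expect_lt(abs(sum(dx[, "I", ]) - (bt * agg$S * agg$I / p$N -
                                        p$sigma * agg$I)), 1e-10 * p$N)
    expect_lt(abs(sum(dx[, "R", ]) - p$sigma * agg$I), 1e-10 * p$N)
  }
})

test_that("effective transmission rate averages the protection factors", {
  p <- fig1_params(rho = 0.5, K = 5)
  # unaware population transmits at the full rate
  x <- empty_state(p)
  x[p$K + 1, "S", "T"] <- 0.9
  x[p$K + 1, "I", "D"] <- 0.1
  expect_equal(effective_beta(x, p), p$beta)
  expect_equal(effective_R(x, p), p$R0)
  # all I and S at level 1: both parties halve transmission at rho = 0.5
  y <- empty_state(p)
  y[2, "I", "T"] <- 0.1
  y[2, "S", "T"] <- 0.8
  expect_equal(effective_beta(y, p), 0.667 * 0.5 * 0.5)
  expect_equal(effective_R(y, p), 0.16675 / 0.133)
  # bounds on random states
  set.seed(11)
  for (i in 1:10) {
    b <- effective_beta(random_state(p), p)
    expect_gte(b, 0); expect_lte(b, p$beta)
  }
  # empty epidemic falls back to the fresh-population limit
  z <- empty_state(p); z[2, "S", "T"] <- 1
  expect_equal(effective_beta(z, p), p$beta)
})

test_that("aggregation sums compartments and preserves the population", {
  p <- fig1_params(K = 4)
  x <- empty_state(p)
  x[p$K + 1, "S", "T"] <- 1
  agg <- aggregate_state(x, p)
  expect_equal(agg$S, 1); expect_equal(agg$I, 0); expect_equal(agg$R, 0)
  y <- empty_state(p)
  y[2, "I", "T"] <- 3; y[2, "I", "D"] <- 4
  expect_equal(aggregate_state(y, p)$I_i[[2]], 7)
  set.seed(3)
  z <- random_state(p)
  aggz <- aggregate_state(z, p)
  expect_equal(aggz$S + aggz$I + aggz$R, p$N)
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- fig1_params(rho = 0.6, K = 10)
  trC <- simulate_epidemic(p, t_max = 120, extend = FALSE)
  trR <- simulate_epidemic(p, t_max = 120, extend = FALSE, compiled = FALSE)
  expect_lt(max(abs(trC$states - trR$states)), 1e-8 * p$N)
})

test_that("doubling the truncation depth leaves summaries unchanged", {
  p <- fig1_params(rho = 0.5, K = NULL)     # default rule: rho^(K-1) < 1e-6
  s1 <- glance(simulate_epidemic(p, t_max = 400))
  s2 <- glance(simulate_epidemic(update_params(p, K = 2L * p$K), t_max = 400))
  expect_equal(s1$peak_I, s2$peak_I, tolerance = 1e-6)
  expect_equal(s1$final_S, s2$final_S, tolerance = 1e-6)
})
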