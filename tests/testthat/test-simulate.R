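test_that("initial state seeds both groups inside the unaware reservoir", {
  p <- fig1_params(d = 0.3)
  x <- make_initial_state(p, 5e-6)
  inf_row <- p$K + 1
  expect_equal(x[inf_row, "S", "T"], 0.699995)
  expect_equal(x[inf_row, "S", "D"], 0.299995)
  expect_equal(x[inf_row, "I", "T"], 5e-6)
  expect_equal(x[inf_row, "I", "D"], 5e-6)
  expect_equal(sum(x), p$N)
  expect_equal(sum(x != 0), 4)
  expect_error(make_initial_state(fig1_params(d = 0), 5e-6), "distrusting")
})

test_that("with no transmission the infected decay exponentially", {
  p <- fig1_params(beta = 0, K = 5)
  tr <- simulate_epidemic(p, t_max = 60, extend = FALSE)
  a <- tidy(tr)
  expect_equal(a$I, 1e-5 * exp(-p$sigma * a$time), tolerance = 1e-6)
})

test_that("unaware no-refresh runs match an independent SIR integration", {
  p <- fig1_params(omega = 0, rho = 0.5, K = 5)
  tr <- simulate_epidemic(p, t_max = 150, extend = FALSE)
  ref <- reference_sir(tr$times, p$beta, p$sigma, S0 = 1 - 1e-5, I0 = 1e-5)
  a <- tidy(tr)
  expect_lt(max(abs(a$I - ref[, "I"])) / max(ref[, "I"]), 1e-6)
  expect_lt(max(abs(a$S - ref[, "S"])) / max(ref[, "S"]), 1e-6)
  # effective rate stays at beta when nobody ever becomes aware
  expect_equal(a$beta_eff, rep(p$beta, nrow(a)), tolerance = 1e-9)
})

test_that("stronger interventions give an earlier and lower peak", {
  lo <- glance(simulate_epidemic(fig1_params(rho = 0.2), t_max = 500))
  hi <- glance(simulate_epidemic(fig1_params(rho = 0.9, K = NULL), t_max = 500))
  expect_lt(hi$peak_I, lo$peak_I)
  expect_lt(hi$t_peak, lo$t_peak)
  expect_gte(lo$duration, lo$t_peak)
  expect_gte(hi$duration, hi$t_peak)
})

test_that("population conservation and susceptible monotonicity hold along trajectories", {
  p <- fig1_params(rho = 0.6, K = 12)
  tr <- simulate_epidemic(p, t_max = 300)
  a <- tidy(tr)
  expect_lt(max(abs(a$S + a$I + a$R - p$N)), 1e-8 * p$N)
  expect_true(all(diff(a$S) <= 1e-10))
})

test_that("summaries are invariant to the population scale", {
  s1 <- glance(simulate_epidemic(fig1_params(rho = 0.4, K = 12), t_max = 300))
  p6 <- fig1_params(rho = 0.4, K = 12, N = 1e6)
  s6 <- glance(simulate_epidemic(p6, t_max = 300))
  expect_equal(s6$peak_I / 1e6, s1$peak_I, tolerance = 1e-9)
  expect_equal(s6$final_S / 1e6, s1$final_S, tolerance = 1e-9)
  expect_equal(s6$t_peak, s1$t_peak, tolerance = 1e-7)
})

test_that("subcritical epidemics never grow and stay near the seed", {
  p <- fig1_params(beta = 0.9 * 0.133, K = 5)   # R0 = 0.9
  s <- glance(simulate_epidemic(p, t_max = 400))
  expect_equal(s$t_peak, 0)
  # total infections bounded by roughly seed / (1 - R0)
  expect_lt(s$total_infected, 1.5 * 1e-5 / (1 - 0.9))
  expect_gte(s$duration, s$t_peak)
})

test_that("trajectory accessors expose tidy aggregates", {
  tr <- simulate_epidemic(fig1_params(K = 6), t_max = 50, extend = FALSE)
  a <- tidy(tr)
  expect_s3_class(a, "tbl_df")
  expect_named(a, c("time", "S", "I", "R", "beta_eff", "R_e"))
  expect_true(all(is.finite(unlist(a))))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  g <- glance(tr)
  expect_named(g, c("peak_I", "t_peak", "final_S", "duration",
                    "total_infected", "converged"))
})
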