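test_that("reduced right-hand side matches direct substitution", {
  p <- fast_params(rho = 0.5)
  # no infectious pressure: only the aware infected compartment moves
  d0 <- fast_limit_rhs(c(0.5, 0.3, 0.01, 0, 0), p)
  expect_equal(unname(d0),
               c(0, 0, -(p$sigma + p$lambda) * 0.01,
                 (p$lambda) * 0.01, 0))
  # infection terms weight the level-1 infected by (1 - rho) twice
  st <- c(S1 = 0.5, Sinf = 0.3, I0 = 0, I1 = 0.02, Iinf = 0.01)
  dd <- fast_limit_rhs(st, p)
  force_inf <- (0.5 * 0.02 + 0.01) * p$beta
  expect_equal(dd[["S1"]], -0.5 * 0.5 * force_inf)
  expect_equal(dd[["Sinf"]], -0.3 * force_inf)
  expect_equal(dd[["I0"]], -p$sigma * 0 + p$omega * 0.02 - p$lambda * 0)
  expect_equal(sum(dd[c("S1", "Sinf")]),
               -(dd[["I1"]] + dd[["I0"]] + dd[["Iinf"]]) -
                 p$sigma * (0.02 + 0.01))
  # stationary aware infecteds: dI0/dt = 0 iff I0 = omega/(sigma+lambda) I1
  I1 <- 0.02
  I0 <- p$omega / (p$sigma + p$lambda) * I1
  ds <- fast_limit_rhs(c(0, 0, I0, I1, 0), p)
  expect_equal(ds[["I0"]], 0)
})

test_that("quasi-steady ratios follow the metastability closure", {
  p <- fast_params(beta = 0.333, rho = 0.5, d = 0.2)
  r <- quasi_steady_ratios(p)
  expect_equal(r$I0_over_I1, 0.33 / (0.133 + 0.2))
  expect_equal(r$Iinf_over_I1, 0.333 * 0.2 * 0.5 / (0.133 - 0.333 * 0.2))
  expect_equal(quasi_steady_ratios(update_params(p, omega = 0))$I0_over_I1, 0)
  expect_equal(quasi_steady_ratios(update_params(p, d = 0))$Iinf_over_I1, 0)
  expect_error(quasi_steady_ratios(update_params(p, d = 0.5)), "sigma/beta")
})

test_that("threshold quadratic coefficients match their closed forms", {
  p <- fast_params(beta = 0.333)
  co0 <- critical_quadratic_coeffs(0, p)
  expect_equal(unname(co0),
               c(1, 0, -(0.133 / 0.333) * (1 + 0.33 / (0.133 + 0.2))))
  co <- critical_quadratic_coeffs(0.2, p)
  y <- 0.333 / (0.133 - 0.333 * 0.2)
  expect_equal(co[["a"]], (1 - 0.2) * (1 + 0.2 * y))
  expect_equal(co[["b"]], 0.2 * (1 + 0.2 * y - y * 0.133 / 0.333))
  expect_equal(co[["c"]], co0[["c"]])
  expect_error(critical_quadratic_coeffs(0.5, p), "critical density")
  # sign structure guarantees a unique positive root
  for (d in seq(0, 0.39, by = 0.05)) {
    cd <- critical_quadratic_coeffs(d, p)
    expect_gt(cd[["a"]], 0); expect_lt(cd[["c"]], 0)
  }
})

test_that("analytic threshold equals an independent bisection of the quadratic", {
  p <- fast_params(beta = 0.333)
  for (d in c(0, 0.1, 0.2, 0.3)) {
    co <- critical_quadratic_coeffs(d, p)
    root <- uniroot(function(x) co[["a"]] * x^2 + co[["b"]] * x + co[["c"]],
                    c(1e-12, 10), tol = 1e-14)$root
    res <- critical_rho_analytic(d, p)
    expect_equal(res$rho_c, 1 - root, tolerance = 1e-9)
    expect_true(res$achievable)
  }
})

test_that("root residual vanishes and the threshold diverges at d_M", {
  p <- fast_params(beta = 0.467)
  d_M <- critical_density(p)
  grid <- seq(0, 0.99 * d_M, length.out = 60)
  res <- critical_rho_analytic(grid, p)
  for (i in seq_along(grid)) {
    co <- critical_quadratic_coeffs(grid[i], p)
    expect_lt(abs(co[["a"]] * res$x[i]^2 + co[["b"]] * res$x[i] + co[["c"]]),
              1e-12)
    expect_gt(res$x[i], 0)
  }
  expect_true(all(diff(res$rho_c) > 0))          # rho_c increases with d
  near <- critical_rho_analytic(d_M * (1 - 1e-6), p)
  expect_gt(near$rho_c, 0.99)                     # -> 1 as d -> d_M
  expect_false(critical_rho_analytic(d_M, p)$achievable)
  expect_false(critical_rho_analytic(0.9, p)$achievable)
})

test_that("subcritical diseases are suppressible at every composition", {
  p <- fast_params(beta = 0.12)                  # R0 < 1
  expect_gt(critical_density(p), 1)
  res <- critical_rho_analytic(seq(0, 1, by = 0.1), p)
  expect_true(all(res$achievable))
})

test_that("threshold sensitivities follow the information mechanisms", {
  p <- fast_params(beta = 0.333)
  d <- 0.15
  base <- critical_rho_analytic(d, p)$rho_c
  # faster refresh produces more information: less protection needed
  expect_lt(critical_rho_analytic(d, update_params(p, omega = 0.66))$rho_c, base)
  # faster fading loses information: more protection needed
  expect_gt(critical_rho_analytic(d, update_params(p, lambda = 0.4))$rho_c, base)
  # faster recovery at fixed R0: infecteds recover before refreshing
  p2 <- update_params(p, sigma = 2 * 0.133, beta = 2 * 0.333)
  expect_gt(critical_rho_analytic(d, p2)$rho_c, base)
})

test_that("full model with near-instant information follows the reduced model", {
  p <- fast_params(beta = 0.333, rho = 0.4, d = 0.2, K = 4)
  seed <- 1e-5
  init <- empty_state(p)
  init[p$K + 1, "S", "T"] <- (1 - p$d) * p$N - seed
  init[p$K + 1, "S", "D"] <- p$d * p$N - seed
  init[1, "I", "T"] <- seed                      # first-hand information exists
  init[p$K + 1, "I", "D"] <- seed
  tr <- simulate_epidemic(p, init = init, t_max = 250, n_out = 251,
                          extend = FALSE)
  red <- integrate_fast_limit(
    p, init = c(S1 = (1 - p$d) * p$N - seed, Sinf = p$d * p$N - seed,
                I0 = seed, I1 = 0, Iinf = seed),
    t_max = 250, n_out = 251)
  proj_S1 <- rowSums(sapply(1:p$K, function(l) tr$states[, l]))        # S_T finite
  nK <- p$K + 1
  proj_Sinf <- tr$states[, nK] + tr$states[, 3 * nK + nK]              # unaware S
  proj_I0 <- tr$states[, nK + 1] + tr$states[, 4 * nK + 1]
  proj_I1 <- rowSums(sapply(2:p$K, function(l) tr$states[, nK + l]))
  proj_Iinf <- tr$states[, 4 * nK + nK]
  late <- tr$times >= 1                          # skip the fast transient
  expect_lt(max(abs(proj_S1 - red$S1)[late]), 0.01 * p$N)
  expect_lt(max(abs(proj_Sinf - red$Sinf)[late]), 0.01 * p$N)
  expect_lt(max(abs(proj_I0 - red$I0)[late]), 0.01 * p$N)
  expect_lt(max(abs(proj_I1 - red$I1)[late]), 0.01 * p$N)
  expect_lt(max(abs(proj_Iinf - red$Iinf)[late]), 0.01 * p$N)
})
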