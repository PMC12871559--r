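test_that("double-reciprocal coefficients match hand-evaluated values", {
  gp <- general_params(Ks = 1, Vmax = 1, Ki = 1, gamma = 1, beta = 0)
  cf <- lb_coefficients(gp, I = c(0, 1))
  # I = 0 recovers Michaelis-Menten; I = 1: slope (1+1+1)/1 = 3,
  # intercept (1+1)/1 = 2 by direct arithmetic on the coefficient forms
  expect_equal(cf$slope, c(1, 3))
  expect_equal(cf$intercept, c(1, 2))

  expect_equal(rate_law(gp, S = 1, I = 0), 0.5)  # half-saturation
  expect_equal(rate_law(gp, S = 1, I = 1), 0.2)  # 1/(3 + 2)

  # reciprocal identity: 1/v0 = slope/S + intercept, exactly
  S <- c(0.625, 2.5, 25)
  I <- c(0, 40, 120)
  gp2 <- general_params(Ks = 1.3, Vmax = 7, Ki = 36, gamma = 0.5,
                        beta = 0.6)
  for (i in I) {
    cf <- lb_coefficients(gp2, i)
    expect_equal(1 / rate_law(gp2, S, rep(i, 3)),
                 cf$slope / S + cf$intercept, tolerance = 1e-14)
  }
})

test_that("domain errors are raised for invalid concentrations/parameters", {
  gp <- general_params(1, 1, 1, 1, 0.5)
  expect_error(lb_coefficients(gp, -1), "must be finite and >= 0")
  expect_error(rate_law(gp, S = 0, I = 0), "must be finite and > 0")
  expect_error(general_params(-1, 1, 1, 1, 0), "Ks")
  expect_error(general_params(1, 1, 1, 1, 1.2), "beta")
  expect_error(traditional_params(Ki = 10, mechanism = "linear_mixed"),
               "requires an alpha")
  expect_error(traditional_params(Ki = 10, alpha = 0.8,
                                  mechanism = "linear_mixed"),
               "> 1")
  expect_error(traditional_params(Ki = 10, alpha = 3,
                                  mechanism = "linear_competitive"),
               "does not apply")
})

test_that("I = 0 reduces every parameter set to Michaelis-Menten", {
  set.seed(11)
  for (k in 1:25) {
    gp <- general_params(Ks = runif(1, 0.1, 10), Vmax = runif(1, 0.5, 20),
                         Ki = runif(1, 1, 200), gamma = exp(runif(1, -3, 3)),
                         beta = runif(1))
    cf <- lb_coefficients(gp, 0)
    expect_equal(cf$slope, gp$Ks / gp$Vmax, tolerance = 1e-14)
    expect_equal(cf$intercept, 1 / gp$Vmax, tolerance = 1e-14)
  }
})

test_that("beta endpoints produce the stated coefficient structure", {
  I <- c(0, 20, 40, 80, 120)
  # beta = 1: intercept independent of I; slope saturates at 1 + 1/gamma
  # times the uninhibited slope
  gp1 <- general_params(1.3, 1, 45, gamma = 0.5, beta = 1)
  cf1 <- lb_coefficients(gp1, I)
  expect_equal(cf1$intercept, rep(1, 5))
  cf_inf <- lb_coefficients(gp1, 1e12)
  expect_equal(cf_inf$slope / cf1$slope[1], 1 + 1 / gp1$gamma,
               tolerance = 1e-9)
  # beta = 0: coefficients equal the dead-end-ESI limiting law identically
  gp0 <- general_params(1.3, 1, 36, gamma = 0.5, beta = 0)
  cf0 <- lb_coefficients(gp0, I)
  expect_equal(cf0$slope,
               (1.3 / 1) * (1 + I / (0.5 * 36) + I / 36), tolerance = 1e-14)
  expect_equal(cf0$intercept, (1 / 1) * (1 + I / 36), tolerance = 1e-14)
})

test_that("intermediate beta with large gamma plateaus both profiles at 1/beta", {
  gp <- general_params(1.3, 1, 36, gamma = 1e8, beta = 0.6)
  cf0 <- lb_coefficients(gp, 0)
  cf_inf <- lb_coefficients(gp, 1e10)
  expect_equal(cf_inf$slope / cf0$slope, 1 / 0.6, tolerance = 1e-6)
  expect_equal(cf_inf$intercept / cf0$intercept, 1 / 0.6, tolerance = 1e-6)
  # gamma >> 1: slope/intercept ratio constant in I (lines pivot on the
  # 1/S axis)
  I <- c(0, 20, 40, 80, 120)
  cf <- lb_coefficients(gp, I)
  ratio <- cf$slope / cf$intercept
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-6)
})

test_that("an innocuous inhibitor (beta = 1, gamma large) leaves rates unchanged", {
  gp <- general_params(2, 5, 30, gamma = 1e10, beta = 1)
  un <- general_params(2, 5, 30, gamma = 1e10, beta = 1)
  S <- c(0.625, 5, 25)
  expect_equal(rate_law(gp, S, rep(120, 3)), rate_law(un, S, rep(0, 3)),
               tolerance = 1e-8)
})

test_that("limiting mechanism assignment follows the gamma/beta regimes", {
  expect_equal(limiting_mechanism(general_params(1, 1, 45, 0.5, 1)),
               "partial_competitive")
  expect_equal(limiting_mechanism(general_params(1, 1, 36, 0.5, 0)),
               "linear_mixed")
  expect_equal(limiting_mechanism(general_params(1, 1, 36, 0.5, 0.6)),
               "partial_mixed")
  expect_equal(limiting_mechanism(general_params(1, 1, 1e4, 0.001, 1)),
               "linear_competitive")
  expect_equal(limiting_mechanism(general_params(1, 1, 36, 200, 0)),
               "linear_noncompetitive")
  expect_equal(limiting_mechanism(general_params(1, 1, 36, 200, 0.6)),
               "partial_noncompetitive")
  # beta snapping at the classification tolerance
  expect_equal(limiting_mechanism(general_params(1, 1, 36, 0.5, 0.96)),
               "partial_competitive")
  expect_equal(limiting_mechanism(general_params(1, 1, 36, 0.5, 0.04)),
               "linear_mixed")
})

test_that("alpha-gamma relation is exact, monotone and involutive", {
  expect_equal(alpha_from_gamma(0.5), 3)
  expect_equal(alpha_from_gamma(1), 2)
  expect_equal(gamma_from_alpha(3), 0.5)
  expect_equal(gamma_from_alpha(12), 1 / 11)
  g <- exp(seq(-4, 4, length.out = 40))
  a <- alpha_from_gamma(g)
  expect_true(all(diff(a) < 0))            # strictly decreasing in gamma
  expect_equal(gamma_from_alpha(a), g, tolerance = 1e-14)  # round trip
  expect_equal(alpha_from_gamma(1e8), 1, tolerance = 1e-7) # hindrance gone
  expect_error(gamma_from_alpha(1), "> 1")
  expect_error(gamma_from_alpha(0.5), "> 1")
})

test_that("traditional parameters map exactly onto the two-site model", {
  # reported wild-type regimes: the matched general constants
  imid <- as_general_params(
    traditional_params(Ki = 15, alpha = 3, mechanism = "partial_competitive"))
  expect_equal(imid$Ki, 45)
  expect_equal(imid$gamma_Ki, 22.5)
  tris <- as_general_params(
    traditional_params(Ki = 12, alpha = 3, mechanism = "linear_mixed"))
  expect_equal(tris$Ki, 36)
  expect_equal(tris$gamma_Ki, 18)
  # strongly outer-site-disfavored linear mixed regime
  lm12 <- as_general_params(
    traditional_params(Ki = 10, alpha = 12, mechanism = "linear_mixed"))
  expect_equal(lm12$Ki, 120)
  expect_equal(lm12$gamma, 1 / 11)
})

test_that("traditional and mapped general laws share coefficients on an I grid", {
  I <- c(0, 5, 20, 40, 80, 120)
  cases <- list(
    traditional_params(Ki = 15, alpha = 3, mechanism = "partial_competitive",
                       Ks = 1.3, Vmax = 7),
    traditional_params(Ki = 12, alpha = 3, mechanism = "linear_mixed",
                       Ks = 1.3, Vmax = 7),
    traditional_params(Ki = 12, alpha = 3, beta = 0.6,
                       mechanism = "partial_mixed", Ks = 1.3, Vmax = 7),
    traditional_params(Ki = 10, alpha = 12, mechanism = "linear_mixed",
                       Ks = 2, Vmax = 1)
  )
  for (tp in cases) {
    gp <- as_general_params(tp)
    expect_equal(lb_coefficients(gp, I), lb_coefficients(tp, I),
                 tolerance = 1e-12)
    # rates agree too, on a full (S, I) grid
    grid <- expand.grid(S = c(0.625, 2.5, 10, 25), I = I)
    expect_equal(rate_law(gp, grid$S, grid$I),
                 rate_law(tp, grid$S, grid$I), tolerance = 1e-12)
    # and the inverse coefficient matching recovers (Ki, alpha, beta)
    back <- as_traditional_params(gp)
    expect_equal(back$mechanism, tp$mechanism)
    expect_equal(back$Ki, tp$Ki, tolerance = 1e-12)
    expect_equal(back$alpha, tp$alpha, tolerance = 1e-12)
    if (!is.na(tp$beta)) expect_equal(back$beta, tp$beta)
  }
})

test_that("unmappable and partially identifiable traditional sets are flagged", {
  nc <- traditional_params(Ki = 36, mechanism = "linear_noncompetitive")
  expect_error(as_general_params(nc), "no exact finite-gamma")
  lc <- as_general_params(
    traditional_params(Ki = 18, mechanism = "linear_competitive"))
  expect_equal(lc$gamma_Ki, 18)  # active-site constant only
  expect_true(is.na(lc$Ki))
  expect_match(lc$note, "gamma << 1", fixed = TRUE)
})
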