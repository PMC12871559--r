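test_that("noiseless classification recovers every generating regime (identity confusion matrix)", {
  truths <- regime_truths()
  calls <- vapply(truths, function(gp) {
    noiseless_fit(gp)$mechanism$mechanism
  }, character(1))
  expect_equal(unname(calls), names(truths))
  # and each call agrees with the limiting-form oracle on the generator
  oracle <- vapply(truths, limiting_mechanism, character(1))
  expect_equal(calls, oracle)
})

test_that("parallel-line (uncompetitive) data are flagged out of family", {
  d <- uncompetitive_rates()
  expect_warning(fit <- inhibfit(d), "no traditional parameter")
  expect_equal(fit$mechanism$mechanism, "uncompetitive_out_of_family")
  expect_null(fit$traditional)
})

test_that("classical estimation round-trips traditional truths", {
  # linear competitive truth, Ki = 18 mM
  tp <- traditional_params(Ki = 18, mechanism = "linear_competitive",
                           Ks = 1.3, Vmax = 1)
  fit <- suppressWarnings(inhibfit(simulate_rates(tp, reference_design())))
  expect_equal(fit$mechanism$mechanism, "linear_competitive")
  expect_equal(fit$traditional$Ki, 18, tolerance = 1e-9)
  # competitive saturation check: at saturating substrate the rate
  # approaches Vmax regardless of inhibitor
  expect_equal(rate_law(tp, S = 1e9, I = 18), 1, tolerance = 1e-6)

  # two-site truths analyzed by the classical route give the matched
  # traditional parameters
  f_im <- noiseless_fit(general_params(1.3, 1, 45, 0.5, 1))
  expect_equal(f_im$traditional$Ki, 15, tolerance = 1e-8)
  expect_equal(f_im$traditional$alpha, 3, tolerance = 1e-8)
  f_tris <- noiseless_fit(general_params(1.3, 1, 36, 0.5, 0))
  expect_equal(f_tris$traditional$Ki, 12, tolerance = 1e-8)
  expect_equal(f_tris$traditional$alpha, 3, tolerance = 1e-8)
  f_pm <- noiseless_fit(general_params(1.3, 1, 36, 0.5, 0.6))
  expect_equal(f_pm$traditional$beta, 0.6, tolerance = 1e-8)
  expect_equal(f_pm$traditional$Ki, 12, tolerance = 1e-8)
  routes <- attr(f_pm$traditional, "beta_routes")
  expect_equal(unname(routes["replot"]), unname(routes["plateau"]),
               tolerance = 1e-6)
})

test_that("reparameterized general constants satisfy the alpha-gamma identity", {
  fits <- list(noiseless_fit(general_params(1.3, 1, 45, 0.5, 1)),
               noiseless_fit(general_params(1.3, 1, 36, 0.5, 0)),
               noiseless_fit(general_params(1.3, 1, 36, 0.5, 0.6)))
  for (f in fits) {
    expect_equal(f$traditional$alpha,
                 1 / f$general$gamma + 1, tolerance = 1e-12)
    expect_equal(f$general$gamma_Ki, f$general$gamma * f$general$Ki,
                 tolerance = 1e-12)
  }
  # competitive data report only the active-site constant
  f_lc <- noiseless_fit(regime_truths()$linear_competitive)
  expect_true(is.na(f_lc$general$Ki))
  expect_equal(f_lc$general$gamma_Ki, 22.5, tolerance = 1e-4)
})

test_that("classification is invariant to rate and concentration rescaling", {
  base <- general_params(1.3, 1, 36, 0.5, 0.6)
  d <- simulate_rates(base, reference_design())
  mech0 <- inhibfit(d)$mechanism$mechanism
  # rescale Vmax (all rates x 37)
  d_v <- d; d_v$v0 <- d_v$v0 * 37
  expect_equal(inhibfit(d_v)$mechanism$mechanism, mech0)
  # joint rescale of S and Ks (mechanism depends on dimensionless groups)
  scaled <- general_params(1.3 * 8, 1, 36, 0.5, 0.6)
  des <- reference_design()
  d_s <- simulate_rates(scaled, assay_design(S = des$S * 8, I = des$I,
                                             replicates = des$replicates))
  fit_s <- inhibfit(d_s)
  expect_equal(fit_s$mechanism$mechanism, mech0)
  expect_equal(fit_s$traditional$Ki, 12, tolerance = 1e-8)
})

test_that("global fit recovers identifiable parameters exactly on noiseless data", {
  for (g in c(0.09, 0.5, 1, 5)) {
    for (b in c(0, 0.6, 1)) {
      truth <- general_params(1.3, 7, 36, g, b)
      gf <- global_fit(simulate_rates(truth, reference_design()))
      est <- coef(gf$params)
      for (nm in c("Ks", "Vmax", "Ki", "gamma")) {
        expect_equal(est[[nm]], coef(truth)[[nm]], tolerance = 1e-6,
                     label = sprintf("%s (gamma=%g, beta=%g)", nm, g, b))
      }
      expect_equal(est[["beta"]], b, tolerance = 1e-6)
    }
  }
})

test_that("global fit flags boundary and near-1 beta identifiability", {
  gf <- global_fit(simulate_rates(general_params(1.3, 7, 45, 0.5, 1),
                                  reference_design()))
  expect_true(any(grepl("beta near 1", gf$notes)))
  expect_error(global_fit(simulate_rates(
    general_params(1.3, 1, 45, 0.5, 1),
    assay_design(S = c(1, 2, 5), I = c(0, 20, 40, 80)))),
    ">= 4 inhibitor and >= 5 substrate")
})

test_that("secondary-plot and global routes agree on noiseless data", {
  truth <- general_params(1.3, 1, 36, 0.5, 0)
  fit <- noiseless_fit(truth, method = "global")
  sec <- as_general_params(fit$traditional)
  glo <- fit$global$params
  expect_equal(glo$Ki, sec$Ki, tolerance = 1e-6)
  expect_equal(glo$gamma, sec$gamma, tolerance = 1e-6)
  # both parameterizations describe the data equally well: equal SSE
  pred_sec <- rate_law(sec, fit$data$S_mM, fit$data$I_mM)
  expect_equal(sum((fit$data$v0 - pred_sec)^2), fit$global$sse,
               tolerance = 1e-10)
})

test_that("noisy global fits are accurate and unbiased within Monte-Carlo error", {
  truth <- general_params(1.3, 1, 45, 0.5, 1)
  # single benchmark fit at the reference design and 5% rate noise
  d1 <- simulate_rates(truth, reference_design(noise_cv = 0.05, seed = 2024))
  gf1 <- global_fit(d1)
  expect_lt(abs(coef(gf1$params)[["Ki"]] - 45) / 45, 0.2)
  # repeat-simulation distribution of the estimator
  kis <- vapply(seq_len(200), function(s) {
    d <- simulate_rates(truth,
                        reference_design(noise_cv = 0.05, seed = 10000 + s))
    coef(global_fit(d)$params)[["Ki"]]
  }, numeric(1))
  se <- stats::sd(kis) / sqrt(length(kis))
  expect_lt(abs(mean(kis) - 45), 3 * se + 0.05 * 45)
  expect_lt(abs(stats::median(kis) - 45) / 45, 0.1)
})

test_that("the fitted model object supports the standard accessors", {
  truth <- general_params(1.3, 1, 36, 0.5, 0.6)
  d <- simulate_rates(truth, reference_design())
  fit <- inhibfit(v0 ~ S_mM + I_mM + replicate, data = d)
  expect_s3_class(fit, "inhibfit")
  expect_named(coef(fit),
               c("Ks", "Vmax", "Ki", "gamma", "beta", "gamma_Ki"))
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)
  expect_equal(predict(fit, data.frame(S = 2.5, I = 40)),
               rate_law(truth, 2.5, 40), tolerance = 1e-8)
  sim <- simulate(fit, nsim = 1, seed = 5)
  expect_s3_class(sim, "rate_data")
  expect_equal(nrow(sim), nrow(d))
  out <- utils::capture.output(summary(fit))
  expect_true(any(grepl("partial_mixed", out)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
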