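# shared fixtures: one generating parameter set per noiseless limiting
# regime, chosen so the assay design (I up to 120 mM) actually expresses
# the regime. The "<<"/">>" regimes use gamma far beyond the classifier
# cut-offs so that the residual curvature of the exact rate law is below
# the secondary-form SSE floor.
regime_truths <- function(Ks = 1.3, Vmax = 1) {
  list(
    linear_competitive = general_params(Ks, Vmax, Ki = 22.5e8,
                                        gamma = 1e-8, beta = 1),
    partial_competitive = general_params(Ks, Vmax, Ki = 45,
                                         gamma = 0.5, beta = 1),
    linear_mixed = general_params(Ks, Vmax, Ki = 36, gamma = 0.5, beta = 0),
    linear_noncompetitive = general_params(Ks, Vmax, Ki = 36,
                                           gamma = 1e8, beta = 0),
    partial_mixed = general_params(Ks, Vmax, Ki = 36, gamma = 0.5,
                                   beta = 0.6),
    partial_noncompetitive = general_params(Ks, Vmax, Ki = 36,
                                            gamma = 1e8, beta = 0.6)
  )
}

noiseless_fit <- function(params, ...) {
  suppressWarnings(
    inhibfit(simulate_rates(params, reference_design()), ...))
}

# uncompetitive (parallel-line) rate law, used to probe the out-of-family
# flag; the inhibitor binds only the ES complex:
# 1/v0 = (Ks/Vmax)(1/S) + (1/Vmax)(1 + I/Ki)
uncompetitive_rates <- function(Ks = 1.3, Vmax = 1, Ki = 30,
                                design = reference_design()) {
  grid <- expand.grid(S_mM = design$S, I_mM = design$I,
                      replicate = seq_len(design$replicates))
  slope <- Ks / Vmax
  intercept <- (1 / Vmax) * (1 + grid$I_mM / Ki)
  grid$v0 <- 1 / (slope / grid$S_mM + intercept)
  structure(grid[, c("S_mM", "I_mM", "replicate", "v0")],
            class = c("rate_data", "data.frame"))
}
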