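#' Classify the inhibition mechanism from a secondary profile
#'
#' Decision tree over the fitted slope/intercept forms of a
#' [fit_secondary()] profile:
#' \enumerate{
#'   \item constant slope with rising intercept: parallel lines, the
#'     uncompetitive pattern, outside the intersecting family;
#'   \item constant intercept: competitive family (lines converge on the
#'     y-axis); linear slope growth gives linear competitive, saturating
#'     growth partial competitive;
#'   \item both rising: if the slope/intercept ratio is constant across
#'     inhibitor levels the lines cross on the 1/S axis (non-competitive
#'     family), otherwise in the second quadrant (mixed); linear forms give
#'     the linear variant, hyperbolic forms the partial variant.
#' }
#' Profiles whose slope and intercept forms disagree (one linear, one
#' hyperbolic) where the family requires them to agree are reported as
#' `inconclusive` rather than silently forced into a class.
#'
#' @param profile A [fit_secondary()] result.
#' @return An object of class `"mechanism_call"`: list with `mechanism`
#'   (a [mechanism_classes] label) and the `evidence` behind it.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' prof <- fit_secondary(fit_lb_lines(simulate_rates(gp, reference_design())))
#' classify_mechanism(prof)
#' @export
classify_mechanism <- function(profile) {
  stopifnot(inherits(profile, "secondary_profile"))
  sf <- profile$slope_model$form
  itf <- profile$intercept_model$form
  evidence <- list(slope_form = sf, intercept_form = itf,
                   ratio_cv = profile$ratio_cv, crossing = profile$crossing)
  mech <- if (sf == "constant" && itf != "constant") {
    "uncompetitive_out_of_family"
  } else if (itf == "constant") {
    switch(sf,
           linear = "linear_competitive",
           hyperbolic = "partial_competitive",
           constant = "inconclusive")  # no inhibition signal at all
  } else if (profile$crossing == "1/S-axis") {
    if (sf == "linear" && itf == "linear") "linear_noncompetitive"
    else if (sf == "hyperbolic" && itf == "hyperbolic")
      "partial_noncompetitive"
    else "inconclusive"
  } else {
    if (sf == "linear" && itf == "linear") "linear_mixed"
    else if (sf == "hyperbolic" && itf == "hyperbolic") "partial_mixed"
    else "inconclusive"
  }
  structure(list(mechanism = mech, evidence = evidence),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Mechanism call:", x$mechanism, "\n")
  ev <- x$evidence
  cat(sprintf("  slope(I) %s, intercept(I) %s, ratio CV %.3g, crossing %s\n",
              ev$slope_form, ev$intercept_form, ev$ratio_cv, ev$crossing))
  invisible(x)
}

#' Estimate traditional parameters from the secondary analysis
#'
#' Implements the classical estimation route for each intersecting
#' mechanism:
#' \itemize{
#'   \item linear mechanisms: the inhibition constant comes from the
#'     slope-versus-I regression (`Ki = a/b` for fit `a + b I`), and for
#'     linear mixed the ESI constant `alpha*Ki` analogously from the
#'     intercept regression, so `alpha` is their ratio;
#'   \item hyperbolic mechanisms: the reciprocal-difference replots of
#'     [delta_replot()] linearise the saturating profiles. For partial
#'     competitive, `alpha = 1 + delta_max/slope(0)` (the slope plateau is
#'     `alpha` times the uninhibited slope) and `alpha*Ki` is the ratio of
#'     the replot coefficients. For partial mixed, `beta` follows from the
#'     intercept plateau (`limiting value = intercept(0)/beta`), `alpha*Ki`
#'     from the intercept replot, and `Ki` from the slope replot. For
#'     partial non-competitive the shared factor gives `beta` and `Ki`
#'     directly.
#' }
#' `Ks` and `Vmax` come from the uninhibited line (`Vmax = 1/intercept(0)`,
#' `Ks = slope(0)/intercept(0)`).
#'
#' @param profile A [fit_secondary()] result.
#' @param mechanism A mechanism label, typically from
#'   [classify_mechanism()]; `uncompetitive_out_of_family` and
#'   `inconclusive` profiles cannot be estimated here.
#' @return A [traditional_params()] object; for hyperbolic mechanisms the
#'   attribute `"beta_routes"` reports the plateau read-off from the
#'   hyperbolic secondary fit alongside the replot-based estimate actually
#'   used.
#' @export
estimate_traditional <- function(profile, mechanism) {
  stopifnot(inherits(profile, "secondary_profile"))
  mechanism <- match.arg(mechanism, mechanism_classes)
  keep <- profile$lines
  s0 <- keep$slope[keep$I == 0][1]
  i0 <- keep$intercept[keep$I == 0][1]
  Vmax <- 1 / i0
  Ks <- s0 / i0
  lin_K <- function(which) {
    fit <- stats::lm(y ~ I, data = data.frame(I = keep$I, y = keep[[which]]))
    cf <- stats::coef(fit)
    if (cf[2] <= 0) {
      stop("apparent ", which, " does not increase with inhibitor; ",
           "linear-mechanism estimation inapplicable", call. = FALSE)
    }
    unname(cf[1] / cf[2])
  }
  switch(mechanism,
    linear_competitive = traditional_params(
      Ki = lin_K("slope"), mechanism = mechanism, Ks = Ks, Vmax = Vmax),
    linear_noncompetitive = traditional_params(
      Ki = lin_K("slope"), mechanism = mechanism, Ks = Ks, Vmax = Vmax),
    linear_mixed = {
      Ki <- lin_K("slope")
      aKi <- lin_K("intercept")
      traditional_params(Ki = Ki, alpha = aKi / Ki, mechanism = mechanism,
                         Ks = Ks, Vmax = Vmax)
    },
    partial_competitive = {
      rp <- delta_replot(keep, "slope")
      if (!is.finite(rp$delta_max)) {
        stop("slope replot implies no saturation; partial-competitive ",
             "estimation inapplicable", call. = FALSE)
      }
      alpha <- 1 + rp$delta_max / rp$y0   # slope plateau = alpha * slope(0)
      aKi <- rp$slope / rp$intercept
      traditional_params(Ki = aKi / alpha, alpha = alpha,
                         mechanism = mechanism, Ks = Ks, Vmax = Vmax)
    },
    partial_mixed = {
      rp_i <- delta_replot(keep, "intercept")
      rp_s <- delta_replot(keep, "slope")
      # intercept replot: 1/delta = (A/(i0(1-b))) (1/I) + b/(i0(1-b)),
      # A = alpha*Ki; plateau i0/b recovers b, then A, then Ki from the
      # slope replot gradient 1/(s0 (1/Ki - b/A)).
      beta <- i0 * rp_i$intercept / (1 + i0 * rp_i$intercept)
      if (beta <= 0 || beta >= 1) {
        stop("intercept replot implies beta outside (0, 1); partial-mixed ",
             "estimation inapplicable", call. = FALSE)
      }
      A <- beta * rp_i$slope / rp_i$intercept
      Ki <- 1 / (1 / (s0 * rp_s$slope) + beta / A)
      out <- traditional_params(Ki = Ki, alpha = A / Ki, beta = beta,
                                mechanism = mechanism, Ks = Ks, Vmax = Vmax)
      attr(out, "beta_routes") <- c(
        replot = beta,
        plateau = if (!is.null(profile$intercept_model$plateau))
          unname(i0 / profile$intercept_model$plateau) else NA_real_)
      out
    },
    partial_noncompetitive = {
      rp_i <- delta_replot(keep, "intercept")
      beta <- i0 * rp_i$intercept / (1 + i0 * rp_i$intercept)
      if (beta <= 0 || beta >= 1) {
        stop("intercept replot implies beta outside (0, 1); ",
             "partial-non-competitive estimation inapplicable",
             call. = FALSE)
      }
      rp_s <- delta_replot(keep, "slope")
      Ki <- s0 * (1 - beta) * rp_s$slope
      out <- traditional_params(Ki = Ki, beta = beta, mechanism = mechanism,
                                Ks = Ks, Vmax = Vmax)
      attr(out, "beta_routes") <- c(
        replot = beta,
        plateau = if (!is.null(profile$intercept_model$plateau))
          unname(i0 / profile$intercept_model$plateau) else NA_real_)
      out
    },
    stop("cannot estimate traditional parameters for mechanism '",
         mechanism, "'", call. = FALSE)
  )
}

#' Reparameterize estimated traditional parameters into the two-site model
#'
#' Applies the exact coefficient-matching map of [as_general_params()]:
#' `gamma = 1/(alpha - 1)`, outer-site `Ki = alpha * Ki_traditional`,
#' active-site constant `gamma * Ki`. For competitive mechanisms only the
#' active-site constant is identifiable (`gamma << 1` bound); the outer
#' `Ki` is reported as `NA` with a note, matching the convention of
#' reporting no finite `gamma` for purely competitive data.
#'
#' @param traditional A [traditional_params()] object.
#' @return A [general_params()] object (with `NA` fields and a note when
#'   identifiability is partial).
#' @examples
#' infer_general(traditional_params(Ki = 12, alpha = 3,
#'                                  mechanism = "linear_mixed"))
#' @export
infer_general <- function(traditional) {
  stopifnot(inherits(traditional, "traditional_params"))
  p <- traditional
  if (p$mechanism %in% c("linear_noncompetitive",
                         "partial_noncompetitive")) {
    # gamma >> 1 limit: both complexes bind through the outer site; the
    # active-site constant gamma*Ki is pushed out of reach of the data
    new_general_params(Ks = p$Ks, Vmax = p$Vmax, Ki = p$Ki,
                       gamma = NA_real_,
                       beta = if (is.na(p$beta)) 0 else p$beta,
                       gamma_Ki = NA_real_,
                       note = paste("gamma >> 1 regime: outer-site Ki only;",
                                    "active-site constant unidentifiable"))
  } else {
    as_general_params(p)
  }
}

#' Global nonlinear fit of the two-site rate law
#'
#' Fits all five general-model parameters by least squares on the rates
#' themselves (not their reciprocals, so reciprocal-space noise distortion
#' is avoided): `v0 = Vmax S (1 + beta I/Ki) / (Ks (1 + I/(gamma Ki) +
#' I/Ki) + S (1 + I/Ki))`. `Ks`, `Vmax`, `Ki` and `gamma` are optimised on
#' the log scale; `beta` is bounded to `[0, 1]`. Starting values default to
#' the classical secondary-plot estimates when those are obtainable and
#' fall back to coarse heuristics otherwise.
#'
#' When the fitted `beta` is at (or numerically against) a bound, or
#' `beta` is near 1 -- where the intercept carries no inhibitor
#' information and only the slope constrains `gamma*Ki` and `Ki` -- a
#' warning note is attached rather than silently reporting an
#' over-confident parameter set.
#'
#' @param data A `rate_data` data frame with >= 4 inhibitor levels and
#'   >= 5 substrate levels.
#' @param start Optional named list/vector with elements `Ks`, `Vmax`,
#'   `Ki`, `gamma`, `beta` overriding the automatic initialisation.
#' @return A list of class `"global_fit"`: the fitted [general_params()],
#'   the Levenberg-Marquardt optimizer result, residual summary and any
#'   identifiability notes.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 7, Ki = 45, gamma = 0.5, beta = 1)
#' gf <- global_fit(simulate_rates(gp, reference_design()))
#' coef(gf$params)
#' @export
global_fit <- function(data, start = NULL) {
  data <- as.data.frame(data)
  if (length(unique(data$I_mM)) < 4 || length(unique(data$S_mM)) < 5) {
    stop("global fit needs >= 4 inhibitor and >= 5 substrate levels",
         call. = FALSE)
  }
  if (is.null(start)) start <- .global_start(data)
  start <- as.list(start)
  st <- c(lKs = log(start$Ks), lV = log(start$Vmax), lKi = log(start$Ki),
          lg = log(start$gamma),
          beta = min(max(start$beta, 0), 1))
  S <- data$S_mM; I <- data$I_mM; v <- data$v0
  model_v <- function(par) {
    Ki <- exp(par[["lKi"]])
    exp(par[["lV"]]) * S * (1 + par[["beta"]] * I / Ki) /
      (exp(par[["lKs"]]) * (1 + I / (exp(par[["lg"]]) * Ki) + I / Ki) +
         S * (1 + I / Ki))
  }
  fit <- minpack.lm::nls.lm(
    par = st, fn = function(par) v - model_v(par),
    lower = c(lKs = -30, lV = -30, lKi = -30, lg = -30, beta = 0),
    upper = c(lKs = 30, lV = 30, lKi = 30, lg = 30, beta = 1),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info == 0 || fit$info == 9) {
    stop("global fit did not converge (", fit$message, ")", call. = FALSE)
  }
  cf <- fit$par
  params <- general_params(Ks = exp(cf[["lKs"]]), Vmax = exp(cf[["lV"]]),
                           Ki = exp(cf[["lKi"]]), gamma = exp(cf[["lg"]]),
                           beta = cf[["beta"]])
  notes <- character()
  if (cf[["beta"]] <= 1e-8 || cf[["beta"]] >= 1 - 1e-8) {
    notes <- c(notes, sprintf("beta pinned at boundary (%.3g)",
                              cf[["beta"]]))
  }
  if (cf[["beta"]] >= 0.95) {
    notes <- c(notes, paste("beta near 1: intercepts carry no inhibitor",
                            "information; Ki and gamma are constrained",
                            "through the slope profile only"))
  }
  res <- fit$fvec
  structure(list(params = params, fit = fit, start = start,
                 sse = sum(res^2), rmse = sqrt(mean(res^2)), notes = notes),
            class = "global_fit")
}

# starting values for the global fit: try the classical route, fall back
# to coarse moment-style guesses
.global_start <- function(data) {
  guess <- tryCatch({
    lines <- fit_lb_lines(data)
    prof <- fit_secondary(lines)
    mech <- classify_mechanism(prof)$mechanism
    tp <- estimate_traditional(prof, mech)
    gp <- as_general_params(tp)
    if (is.na(gp$Ki)) {
      # competitive: outer site unseen; start gamma small with the
      # active-site constant fixed at the estimate
      list(Ks = gp$Ks, Vmax = gp$Vmax, Ki = gp$gamma_Ki / 0.01,
           gamma = 0.01, beta = 1)
    } else {
      list(Ks = gp$Ks, Vmax = gp$Vmax, Ki = gp$Ki, gamma = gp$gamma,
           beta = if (is.na(gp$beta)) 0.5 else gp$beta)
    }
  }, error = function(e) NULL)
  if (!is.null(guess)) return(guess)
  base <- data[data$I_mM == min(data$I_mM), , drop = FALSE]
  Vmax <- max(base$v0) * 1.2
  Ks <- stats::median(base$S_mM)
  list(Ks = Ks, Vmax = Vmax, Ki = stats::median(data$I_mM[data$I_mM > 0]),
       gamma = 1, beta = 0.5)
}

#' @export
print.global_fit <- function(x, digits = 4, ...) {
  cat("Global nonlinear fit of the two-site rate law\n")
  print(x$params, digits = digits)
  cat(sprintf("  SSE = %.4g, RMSE = %.4g\n", x$sse, x$rmse))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
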