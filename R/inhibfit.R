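#' Fit an enzyme inhibition mechanism to initial-rate data
#'
#' The package's main entry point: runs the full classical analysis chain
#' on an initial-rate dataset -- per-inhibitor-level double-reciprocal fits
#' ([fit_lb_lines()]), secondary slope/intercept analysis
#' ([fit_secondary()]), mechanism classification ([classify_mechanism()]),
#' traditional parameter estimation ([estimate_traditional()]) and
#' reparameterization into the general two-site model ([infer_general()]).
#' With `method = "global"` a direct nonlinear fit of the two-site rate law
#' ([global_fit()]) is run in addition, initialised from the classical
#' estimates.
#'
#' @param object A data frame of rates, or a formula such as
#'   `v0 ~ S_mM + I_mM` naming the rate, substrate and inhibitor columns of
#'   `data` (in that order; a `replicate` column is picked up when
#'   present).
#' @param ... Passed between methods.
#' @return An object of class `"inhibfit"` with components `lines`,
#'   `profile`, `mechanism` (a `mechanism_call`), `traditional`, `general`,
#'   and (for `method = "global"`) `global`. Standard accessors apply:
#'   [coef.inhibfit()], [predict.inhibfit()], [residuals.inhibfit()],
#'   [fitted.inhibfit()], [simulate.inhibfit()], [plot.inhibfit()],
#'   [summary.inhibfit()].
#' @examples
#' truth <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5,
#'                         beta = 1)
#' fit <- inhibfit(simulate_rates(truth, reference_design()))
#' fit
#' coef(fit)
#' @export
inhibfit <- function(object, ...) UseMethod("inhibfit")

#' @rdname inhibfit
#' @param formula A formula `rate ~ substrate + inhibitor` (column names in
#'   `data`); a third right-hand term, if given, names the replicate
#'   column.
#' @param data Data frame holding the columns named in `formula`.
#' @export
inhibfit.formula <- function(formula, data, ...) {
  tm <- stats::terms(formula)
  rhs <- attr(tm, "term.labels")
  lhs <- as.character(formula[[2]])
  if (length(rhs) < 2) {
    stop("formula must name substrate and inhibitor columns, e.g. ",
         "v0 ~ S_mM + I_mM", call. = FALSE)
  }
  cols <- c(lhs, rhs)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(S_mM = data[[rhs[1]]], I_mM = data[[rhs[2]]],
                  v0 = data[[lhs]])
  d$replicate <- if (length(rhs) >= 3) data[[rhs[3]]] else 1L
  out <- inhibfit.data.frame(d, ...)
  out$call <- match.call()
  out
}

#' @rdname inhibfit
#' @param method `"secondary"` for the classical reciprocal-space route
#'   alone, `"global"` to add the direct nonlinear fit of the two-site law.
#' @param r2_min Acceptance threshold for the primary line fits.
#' @param f_alpha Significance level of the secondary-form F-tests.
#' @param ratio_cv_tol Tolerance for the slope/intercept ratio-constancy
#'   diagnostic.
#' @export
inhibfit.data.frame <- function(object, method = c("secondary", "global"),
                                r2_min = 0.9, f_alpha = 0.05,
                                ratio_cv_tol = 0.01, ...) {
  method <- match.arg(method)
  data <- object
  lines <- fit_lb_lines(data, r2_min = r2_min)
  profile <- fit_secondary(lines, f_alpha = f_alpha,
                           ratio_cv_tol = ratio_cv_tol)
  mech <- classify_mechanism(profile)
  traditional <- general <- NULL
  if (!mech$mechanism %in% c("uncompetitive_out_of_family",
                             "inconclusive")) {
    traditional <- estimate_traditional(profile, mech$mechanism)
    general <- infer_general(traditional)
  } else {
    warning("mechanism '", mech$mechanism,
            "': no traditional parameter estimation performed",
            call. = FALSE)
  }
  global <- NULL
  if (method == "global") {
    st <- if (!is.null(general) && !is.na(general$Ki)) {
      list(Ks = general$Ks, Vmax = general$Vmax, Ki = general$Ki,
           gamma = general$gamma,
           beta = if (is.na(general$beta)) 0.5 else general$beta)
    } else NULL
    global <- global_fit(data, start = st)
  }
  structure(
    list(call = match.call(), data = data, lines = lines, profile = profile,
         mechanism = mech, traditional = traditional, general = general,
         global = global, method = method),
    class = "inhibfit"
  )
}

# parameter object used for prediction: global fit if present, else the
# inferred general parameters, else the traditional estimate
.predict_params <- function(object) {
  if (!is.null(object$global)) return(object$global$params)
  g <- object$general
  if (!is.null(g) && !anyNA(c(g$Ks, g$Vmax, g$Ki, g$gamma, g$beta))) {
    return(g)
  }
  if (!is.null(object$traditional)) return(object$traditional)
  stop("no estimated parameters available for prediction", call. = FALSE)
}

#' @export
print.inhibfit <- function(x, digits = 4, ...) {
  cat("Two-site enzyme inhibition analysis\n\n")
  print(x$mechanism)
  if (!is.null(x$traditional)) {
    cat("\n")
    print(x$traditional, digits = digits)
  }
  if (!is.null(x$general)) {
    cat("\n")
    print(x$general, digits = digits)
  }
  if (!is.null(x$global)) {
    cat("\n")
    print(x$global, digits = digits)
  }
  invisible(x)
}

#' Summarise an inhibition fit
#'
#' @param object An [inhibfit()] result.
#' @param ... Unused.
#' @return The object, invisibly, after printing the primary lines,
#'   secondary forms, mechanism call and parameter estimates.
#' @export
summary.inhibfit <- function(object, ...) {
  print(object$lines)
  cat("\n")
  print(object$profile)
  cat("\n")
  print(object)
}

#' @export
coef.inhibfit <- function(object, ...) {
  p <- .predict_params(object)
  stats::coef(p)
}

#' Predicted initial rates from a fitted inhibition model
#'
#' @param object An [inhibfit()] result.
#' @param newdata Data frame with substrate and inhibitor columns (`S_mM`
#'   and `I_mM`, or `S` and `I`); defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.inhibfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  S <- if ("S_mM" %in% names(newdata)) newdata$S_mM else newdata$S
  I <- if ("I_mM" %in% names(newdata)) newdata$I_mM else newdata$I
  if (is.null(S) || is.null(I)) {
    stop("newdata must provide substrate (S_mM or S) and inhibitor ",
         "(I_mM or I) columns", call. = FALSE)
  }
  rate_law(.predict_params(object), S, I)
}

#' @export
fitted.inhibfit <- function(object, ...) predict(object)

#' @export
residuals.inhibfit <- function(object, ...) {
  object$data$v0 - fitted(object)
}

#' Simulate datasets from a fitted inhibition model
#'
#' @param object An [inhibfit()] result.
#' @param nsim Number of datasets.
#' @param seed Seed for the noise draws (required when `noise_cv > 0`).
#' @param design An [assay_design()]; defaults to the grid of the fitted
#'   data with the requested noise.
#' @param noise_cv Rate noise CV used when `design` is not supplied.
#' @param ... Unused.
#' @return A `rate_data` data frame for `nsim = 1`, otherwise a list of
#'   them (seeds advanced per dataset).
#' @export
simulate.inhibfit <- function(object, nsim = 1, seed = NULL,
                              design = NULL, noise_cv = 0.05, ...) {
  params <- .predict_params(object)
  if (is.null(design)) {
    design <- assay_design(S = sort(unique(object$data$S_mM)),
                           I = sort(unique(object$data$I_mM)),
                           replicates = max(1, length(unique(
                             object$data$replicate))),
                           noise_cv = noise_cv, seed = seed)
  }
  sims <- lapply(seq_len(nsim), function(k) {
    d <- design
    if (!is.null(d$seed)) d$seed <- d$seed + k - 1L
    simulate_rates(params, d)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Diagnostic plots for an inhibition fit
#'
#' Four base-graphics panels: the double-reciprocal plot with the fitted
#' per-inhibitor lines, the apparent slope and apparent intercept against
#' inhibitor concentration with the selected secondary form, and (when
#' applicable) the reciprocal-difference replot of the slope increments.
#'
#' @param x An [inhibfit()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.inhibfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  d <- x$data
  mv <- stats::aggregate(v0 ~ S_mM + I_mM, data = d, FUN = mean)
  graphics::plot(1 / mv$S_mM, 1 / mv$v0, pch = 16,
                 col = as.integer(factor(mv$I_mM)),
                 xlab = "1/[S] (1/mM)", ylab = "1/v0",
                 main = "Double-reciprocal", ...)
  for (i in seq_len(nrow(x$lines))) {
    graphics::abline(x$lines$intercept[i], x$lines$slope[i],
                     col = i, lty = 2)
  }
  ln <- x$profile$lines
  .panel <- function(which, model) {
    graphics::plot(ln$I, ln[[which]], pch = 16, xlab = "[I] (mM)",
                   ylab = paste("apparent", which),
                   main = sprintf("%s(I): %s", which, model$form))
    Igrid <- seq(0, max(ln$I), length.out = 100)
    yy <- switch(model$form,
      constant = rep(model$pars[["a"]], length(Igrid)),
      linear = model$pars[["a"]] + model$pars[["b"]] * Igrid,
      hyperbolic = model$pars[["a"]] * (1 + model$pars[["p"]] * Igrid) /
        (1 + model$pars[["q"]] * Igrid))
    graphics::lines(Igrid, yy, col = 2)
  }
  .panel("slope", x$profile$slope_model)
  .panel("intercept", x$profile$intercept_model)
  rp <- tryCatch(delta_replot(x$lines, "slope"), error = function(e) NULL)
  if (!is.null(rp)) {
    nz <- ln$I > 0
    graphics::plot(1 / ln$I[nz], 1 / (ln$slope[nz] - rp$y0), pch = 16,
                   xlab = "1/[I] (1/mM)", ylab = "1/(delta slope)",
                   main = "Slope replot")
    graphics::abline(rp$intercept, rp$slope, col = 2)
  } else {
    graphics::plot.new()
  }
  invisible(x)
}
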