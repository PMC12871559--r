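#' Double-reciprocal coefficients of an inhibition rate law
#'
#' Slope and intercept of the Lineweaver-Burk line `1/v0 = slope/S +
#' intercept` at each inhibitor concentration, for either parameter
#' description.
#'
#' For the general two-site model,
#' `slope = (Ks/Vmax) (1 + I/(gamma Ki) + I/Ki) / (1 + beta I/Ki)` and
#' `intercept = (1/Vmax) (1 + I/Ki) / (1 + beta I/Ki)`. For the traditional
#' single-site laws the slope/intercept multipliers are the textbook factors
#' of each mechanism (see Details).
#'
#' @details Traditional slope and intercept factors (multiplying `Ks/Vmax`
#' and `1/Vmax` respectively), with `A = alpha * Ki`:
#' \itemize{
#'   \item linear competitive: `(1 + I/Ki)`, `1`
#'   \item linear non-competitive: `(1 + I/Ki)` on both
#'   \item linear mixed: `(1 + I/Ki)`, `(1 + I/A)`
#'   \item partial competitive: `(1 + I/Ki)/(1 + I/A)`, `1`
#'   \item partial mixed: `(1 + I/Ki)/(1 + beta I/A)`,
#'     `(1 + I/A)/(1 + beta I/A)`
#'   \item partial non-competitive: both `(1 + I/Ki)/(1 + beta I/Ki)`
#' }
#'
#' @param object A [general_params()] or [traditional_params()] object.
#' @param I Inhibitor concentration(s), mM, non-negative. Vectorised.
#' @param ... Unused.
#' @return A data frame with columns `I`, `slope`, `intercept`.
#' @examples
#' gp <- general_params(Ks = 1, Vmax = 1, Ki = 1, gamma = 1, beta = 0)
#' lb_coefficients(gp, I = c(0, 1))  # slope 1, 3; intercept 1, 2
#' @export
lb_coefficients <- function(object, I, ...) UseMethod("lb_coefficients")

.check_I <- function(I) {
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0)) {
    stop("inhibitor concentrations 'I' must be finite and >= 0",
         call. = FALSE)
  }
  as.numeric(I)
}

#' @rdname lb_coefficients
#' @export
lb_coefficients.general_params <- function(object, I, ...) {
  I <- .check_I(I)
  p <- object
  if (any(!is.finite(c(p$Ks, p$Vmax, p$Ki, p$gamma, p$beta)))) {
    stop("general parameters must all be finite for rate-law evaluation",
         call. = FALSE)
  }
  denom <- 1 + p$beta * I / p$Ki
  slope <- (p$Ks / p$Vmax) * (1 + I / (p$gamma * p$Ki) + I / p$Ki) / denom
  intercept <- (1 / p$Vmax) * (1 + I / p$Ki) / denom
  data.frame(I = I, slope = slope, intercept = intercept)
}

#' @rdname lb_coefficients
#' @export
lb_coefficients.traditional_params <- function(object, I, ...) {
  I <- .check_I(I)
  p <- object
  if (is.na(p$Ks) || is.na(p$Vmax)) {
    stop("traditional parameters need Ks and Vmax to evaluate the rate law",
         call. = FALSE)
  }
  A <- p$alpha * p$Ki
  f <- switch(p$mechanism,
    linear_competitive = list(s = 1 + I / p$Ki, i = rep(1, length(I))),
    linear_noncompetitive = list(s = 1 + I / p$Ki, i = 1 + I / p$Ki),
    linear_mixed = list(s = 1 + I / p$Ki, i = 1 + I / A),
    partial_competitive = list(s = (1 + I / p$Ki) / (1 + I / A),
                               i = rep(1, length(I))),
    partial_mixed = list(s = (1 + I / p$Ki) / (1 + p$beta * I / A),
                         i = (1 + I / A) / (1 + p$beta * I / A)),
    partial_noncompetitive = list(
      s = (1 + I / p$Ki) / (1 + p$beta * I / p$Ki),
      i = (1 + I / p$Ki) / (1 + p$beta * I / p$Ki)),
    stop("unsupported mechanism: ", p$mechanism, call. = FALSE)
  )
  data.frame(I = I, slope = (p$Ks / p$Vmax) * f$s,
             intercept = (1 / p$Vmax) * f$i)
}

#' Initial rate under an inhibition rate law
#'
#' Forward evaluation of the rate law: `v0 = 1 / (slope/S + intercept)`
#' with the slope/intercept of [lb_coefficients()]. Vectorised over `S`
#' and `I` (recycled to a common length).
#'
#' @param object A [general_params()] or [traditional_params()] object.
#' @param S Substrate concentration(s), mM, strictly positive.
#' @param I Inhibitor concentration(s), mM, non-negative.
#' @return Numeric vector of initial rates, strictly positive.
#' @examples
#' gp <- general_params(Ks = 1, Vmax = 1, Ki = 1, gamma = 1, beta = 0)
#' rate_law(gp, S = 1, I = c(0, 1))  # 0.5, 0.2
#' @export
rate_law <- function(object, S, I) {
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0)) {
    stop("substrate concentrations 'S' must be finite and > 0",
         call. = FALSE)
  }
  n <- max(length(S), length(I))
  S <- rep_len(as.numeric(S), n)
  I <- rep_len(.check_I(I), n)
  cf <- lb_coefficients(object, I)
  1 / (cf$slope / S + cf$intercept)
}

#' Limiting mechanism of a general two-site parameter set
#'
#' Assigns the intersecting mechanism class that the general rate law
#' reduces to in the regime of its `gamma` and `beta` values:
#' \itemize{
#'   \item `beta = 1`, `gamma << 1`: linear competitive (active-site binding
#'     dominant, outer site silent at `I < Ki`)
#'   \item `beta = 1`, `gamma` finite: partial competitive (constant
#'     intercept, hyperbolic slope saturating at `1 + 1/gamma` times the
#'     uninhibited slope)
#'   \item `beta = 0`, `gamma` finite: linear mixed (lines crossing in the
#'     second quadrant, linear secondary plots)
#'   \item `beta = 0`, `gamma >> 1`: linear non-competitive (shared factor,
#'     crossing on the 1/S axis)
#'   \item `0 < beta < 1`, `gamma >> 1`: partial non-competitive (both
#'     plateaus at `1/beta`)
#'   \item `0 < beta < 1`, `gamma` finite: partial mixed
#' }
#'
#' The regime cut-offs are configurable; the underlying theory states them
#' only qualitatively. `beta` within `beta_tol` of 1 (or 0) is treated as
#' exactly 1 (or 0).
#'
#' @param object A [general_params()] object.
#' @param gamma_small Threshold below which `gamma` counts as `<< 1`.
#' @param gamma_large Threshold above which `gamma` counts as `>> 1`.
#' @param beta_tol Half-width for snapping `beta` to its 0/1 endpoints.
#' @return A mechanism label from [mechanism_classes].
#' @examples
#' limiting_mechanism(general_params(1, 1, 45, gamma = 0.5, beta = 1))
#' @export
limiting_mechanism <- function(object, gamma_small = 0.01,
                               gamma_large = 100, beta_tol = 0.05) {
  stopifnot(inherits(object, "general_params"))
  b <- object$beta
  g <- object$gamma
  beta_class <- if (b >= 1 - beta_tol) "one"
                else if (b <= beta_tol) "zero"
                else "partial"
  switch(beta_class,
    one = if (g <= gamma_small) "linear_competitive" else "partial_competitive",
    zero = if (g >= gamma_large) "linear_noncompetitive" else "linear_mixed",
    partial = if (g >= gamma_large) "partial_noncompetitive"
              else "partial_mixed"
  )
}

#' Map traditional parameters onto the general two-site model
#'
#' For mechanisms carrying an alpha factor, equating the slope and intercept
#' factors of the general rate law with the traditional law for all
#' inhibitor concentrations gives the exact reparameterization
#' `Ki_general = alpha * Ki_traditional`, `gamma = 1/(alpha - 1)` and hence
#' an active-site dissociation constant
#' `gamma * Ki_general = alpha * Ki_traditional / (alpha - 1)`; `beta`
#' carries over (1 for partial competitive, 0 for linear mixed). The
#' resulting general parameters reproduce the traditional double-reciprocal
#' coefficients identically at every inhibitor concentration.
#'
#' Linear competitive data determine only the active-site constant: the
#' outer-site `Ki` is unidentifiable (the `gamma << 1` regime), so the
#' mapping returns `gamma * Ki = Ki_traditional` with `Ki` and `gamma`
#' set `NA` and an explanatory note. Non-competitive mechanisms correspond
#' to the `gamma >> 1` limit and have no exact finite-`gamma` counterpart;
#' they are refused.
#'
#' @param object A [traditional_params()] object.
#' @param ... Unused.
#' @return A [general_params()] object (possibly with `NA` for
#'   unidentifiable fields and a `note`).
#' @examples
#' as_general_params(traditional_params(Ki = 15, alpha = 3,
#'                   mechanism = "partial_competitive"))
#' @export
as_general_params <- function(object, ...) UseMethod("as_general_params")

#' @rdname as_general_params
#' @export
as_general_params.traditional_params <- function(object, ...) {
  p <- object
  if (p$mechanism %in% .alpha_mechanisms) {
    gamma <- gamma_from_alpha(p$alpha)
    Ki <- p$alpha * p$Ki
    beta <- switch(p$mechanism,
                   partial_competitive = 1,
                   linear_mixed = 0,
                   partial_mixed = p$beta)
    new_general_params(Ks = p$Ks, Vmax = p$Vmax, Ki = Ki, gamma = gamma,
                       beta = beta)
  } else if (p$mechanism == "linear_competitive") {
    new_general_params(Ks = p$Ks, Vmax = p$Vmax, Ki = NA_real_,
                       gamma = NA_real_, beta = 1, gamma_Ki = p$Ki,
                       note = paste("gamma << 1 regime: only the active-site",
                                    "constant gamma*Ki is identifiable;",
                                    "outer-site Ki unbounded above"))
  } else {
    stop("mechanism '", p$mechanism, "' lacks an alpha factor and is not ",
         "competitive: no exact finite-gamma general parameterization",
         call. = FALSE)
  }
}

#' Map general two-site parameters onto the traditional description
#'
#' Inverse of [as_general_params()]: matches the double-reciprocal
#' coefficients of the general law to the traditional law of its limiting
#' mechanism. For finite-`gamma` regimes this gives
#' `Ki_traditional = gamma * Ki / (1 + gamma)` (the harmonic combination of
#' the two sites), `alpha = 1/gamma + 1` and `beta` carried over; the
#' mapping is exact for all inhibitor concentrations. Regimes classified as
#' competitive or non-competitive limits return the corresponding limit
#' parameters.
#'
#' @param object A [general_params()] object.
#' @param ... Passed to [limiting_mechanism()] (regime thresholds).
#' @return A [traditional_params()] object.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' as_traditional_params(gp)  # Ki = 15, alpha = 3, partial competitive
#' @export
as_traditional_params <- function(object, ...) UseMethod("as_traditional_params")

#' @rdname as_traditional_params
#' @export
as_traditional_params.general_params <- function(object, ...) {
  p <- object
  mech <- limiting_mechanism(p, ...)
  switch(mech,
    partial_competitive = ,
    linear_mixed = ,
    partial_mixed = traditional_params(
      Ki = p$gamma * p$Ki / (1 + p$gamma),
      alpha = alpha_from_gamma(p$gamma),
      beta = if (mech == "partial_mixed") p$beta else NA_real_,
      mechanism = mech, Ks = p$Ks, Vmax = p$Vmax),
    linear_competitive = traditional_params(
      Ki = p$gamma * p$Ki, mechanism = mech, Ks = p$Ks, Vmax = p$Vmax),
    linear_noncompetitive = traditional_params(
      Ki = p$Ki, mechanism = mech, Ks = p$Ks, Vmax = p$Vmax),
    partial_noncompetitive = traditional_params(
      Ki = p$Ki, beta = p$beta, mechanism = mech, Ks = p$Ks, Vmax = p$Vmax)
  )
}
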