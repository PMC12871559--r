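#' Mechanism classes of intersecting enzyme inhibition
#'
#' The six classical intersecting ("simple") inhibition mechanisms, plus an
#' out-of-family flag for uncompetitive (parallel-line) behaviour and an
#' `inconclusive` outcome for profiles whose slope/intercept forms conflict.
#'
#' @format A character vector of the eight recognised mechanism labels.
#' @export
mechanism_classes <- c(
  "linear_competitive",
  "linear_noncompetitive",
  "linear_mixed",
  "partial_competitive",
  "partial_noncompetitive",
  "partial_mixed",
  "uncompetitive_out_of_family",
  "inconclusive"
)

# mechanisms for which the traditional description carries an alpha factor
.alpha_mechanisms <- c("linear_mixed", "partial_competitive", "partial_mixed")

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' General two-site inhibition model parameters
#'
#' Parameters of the general inhibition model in which a single inhibitor can
#' occupy two sites on a one-active-site enzyme: one inside the active site
#' (dissociation constant `gamma * Ki`, blocking substrate binding) and one
#' beyond the active site (dissociation constant `Ki`, leaving substrate
#' binding unaffected). The ternary enzyme-substrate-inhibitor complex turns
#' over at a fraction `beta` of the uninhibited catalytic rate.
#'
#' The double-reciprocal (Lineweaver-Burk) form of the rate law is
#' \deqn{1/v_0 = (K_s/V_{max}) \frac{1 + I/(\gamma K_i) + I/K_i}
#'   {1 + \beta I/K_i} \frac{1}{S}
#'   + (1/V_{max}) \frac{1 + I/K_i}{1 + \beta I/K_i}.}
#'
#' `gamma < 1` means the inhibitor prefers the active site; `gamma = 1`
#' equal affinity; `gamma > 1` preference for the outer site. `beta = 1`
#' makes the ternary complex fully productive (innocuous), `beta = 0`
#' dead-end, and intermediate values partially productive. `Vmax` is
#' `k3 * [E]_total`; the turnover constant `k3` is not separately
#' identifiable from initial rates and is not stored.
#'
#' @param Ks Substrate dissociation constant of the ES complex, mM.
#' @param Vmax Maximal rate, arbitrary rate units.
#' @param Ki Dissociation constant of the inhibitor at the site beyond the
#'   active site (EI and ESI complexes), mM.
#' @param gamma Relative-affinity factor; the active-site dissociation
#'   constant is `gamma * Ki`. Dimensionless, positive.
#' @param beta Reactivity factor of the ESI complex, in `[0, 1]`.
#' @return An object of class `"general_params"`: a list with the five
#'   parameters plus the derived active-site constant `gamma_Ki`.
#' @seealso [traditional_params()], [lb_coefficients()], [rate_law()],
#'   [limiting_mechanism()], [as_traditional_params()]
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' lb_coefficients(gp, I = c(0, 20, 40, 80, 120))
#' @export
general_params <- function(Ks, Vmax, Ki, gamma, beta) {
  .check_positive(Ks, "Ks")
  .check_positive(Vmax, "Vmax")
  .check_positive(Ki, "Ki")
  .check_positive(gamma, "gamma")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0 || beta > 1) {
    stop("'beta' must be a single number in [0, 1]", call. = FALSE)
  }
  new_general_params(Ks = Ks, Vmax = Vmax, Ki = Ki, gamma = gamma,
                     beta = beta)
}

# internal constructor; permits NA fields for partially identified results
new_general_params <- function(Ks = NA_real_, Vmax = NA_real_, Ki = NA_real_,
                               gamma = NA_real_, beta = NA_real_,
                               gamma_Ki = gamma * Ki, note = NULL) {
  structure(
    list(Ks = Ks, Vmax = Vmax, Ki = Ki, gamma = gamma, beta = beta,
         gamma_Ki = gamma_Ki, note = note),
    class = c("general_params", "inhib_params")
  )
}

#' Traditional single-site inhibition parameters
#'
#' Textbook description of an intersecting inhibition mechanism with a single
#' inhibitor binding site: an inhibition constant `Ki` (dissociation constant
#' of the EI complex), a mutual-hindrance factor `alpha` (the ESI complex
#' dissociates with constant `alpha * Ki`; only for mixed and partial
#' mechanisms), and a reactivity factor `beta` for hyperbolic (partial)
#' mechanisms.
#'
#' @param Ki Traditional inhibition constant, mM.
#' @param mechanism One of the first six values of [mechanism_classes].
#' @param alpha Mutual-hindrance factor, `> 1`; required for
#'   `linear_mixed`, `partial_competitive` and `partial_mixed`, and must be
#'   absent (`NA`) for competitive and non-competitive mechanisms.
#' @param beta ESI reactivity factor in `[0, 1]` for hyperbolic mechanisms;
#'   fixed implicitly at 1 for `partial_competitive` and 0 for linear
#'   mechanisms.
#' @param Ks,Vmax Optional Michaelis-Menten constants (mM, rate units) when
#'   known; `NA` otherwise.
#' @return An object of class `"traditional_params"`.
#' @seealso [general_params()], [as_general_params()], [rate_law()]
#' @examples
#' tp <- traditional_params(Ki = 15, alpha = 3, beta = 1,
#'                          mechanism = "partial_competitive")
#' as_general_params(tp)   # Ki = 45 mM, gamma*Ki = 22.5 mM
#' @export
traditional_params <- function(Ki, mechanism, alpha = NA_real_,
                               beta = NA_real_, Ks = NA_real_,
                               Vmax = NA_real_) {
  mechanism <- match.arg(mechanism, mechanism_classes[1:6])
  .check_positive(Ki, "Ki")
  needs_alpha <- mechanism %in% .alpha_mechanisms
  if (needs_alpha) {
    if (is.na(alpha)) {
      stop(sprintf("mechanism '%s' requires an alpha factor", mechanism),
           call. = FALSE)
    }
    if (!is.finite(alpha) || alpha <= 1) {
      stop("'alpha' must be finite and > 1", call. = FALSE)
    }
  } else if (!is.na(alpha)) {
    stop(sprintf("alpha does not apply to mechanism '%s'", mechanism),
         call. = FALSE)
  }
  beta <- switch(mechanism,
    partial_competitive = 1,
    linear_competitive = NA_real_,
    linear_mixed = 0,
    linear_noncompetitive = 0,
    {
      # partial_mixed / partial_noncompetitive need an explicit 0 < beta < 1
      if (is.na(beta) || beta <= 0 || beta >= 1) {
        stop(sprintf("mechanism '%s' requires beta strictly in (0, 1)",
                     mechanism), call. = FALSE)
      }
      beta
    }
  )
  structure(
    list(Ki = Ki, alpha = alpha, beta = beta, mechanism = mechanism,
         Ks = Ks, Vmax = Vmax),
    class = c("traditional_params", "inhib_params")
  )
}

#' @export
print.general_params <- function(x, digits = 4, ...) {
  cat("General two-site inhibition parameters\n")
  cat(sprintf("  Ks    = %s mM\n", format(x$Ks, digits = digits)))
  cat(sprintf("  Vmax  = %s rate units\n", format(x$Vmax, digits = digits)))
  cat(sprintf("  Ki    = %s mM  (outer site)\n", format(x$Ki, digits = digits)))
  cat(sprintf("  gamma = %s\n", format(x$gamma, digits = digits)))
  cat(sprintf("  gamma*Ki = %s mM  (active site)\n",
              format(x$gamma_Ki, digits = digits)))
  cat(sprintf("  beta  = %s\n", format(x$beta, digits = digits)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
print.traditional_params <- function(x, digits = 4, ...) {
  cat("Traditional single-site inhibition parameters\n")
  cat(sprintf("  mechanism = %s\n", x$mechanism))
  cat(sprintf("  Ki    = %s mM\n", format(x$Ki, digits = digits)))
  cat(sprintf("  alpha = %s\n",
              if (is.na(x$alpha)) "(not applicable)"
              else format(x$alpha, digits = digits)))
  cat(sprintf("  beta  = %s\n",
              if (is.na(x$beta)) "(not applicable)"
              else format(x$beta, digits = digits)))
  if (!is.na(x$Ks))
    cat(sprintf("  Ks = %s mM, Vmax = %s\n", format(x$Ks, digits = digits),
                format(x$Vmax, digits = digits)))
  invisible(x)
}

#' @export
coef.general_params <- function(object, ...) {
  c(Ks = object$Ks, Vmax = object$Vmax, Ki = object$Ki,
    gamma = object$gamma, beta = object$beta, gamma_Ki = object$gamma_Ki)
}

#' @export
coef.traditional_params <- function(object, ...) {
  c(Ki = object$Ki, alpha = object$alpha, beta = object$beta,
    Ks = object$Ks, Vmax = object$Vmax)
}

#' Convert between the hindrance factor alpha and the affinity ratio gamma
#'
#' The traditional mutual-hindrance factor of mixed/partial mechanisms is an
#' apparent quantity that the two-site model traces back to the relative
#' affinity of the inhibitor for its two sites:
#' \eqn{\alpha = 1/\gamma + 1}, equivalently \eqn{\gamma = 1/(\alpha - 1)}.
#' As the active site becomes dominant (`gamma` below 1) the apparent
#' hindrance grows; as `gamma` grows large, `alpha` tends to 1 and the
#' hindrance disappears. No finite `gamma` corresponds to `alpha <= 1`.
#'
#' @param gamma Relative-affinity factor, positive.
#' @param alpha Mutual-hindrance factor, `> 1`.
#' @return The converted factor.
#' @examples
#' alpha_from_gamma(0.5)  # 3
#' gamma_from_alpha(3)    # 0.5
#' @export
alpha_from_gamma <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("'gamma' must be positive and finite", call. = FALSE)
  }
  1 / gamma + 1
}

#' @rdname alpha_from_gamma
#' @export
gamma_from_alpha <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 1)) {
    stop("'alpha' must be finite and > 1 (no finite gamma otherwise)",
         call. = FALSE)
  }
  1 / (alpha - 1)
}
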