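#' Fit Lineweaver-Burk lines per inhibitor concentration
#'
#' For each inhibitor level, averages replicate rates per substrate
#' concentration and regresses `1/mean(v0)` on `1/S` by ordinary least
#' squares, mirroring the classical double-reciprocal analysis in which
#' plotted rates are replicate means. Lines with R^2 at or below `r2_min`
#' are flagged as rejected and excluded from downstream secondary analysis.
#'
#' @param data A `rate_data` data frame (see [simulate_rates()] or
#'   [read_rates()]) with columns `S_mM`, `I_mM`, `v0` and optionally
#'   `replicate`.
#' @param r2_min Acceptance threshold on the coefficient of determination;
#'   the conventional cut-off for this assay family is 0.9.
#' @return An object of class `"lb_lines"`: a data frame with one row per
#'   inhibitor level and columns `I`, `slope` (apparent `Ks/Vmax`),
#'   `intercept` (apparent `1/Vmax`), `r2`, `n_points`, `accepted`.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' fit_lb_lines(simulate_rates(gp, reference_design()))
#' @export
fit_lb_lines <- function(data, r2_min = 0.9) {
  data <- as.data.frame(data)
  req <- c("S_mM", "I_mM", "v0")
  if (!all(req %in% names(data))) {
    stop("data must contain columns S_mM, I_mM, v0", call. = FALSE)
  }
  if (any(!is.finite(data$v0)) || any(data$v0 <= 0)) {
    stop("all rates v0 must be positive and finite", call. = FALSE)
  }
  out <- lapply(split(data, data$I_mM), function(d) {
    mv <- tapply(d$v0, d$S_mM, mean)
    S <- as.numeric(names(mv))
    if (length(S) < 3) {
      stop("need >= 3 distinct substrate concentrations per inhibitor ",
           "level (got ", length(S), " at I = ", d$I_mM[1], " mM)",
           call. = FALSE)
    }
    fit <- stats::lm(y ~ x, data = data.frame(x = 1 / S, y = 1 / mv))
    cf <- stats::coef(fit)
    data.frame(I = d$I_mM[1], slope = unname(cf[2]),
               intercept = unname(cf[1]), r2 = .r_squared(fit),
               n_points = length(S))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$I), , drop = FALSE]
  rownames(res) <- NULL
  res$accepted <- res$r2 > r2_min
  structure(res, class = c("lb_lines", "data.frame"), r2_min = r2_min)
}

#' @export
print.lb_lines <- function(x, digits = 4, ...) {
  cat("Lineweaver-Burk primary fits (1/v0 on 1/S per inhibitor level)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (any(!x$accepted)) {
    cat(sprintf("note: %d line(s) rejected at R^2 <= %g\n",
                sum(!x$accepted), attr(x, "r2_min")))
  }
  invisible(x)
}

# coefficient of determination without summary.lm's perfect-fit warning
.r_squared <- function(fit) {
  y <- stats::model.frame(fit)[[1]]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  max(0, 1 - sum(stats::resid(fit)^2) / sst)
}

# fit y = a (1 + p I)/(1 + q I) with a, p, q >= 0.
# The relation is linear in (a, a*p, q) after clearing the denominator:
# y = a + a*p*I - q*(I*y); that exact linearization seeds an nls refinement
# (and stands in for it if nls cannot improve).
fit_rect_hyperbola <- function(I, y) {
  X <- cbind(1, I, -I * y)
  cf <- tryCatch(qr.solve(qr(X), y), error = function(e) NULL)
  start <- if (!is.null(cf) && cf[1] > 0 && cf[3] > -1e-12) {
    list(a = cf[1], p = max(cf[2] / cf[1], 1e-10), q = max(cf[3], 1e-10))
  } else {
    list(a = y[I == min(I)][1], p = 1 / stats::median(I[I > 0]),
         q = 0.5 / stats::median(I[I > 0]))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 + p * I) / (1 + q * I),
                      data = data.frame(I = I, y = y), start = start,
                      lower = c(a = 1e-12, p = 0, q = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pars <- unlist(start)
    fitted <- pars["a"] * (1 + pars["p"] * I) / (1 + pars["q"] * I)
    list(pars = pars, sse = sum((y - fitted)^2), n_par = 3)
  } else {
    list(pars = stats::coef(fit), sse = sum(stats::resid(fit)^2), n_par = 3)
  }
}

# pick constant / linear / hyperbolic for y(I) by nested comparison:
# a model whose SSE is already below `sse_floor` (relative to the total sum
# of squares) is accepted outright, simplest first, so that exact data are
# never over-fitted; otherwise an extra-sum-of-squares F-test cascade at
# level `f_alpha` decides.
select_secondary_form <- function(I, y, f_alpha = 0.05, sse_floor = 1e-12) {
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  scale2 <- max(sum(y^2), .Machine$double.eps)
  sse_c <- sst
  lin <- stats::lm(y ~ I)
  sse_l <- sum(stats::resid(lin)^2)
  hyp <- fit_rect_hyperbola(I, y)
  sse_h <- hyp$sse

  hyp_pars <- hyp$pars
  plateau <- if (hyp_pars["q"] > 0) hyp_pars["a"] * hyp_pars["p"] / hyp_pars["q"]
             else Inf
  models <- list(
    constant = list(form = "constant", pars = c(a = mean(y)), sse = sse_c,
                    n_par = 1),
    linear = list(form = "linear",
                  pars = c(a = unname(stats::coef(lin)[1]),
                           b = unname(stats::coef(lin)[2])),
                  sse = sse_l, n_par = 2),
    hyperbolic = list(form = "hyperbolic", pars = hyp_pars, sse = sse_h,
                      n_par = 3, plateau = unname(plateau))
  )

  adequate <- function(sse) sse / scale2 < sse_floor
  if (adequate(sse_c) || sst / scale2 < sse_floor) return(models$constant)
  if (adequate(sse_l)) return(models$linear)
  if (adequate(sse_h)) return(models$hyperbolic)

  ftest <- function(sse0, sse1, df_extra, df_res) {
    if (df_res <= 0 || sse1 <= 0) return(0)
    f <- ((sse0 - sse1) / df_extra) / (sse1 / df_res)
    stats::pf(f, df_extra, df_res, lower.tail = FALSE)
  }
  pick <- models$constant
  if (ftest(sse_c, sse_l, 1, n - 2) < f_alpha) pick <- models$linear
  if (pick$form == "linear" &&
      ftest(sse_l, sse_h, 1, n - 3) < f_alpha &&
      is.finite(plateau) && plateau > hyp_pars["a"]) {
    pick <- models$hyperbolic
  }
  pick
}

#' Secondary analysis of slope and intercept versus inhibitor concentration
#'
#' Fits the apparent-slope and apparent-intercept profiles against inhibitor
#' concentration with three nested forms -- constant, linear `a + b I`, and
#' the saturating hyperbola `a (1 + p I)/(1 + q I)` -- selecting by an
#' extra-sum-of-squares F-test guarded by a relative-SSE floor so that exact
#' (noise-free) profiles always take the simplest adequate form. The profile
#' also records where the primary lines cross (y-axis, 1/S-axis, second
#' quadrant, or parallel) and, for hyperbolic forms, the plateau estimate.
#'
#' @param lines An [fit_lb_lines()] result. Rejected lines are dropped.
#' @param f_alpha Significance level of the nested F-tests.
#' @param sse_floor Relative residual floor below which a form counts as
#'   exact.
#' @param ratio_cv_tol Coefficient-of-variation tolerance under which the
#'   slope/intercept ratio counts as constant across inhibitor levels (the
#'   non-competitive crossing diagnostic).
#' @return An object of class `"secondary_profile"` with elements `lines`,
#'   `slope_model`, `intercept_model`, `ratio_cv`, `crossing`.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' fit_secondary(fit_lb_lines(simulate_rates(gp, reference_design())))
#' @export
fit_secondary <- function(lines, f_alpha = 0.05, sse_floor = 1e-12,
                          ratio_cv_tol = 0.01) {
  stopifnot(inherits(lines, "lb_lines"))
  keep <- lines[lines$accepted, , drop = FALSE]
  if (length(unique(keep$I)) < 4) {
    stop("secondary analysis needs >= 4 accepted inhibitor levels",
         call. = FALSE)
  }
  if (!any(keep$I == 0)) {
    stop("secondary analysis needs the uninhibited (I = 0) line",
         call. = FALSE)
  }
  slope_model <- select_secondary_form(keep$I, keep$slope, f_alpha, sse_floor)
  intercept_model <- select_secondary_form(keep$I, keep$intercept, f_alpha,
                                           sse_floor)
  ratio <- keep$slope / keep$intercept
  ratio_cv <- stats::sd(ratio) / mean(ratio)
  slope_rises <- slope_model$form != "constant"
  intercept_rises <- intercept_model$form != "constant"
  crossing <- if (!slope_rises && intercept_rises) "parallel"
              else if (!intercept_rises) "y-axis"
              else if (ratio_cv <= ratio_cv_tol) "1/S-axis"
              else "second quadrant"
  structure(
    list(lines = keep, slope_model = slope_model,
         intercept_model = intercept_model, ratio_cv = ratio_cv,
         crossing = crossing, f_alpha = f_alpha,
         ratio_cv_tol = ratio_cv_tol,
         n_rejected = sum(!lines$accepted)),
    class = "secondary_profile"
  )
}

#' @export
print.secondary_profile <- function(x, digits = 4, ...) {
  cat("Secondary analysis of Lineweaver-Burk lines\n")
  cat(sprintf("  slope(I): %s; intercept(I): %s\n",
              x$slope_model$form, x$intercept_model$form))
  cat(sprintf("  slope/intercept ratio CV = %.3g; crossing: %s\n",
              x$ratio_cv, x$crossing))
  if (x$n_rejected > 0)
    cat(sprintf("  %d primary line(s) rejected\n", x$n_rejected))
  invisible(x)
}

#' Reciprocal-difference replot of slope or intercept increments
#'
#' The hyperbolic (partial) mechanisms make the apparent slope or intercept
#' saturate with inhibitor; the increment over the uninhibited line,
#' `delta(I) = y(I) - y(0)`, then obeys an exactly linear relation between
#' `1/delta` and `1/I`. This replot regression linearises the plateau: the
#' saturating increment is `1/replot_intercept`, so the limiting value of
#' the profile is `y(0) + 1/replot_intercept`. For linear mechanisms
#' `delta` grows without bound and the replot intercept tends to zero.
#'
#' @param lines An [fit_lb_lines()] result containing the I = 0 line and at
#'   least three non-zero inhibitor levels with strictly increasing profile.
#' @param which `"slope"` or `"intercept"`: which apparent coefficient to
#'   replot.
#' @return A list with the replot regression (`slope`, `intercept`, `r2`),
#'   the reference value `y0`, the saturating increment `delta_max`
#'   (`Inf` when the replot intercept is not positive) and the implied
#'   `limiting_value` `y0 + delta_max`.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' ln <- fit_lb_lines(simulate_rates(gp, reference_design()))
#' delta_replot(ln, "slope")
#' @export
delta_replot <- function(lines, which = c("slope", "intercept")) {
  which <- match.arg(which)
  stopifnot(inherits(lines, "lb_lines"))
  keep <- lines[lines$accepted, , drop = FALSE]
  if (!any(keep$I == 0)) {
    stop("delta replot needs the uninhibited (I = 0) reference line",
         call. = FALSE)
  }
  y <- keep[[which]]
  y0 <- y[keep$I == 0][1]
  nz <- keep$I > 0
  if (sum(nz) < 3) {
    stop("delta replot needs >= 3 non-zero inhibitor levels", call. = FALSE)
  }
  delta <- y[nz] - y0
  if (any(delta <= 0)) {
    stop("delta replot inapplicable: apparent ", which,
         " does not increase with inhibitor at every level", call. = FALSE)
  }
  fit <- stats::lm(yy ~ xx,
                   data = data.frame(xx = 1 / keep$I[nz], yy = 1 / delta))
  cf <- stats::coef(fit)
  r2 <- .r_squared(fit)
  int <- unname(cf[1])
  delta_max <- if (int > 0) 1 / int else Inf
  list(which = which, slope = unname(cf[2]), intercept = int, r2 = r2,
       y0 = y0, delta_max = delta_max, limiting_value = y0 + delta_max)
}
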