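#' Initial-rate assay design
#'
#' Defines the grid of substrate and inhibitor concentrations, the replicate
#' count and the noise model under which [simulate_rates()] generates data.
#'
#' @param S Substrate concentrations, mM, all positive; at least two
#'   distinct values are needed for line fitting downstream.
#' @param I Inhibitor concentrations, mM, non-negative. Must contain 0: the
#'   uninhibited reference line anchors the secondary delta replots.
#' @param replicates Replicate rate determinations per (S, I) pair.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   rate noise; 0 gives exact model rates.
#' @param seed Random seed; mandatory when `noise_cv > 0` so that noisy
#'   simulations are never silently irreproducible.
#' @return An object of class `"assay_design"`.
#' @seealso [reference_design()], [simulate_rates()]
#' @export
assay_design <- function(S, I, replicates = 3, noise_cv = 0, seed = NULL) {
  if (!is.numeric(S) || length(S) < 2 || any(!is.finite(S)) || any(S <= 0)) {
    stop("'S' must be >= 2 positive substrate concentrations", call. = FALSE)
  }
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0)) {
    stop("'I' must be non-negative inhibitor concentrations", call. = FALSE)
  }
  if (!any(I == 0)) {
    stop("'I' must include 0 (uninhibited reference)", call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (noise_cv > 0 && is.null(seed)) {
    stop("a 'seed' is required when noise_cv > 0", call. = FALSE)
  }
  structure(
    list(S = sort(unique(as.numeric(S))), I = sort(unique(as.numeric(I))),
         replicates = as.integer(replicates), noise_cv = noise_cv,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "assay_design"
  )
}

#' Reference inhibition assay design
#'
#' The design used throughout for benchmarking: 10 substrate concentrations
#' spanning 0.625-25 mM, five inhibitor concentrations 0-120 mM, and
#' triplicate rates. The substrate series is the two-fold ladder
#' 0.625, 1.25, 2.5, 5, 10, 25 completed to ten levels with the arithmetic
#' midpoints 1.875, 3.75, 7.5 and 17.5 of its upper intervals.
#'
#' @inheritParams assay_design
#' @return An `"assay_design"` with `S` of length 10 and
#'   `I = c(0, 20, 40, 80, 120)`.
#' @examples
#' reference_design()
#' @export
reference_design <- function(replicates = 3, noise_cv = 0, seed = NULL) {
  S <- sort(c(0.625, 1.25, 2.5, 5, 10, 25, 1.875, 3.75, 7.5, 17.5))
  assay_design(S = S, I = c(0, 20, 40, 80, 120), replicates = replicates,
               noise_cv = noise_cv, seed = seed)
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Initial-rate assay design\n")
  cat("  S (mM):", paste(format(x$S), collapse = ", "), "\n")
  cat("  I (mM):", paste(format(x$I), collapse = ", "), "\n")
  cat(sprintf("  replicates = %d, noise CV = %g%s\n", x$replicates,
              x$noise_cv,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate an initial-rate dataset
#'
#' Evaluates the rate law of `params` over the design grid and perturbs each
#' rate with multiplicative Gaussian noise: `v0 = v_true * (1 + e)`,
#' `e ~ N(0, noise_cv)`, redrawn while non-positive. Rates across the design
#' span roughly 40-fold, so a constant coefficient of variation is the
#' natural error structure for replicate chromogenic initial-rate assays.
#' The same parameters, design and seed always reproduce the identical
#' dataset.
#'
#' @param params A [general_params()] or [traditional_params()] object.
#' @param design An [assay_design()].
#' @return A data frame of class `"rate_data"` with columns `S_mM`, `I_mM`,
#'   `replicate`, `v0` (one row per replicate per grid point) and attributes
#'   recording the generating parameters and seed.
#' @examples
#' gp <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
#' d <- simulate_rates(gp, reference_design())
#' head(d)
#' @export
simulate_rates <- function(params, design = reference_design()) {
  stopifnot(inherits(params, "inhib_params"),
            inherits(design, "assay_design"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      S_mM = design$S, I_mM = design$I,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("S_mM", "I_mM", "replicate")]
  grid <- grid[order(grid$I_mM, grid$S_mM, grid$replicate), , drop = FALSE]
  rownames(grid) <- NULL
  v_true <- rate_law(params, grid$S_mM, grid$I_mM)
  if (design$noise_cv > 0) {
    grid$v0 <- with_seed(design$seed, {
      v <- v_true * (1 + stats::rnorm(length(v_true), 0, design$noise_cv))
      bad <- which(v <= 0)
      while (length(bad)) {
        v[bad] <- v_true[bad] *
          (1 + stats::rnorm(length(bad), 0, design$noise_cv))
        bad <- bad[v[bad] <= 0]
      }
      v
    })
  } else {
    grid$v0 <- v_true
  }
  structure(grid,
            class = c("rate_data", "data.frame"),
            params = params, design = design)
}
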