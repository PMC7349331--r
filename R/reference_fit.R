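#' Reference sizing: single-exponential least-squares fit
#'
#' The classical DLS estimate: find the diameter `d` minimizing
#' `sum_k (G(k) - exp(-2 D(d) q^2 tau_k))^2` over the retained lags,
#' with `D(d)` from the Einstein-Stokes relation. The optimizer is
#' deterministic: a coarse scan over `n_grid` log-spaced diameters in
#' `search_range` followed by golden-section/Brent refinement of
#' `log10(d)` around the best grid point, so the result does not depend
#' on a starting guess.
#'
#' @param curve A normalized `acr_curve` (see [normalized_acr()]).
#' @param setup An [optical_setup()].
#' @param search_range Diameter bounds `c(d_lo, d_hi)` in metres
#'   (default 10 nm to 20 um).
#' @param n_grid Number of coarse-scan points (default 200).
#' @return An object of class `dls_fit`: `diameter` (m), `diffusion`
#'   (m^2/s), `residual_sse`, `n_lags_used`, `converged` (FALSE when the
#'   minimizer ended at a search boundary).
#' @examples
#' setup <- optical_setup()
#' fit <- fit_single_exponential(expected_acr(setup, 1e-6), setup)
#' fit$diameter  # 1e-6 to numerical tolerance
#' @export
fit_single_exponential <- function(curve, setup,
                                   search_range = c(10e-9, 20e-6),
                                   n_grid = 200L) {
  stopifnot(inherits(curve, "acr_curve"))
  validate_optical_setup(setup)
  if (!curve$normalized) {
    stop("`curve` must be normalized before fitting (see normalize_acr())",
         call. = FALSE)
  }
  if (length(search_range) != 2L || any(search_range <= 0) ||
      search_range[1L] >= search_range[2L]) {
    stop("`search_range` must be c(d_lo, d_hi) with 0 < d_lo < d_hi",
         call. = FALSE)
  }
  q <- scattering_vector_modulus(setup)
  tau <- acr_lag_times(curve)
  g <- curve$values
  kt3pe <- K_BOLTZMANN * setup$temperature / (3 * pi * setup$viscosity)
  sse <- function(log10_d) {
    d <- 10^log10_d
    a1 <- 2 * (kt3pe / d) * q^2
    sum((g - exp(-a1 * tau))^2)
  }
  lb <- log10(search_range[1L])
  ub <- log10(search_range[2L])
  grid <- seq(lb, ub, length.out = n_grid)
  vals <- vapply(grid, sse, numeric(1))
  j <- which.min(vals)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(n_grid, j + 1L)]
  opt <- optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  best <- opt$minimum
  converged <- (best - lb > 1e-4) && (ub - best > 1e-4)
  d_hat <- 10^best
  structure(
    list(diameter = d_hat,
         diffusion = diffusion_coefficient(setup, d_hat),
         residual_sse = opt$objective,
         n_lags_used = length(g),
         converged = converged),
    class = "dls_fit"
  )
}

#' @export
print.dls_fit <- function(x, ...) {
  cat(sprintf("<dls_fit> d = %.4g nm, SSE = %.4g over %d lags%s\n",
              x$diameter * 1e9, x$residual_sse, x$n_lags_used,
              if (x$converged) "" else " (boundary hit, not converged)"))
  invisible(x)
}

#' Reference-fit a batch of ACR curves
#'
#' Applies [fit_single_exponential()] to each curve; a per-curve
#' failure is recorded as a flagged row (`diameter = NA`,
#' `converged = FALSE`, an `error` message) rather than aborting the
#' batch.
#'
#' @param curves A list of normalized `acr_curve` objects (or an
#'   `dls_corpus`, whose stored ACR rows are fitted).
#' @param setup An [optical_setup()].
#' @param ... Passed to [fit_single_exponential()].
#' @return A list of `dls_fit` objects, order preserved.
#' @export
batch_reference_fit <- function(curves, setup, ...) {
  if (inherits(curves, "dls_corpus")) {
    spacing <- 1 / curves$setup$sampling_frequency
    mat <- curves$acr
    curves <- lapply(seq_len(nrow(mat)), function(i) {
      acr_curve(mat[i, ], spacing, normalized = TRUE)
    })
  }
  lapply(curves, function(cv) {
    tryCatch(fit_single_exponential(cv, setup, ...),
             error = function(e) {
               structure(list(diameter = NA_real_, diffusion = NA_real_,
                              residual_sse = NA_real_,
                              n_lags_used = length(cv$values),
                              converged = FALSE,
                              error = conditionMessage(e)),
                         class = "dls_fit")
             })
  })
}
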