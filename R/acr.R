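#' Intensity autocorrelation of a DLS time-series
#'
#' Computes the raw (biased, mean-retaining) sample autocorrelation
#' `G(k) = (1/N) * sum_t I(t) I(t + k)` at lags `0 .. n_lags - 1` via
#' FFT with zero padding. The mean is deliberately not removed: the
#' baseline it induces is the constant `B` of the correlation model and
#' is subtracted later by [normalize_acr()].
#'
#' @param series A [dls_time_series()], longer than `n_lags`.
#' @param n_lags Number of lags to retain (default 350).
#' @return An object of class `acr_curve`: numeric `values` of length
#'   `n_lags`, `lag_spacing` in seconds (`1 / f_s`) and a `normalized`
#'   flag (here `FALSE`).
#' @examples
#' s <- generate_clean_series(optical_setup(),
#'                            synthesis_config(1e-6, n_points = 2048,
#'                                             seed = 1))
#' g <- autocorrelation(s, n_lags = 100)
#' @export
autocorrelation <- function(series, n_lags = 350L) {
  stopifnot(inherits(series, "dls_time_series"))
  n_lags <- as.integer(n_lags)
  x <- series$samples
  n <- length(x)
  if (n <= n_lags) {
    stop(sprintf("series length (%d) must exceed n_lags (%d)", n, n_lags),
         call. = FALSE)
  }
  nfft <- stats::nextn(n + n_lags, 2)
  p <- fft(c(x, numeric(nfft - n)))
  g_full <- Re(fft(Mod(p)^2, inverse = TRUE)) / nfft
  acr_curve(g_full[seq_len(n_lags)] / n, 1 / series$sampling_frequency,
            normalized = FALSE)
}

#' @rdname autocorrelation
#' @param values Numeric lag values (lag 0 first).
#' @param lag_spacing Lag spacing in seconds.
#' @param normalized Logical flag.
#' @export
acr_curve <- function(values, lag_spacing, normalized = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("ACR values must all be finite", call. = FALSE)
  }
  if (!is.numeric(lag_spacing) || lag_spacing <= 0) {
    stop("`lag_spacing` must be > 0 (seconds)", call. = FALSE)
  }
  structure(list(values = values, lag_spacing = lag_spacing,
                 normalized = isTRUE(normalized)),
            class = "acr_curve")
}

#' @export
print.acr_curve <- function(x, ...) {
  cat(sprintf("<acr_curve> %d lags, spacing %.3g s, %s\n",
              length(x$values), x$lag_spacing,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Lag times (seconds) of an ACR curve
#' @param curve An `acr_curve`.
#' @return Numeric vector `k * lag_spacing`, `k = 0 .. n - 1`.
#' @export
acr_lag_times <- function(curve) {
  (seq_along(curve$values) - 1) * curve$lag_spacing
}

#' Normalize an intensity autocorrelation
#'
#' Two-step normalization of the raw correlation
#' `G(tau) = A exp(-2 D q^2 tau) + B`: the baseline `B` is estimated as
#' the mean over the last `baseline_frac` of the supplied lags and
#' subtracted, then the curve is rescaled by an estimate of the lag-0
#' amplitude `A` so the result equals 1 at lag 0 and is directly
#' comparable to `exp(-2 D q^2 tau)`. The rescaling plays the role of
#' the experimental single-speckle adjustment that makes the spatial
#' coherence factor unity.
#'
#' Two amplitude estimators are available. `"extrapolate"` (default)
#' regresses `log(G - B)` on the lag index over the early part of the
#' decay (lags 1 up to where the curve has fallen to half its lag-1
#' value, capped at 100) and extrapolates to lag 0; the raw zero-lag
#' channel is then overwritten with 1. This is the usual correlator
#' practice: uncorrelated broadband noise decorrelates within one
#' sample interval and so piles up entirely in the zero-lag channel,
#' which would otherwise leak into the overall scale. `"anchor"` uses
#' the raw `G(0) - B` directly. Both are exact on a noiseless
#' exponential.
#'
#' The baseline window must sit beyond the correlation decay, so the
#' raw curve should be computed over more lags than are finally kept
#' (see `n_keep`); [normalized_acr()] wires this up.
#'
#' Already-normalized curves are returned unchanged (idempotence).
#'
#' @param curve A raw `acr_curve` with at least 50 lags.
#' @param baseline_frac Fraction of trailing lags averaged for the
#'   baseline estimate (default 0.1).
#' @param n_keep If non-`NULL`, truncate the normalized curve to its
#'   first `n_keep` lags.
#' @param amplitude `"extrapolate"` (default) or `"anchor"`, see
#'   Details.
#' @return A normalized `acr_curve`.
#' @export
normalize_acr <- function(curve, baseline_frac = 0.1, n_keep = NULL,
                          amplitude = c("extrapolate", "anchor")) {
  stopifnot(inherits(curve, "acr_curve"))
  amplitude <- match.arg(amplitude)
  v <- curve$values
  if (curve$normalized) {
    if (!is.null(n_keep)) v <- v[seq_len(min(n_keep, length(v)))]
    return(acr_curve(v, curve$lag_spacing, normalized = TRUE))
  }
  if (length(v) < 50L) {
    stop("need at least 50 raw lags to estimate the baseline", call. = FALSE)
  }
  n_tail <- max(1L, floor(baseline_frac * length(v)))
  b_hat <- mean(v[(length(v) - n_tail + 1L):length(v)])
  u <- v - b_hat
  if (u[1L] <= 0) {
    stop("degenerate normalization: ACR has no dynamic range above its baseline",
         call. = FALSE)
  }
  a_hat <- u[1L]
  if (amplitude == "extrapolate") {
    m <- which(u[-1L] < 0.5 * u[1L])[1L]
    if (is.na(m)) m <- 100L
    m <- max(3L, min(100L, m, length(u) - 1L))
    k <- seq_len(m)
    w <- u[k + 1L]
    ok <- w > 0
    if (sum(ok) >= 2L) {
      coefs <- stats::lm.fit(cbind(1, k[ok]), log(w[ok]))$coefficients
      a_ext <- exp(coefs[[1L]])
      # trust the extrapolation only when it stays commensurate with the
      # raw zero-lag value; otherwise the curve is not exponential-like
      # (e.g. white noise) and the anchor is the honest estimate
      if (is.finite(a_ext) && a_ext > u[1L] / 3 && a_ext < u[1L] * 3) {
        a_hat <- a_ext
      }
    }
  }
  out <- u / a_hat
  out[1L] <- 1
  if (!is.null(n_keep)) out <- out[seq_len(min(n_keep, length(out)))]
  acr_curve(out, curve$lag_spacing, normalized = TRUE)
}

#' Normalized n-lag ACR of a time-series
#'
#' Computes the raw autocorrelation over `internal_lags` lags (enough
#' that the trailing baseline window lies past the decay even for
#' micron-sized particles at 16 kHz), normalizes it, and keeps the
#' first `n_lags` lags -- the standard input to both the reference fit
#' and the neural network.
#'
#' @inheritParams autocorrelation
#' @param internal_lags Lags used for the raw curve and its baseline
#'   window (default `4 * n_lags`).
#' @param baseline_frac Passed to [normalize_acr()].
#' @return A normalized `acr_curve` of length `n_lags`.
#' @export
normalized_acr <- function(series, n_lags = 350L,
                           internal_lags = 4L * n_lags,
                           baseline_frac = 0.1) {
  raw <- autocorrelation(series, n_lags = internal_lags)
  normalize_acr(raw, baseline_frac = baseline_frac, n_keep = n_lags)
}

#' Expected normalized ACR of mono-dispersed particles
#'
#' The analytic single-exponential correlation
#' `exp(-2 D q^2 tau)` for a given diameter under a given setup.
#'
#' @param setup An [optical_setup()].
#' @param diameter Hydrodynamic diameter (m).
#' @param n_lags Number of lags.
#' @return A normalized `acr_curve`.
#' @export
expected_acr <- function(setup, diameter, n_lags = 350L) {
  a1 <- halfwidth_from_diameter(setup, diameter)
  tau <- (seq_len(n_lags) - 1) / setup$sampling_frequency
  acr_curve(exp(-a1 * tau), 1 / setup$sampling_frequency, normalized = TRUE)
}

#' Read / write an ACR curve as two-column CSV
#'
#' Columns `lag_seconds` and `value`; a `normalized` attribute is kept
#' in a comment-free third column-less header convention: curves read
#' back are flagged normalized when their first value equals 1 within
#' 1e-9 and the file was written from a normalized curve.
#'
#' @param curve An `acr_curve`.
#' @param path File path.
#' @return `read_acr_csv()` returns an `acr_curve`; `write_acr_csv()`
#'   returns `path` invisibly.
#' @export
write_acr_csv <- function(curve, path) {
  stopifnot(inherits(curve, "acr_curve"))
  df <- data.frame(lag_seconds = acr_lag_times(curve), value = curve$values,
                   normalized = curve$normalized)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_acr_csv
#' @export
read_acr_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("lag_seconds", "value") %in% names(df))) {
    stop("ACR CSV must have columns `lag_seconds` and `value`", call. = FALSE)
  }
  if (nrow(df) < 2L) stop("ACR CSV has fewer than 2 lags", call. = FALSE)
  spacing <- df$lag_seconds[2L] - df$lag_seconds[1L]
  normalized <- if ("normalized" %in% names(df)) isTRUE(df$normalized[1L]) else FALSE
  acr_curve(df$value, spacing, normalized = normalized)
}
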