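#' DLS intensity time-series
#'
#' A uniformly sampled sequence of scattered-light intensities
#' `I(0), I(dt), I(2 dt), ...` with `dt = 1 / sampling_frequency`.
#'
#' @param samples Numeric vector of intensity values (arbitrary units),
#'   all finite, length >= 2.
#' @param sampling_frequency Sampling rate (Hz), > 0.
#' @param origin One of `"simulated-clean"`, `"simulated-noisy"`,
#'   `"recorded"`.
#' @return An object of class `dls_time_series`.
#' @export
dls_time_series <- function(samples, sampling_frequency,
                            origin = c("recorded", "simulated-clean",
                                       "simulated-noisy")) {
  origin <- match.arg(origin)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a time-series needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("time-series samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_frequency) || length(sampling_frequency) != 1L ||
      !is.finite(sampling_frequency) || sampling_frequency <= 0) {
    stop("`sampling_frequency` must be a positive scalar (Hz)",
         call. = FALSE)
  }
  structure(
    list(samples = samples,
         sampling_frequency = as.numeric(sampling_frequency),
         origin = origin),
    class = "dls_time_series"
  )
}

#' @export
print.dls_time_series <- function(x, ...) {
  cat(sprintf("<dls_time_series> %d samples @ %g Hz (%.4g s), origin: %s\n",
              length(x$samples), x$sampling_frequency,
              length(x$samples) / x$sampling_frequency, x$origin))
  invisible(x)
}

#' @export
length.dls_time_series <- function(x) length(x$samples)

## Evaluate seeded code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  code
}
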