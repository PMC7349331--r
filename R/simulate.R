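#' Synthesis configuration for simulated DLS time-series
#'
#' A simulated series is a sum of `n_freqs` harmonics whose amplitudes
#' are the square roots of the Lorentzian spectral density at the grid
#' frequencies `f_i = i * f_s / n_points`, `i = 0 .. n_freqs - 1`, with
#' independent uniform random phases in (0, 2 pi). With
#' `n_freqs = n_points / 2 + 1` (the default) the grid coincides with
#' the real-FFT bins of the series, so the sum can be evaluated exactly
#' by an inverse FFT.
#'
#' @param diameter Particle hydrodynamic diameter (m), > 0.
#' @param n_points Number of samples per series (default 32768).
#' @param n_freqs Number of harmonic components (default
#'   `n_points / 2 + 1`, i.e. 16385 for the default length).
#' @param a0 Lorentzian amplitude scale (default 50; the normalized
#'   autocorrelation is insensitive to it).
#' @param dc_offset Constant added to the synthesised series (default 0;
#'   recorded intensities are nonnegative, but the offset cancels in
#'   ACR normalization).
#' @param seed Optional integer seed for the random phases.
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(diameter, n_points = 32768L, n_freqs = NULL,
                             a0 = 50, dc_offset = 0, seed = NULL) {
  n_points <- as.integer(n_points)
  if (is.null(n_freqs)) n_freqs <- n_points %/% 2L + 1L
  n_freqs <- as.integer(n_freqs)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  if (n_freqs < 2L) stop("`n_freqs` must be >= 2", call. = FALSE)
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      !is.finite(diameter) || diameter <= 0) {
    stop("`diameter` must be a positive length in metres", call. = FALSE)
  }
  if (!is.numeric(a0) || a0 <= 0) stop("`a0` must be > 0", call. = FALSE)
  structure(
    list(diameter = diameter, n_points = n_points, n_freqs = n_freqs,
         a0 = a0, dc_offset = dc_offset, seed = seed),
    class = "synthesis_config"
  )
}

#' Simulate a clean (noise-free) DLS time-series
#'
#' Evaluates `x(t_k) = sum_i sqrt(S(f_i)) * sin(2 pi f_i t_k + phi_i)`
#' where `S` is the Lorentzian spectrum whose half-width corresponds to
#' the configured diameter (see [lorentzian_spectrum()]), `t_k = k / f_s`
#' and the phases are uniform in (0, 2 pi).
#'
#' Two evaluation paths are provided. `method = "fft"` builds the
#' one-sided complex spectrum `sqrt(S(f_i)) * exp(1i * phi_i)` and takes
#' the imaginary part of its inverse DFT; it requires
#' `n_freqs = n_points / 2 + 1`. `method = "direct"` evaluates the
#' double sum literally in `O(n_points * n_freqs)` time and works for
#' any `n_freqs`; it is the reference implementation the FFT path is
#' validated against.
#'
#' @param setup An [optical_setup()].
#' @param cfg A [synthesis_config()].
#' @param method `"fft"` (fast, default) or `"direct"` (reference).
#' @return A [dls_time_series()] with origin `"simulated-clean"`.
#' @examples
#' s <- generate_clean_series(optical_setup(),
#'                            synthesis_config(500e-9, n_points = 1024,
#'                                             seed = 1))
#' @export
generate_clean_series <- function(setup, cfg, method = c("fft", "direct")) {
  method <- match.arg(method)
  validate_optical_setup(setup)
  stopifnot(inherits(cfg, "synthesis_config"))
  fs <- setup$sampling_frequency
  n <- cfg$n_points
  if (method == "fft" && cfg$n_freqs != n %/% 2L + 1L) {
    stop(sprintf(
      "spectral synthesis requires n_freqs = n_points/2 + 1 (= %d), got %d; use method = \"direct\"",
      n %/% 2L + 1L, cfg$n_freqs), call. = FALSE)
  }
  a1 <- halfwidth_from_diameter(setup, cfg$diameter)
  freqs <- (seq_len(cfg$n_freqs) - 1) * fs / n
  amps <- sqrt(lorentzian_spectrum(cfg$a0, a1, freqs))
  phases <- with_seed(cfg$seed, runif(cfg$n_freqs, 0, 2 * pi))

  if (method == "fft") {
    spec <- complex(length.out = n)
    spec[seq_len(cfg$n_freqs)] <- amps * exp(1i * phases)
    x <- Im(fft(spec, inverse = TRUE))
  } else {
    x <- .harmonic_sum_exact(n, 1 / fs, freqs, amps, phases)
  }
  dls_time_series(x + cfg$dc_offset, fs, origin = "simulated-clean")
}

#' Noise model configuration
#'
#' Two additive noise terms emulate what a bench DLS acquisition picks
#' up. Power-grid noise is a sum of harmonics of the mains frequency
#' (50 Hz), `i = 1 .. i_max` with `i_max = round(f_s / 50)`, whose
#' amplitudes decay exponentially with the harmonic number:
#' `0.03 * A_ts * exp(-0.25 * i)`, where `A_ts` is the peak-to-peak
#' amplitude of the series the noise is added to. Broadband noise is a
#' sum of `n_rnd` sinusoids at frequencies uniform in `[1, f_s]` with
#' amplitudes `0.01 * A_ts * exp(-0.005 * i)`. All phases are uniform
#' in (0, 2 pi). Note `i_max` is defined relative to `f_s`, not
#' `f_s / 2`, so the upper grid harmonics alias; they are injected as
#' written.
#'
#' @param grid_base_frequency Mains frequency (Hz), default 50.
#' @param grid_amp_coeff Grid-harmonic amplitude coefficient, default 0.03.
#' @param grid_decay Per-harmonic exponential decay rate, default 0.25.
#' @param rnd_amp_coeff Broadband amplitude coefficient, default 0.01.
#' @param rnd_decay Per-component decay rate, default 0.005.
#' @param n_rnd Number of broadband components, default 300.
#' @param seed Optional integer seed.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(grid_base_frequency = 50, grid_amp_coeff = 0.03,
                         grid_decay = 0.25, rnd_amp_coeff = 0.01,
                         rnd_decay = 0.005, n_rnd = 300L, seed = NULL) {
  vals <- c(grid_base_frequency = grid_base_frequency,
            grid_amp_coeff = grid_amp_coeff, grid_decay = grid_decay,
            rnd_amp_coeff = rnd_amp_coeff, rnd_decay = rnd_decay)
  if (any(!is.finite(vals)) || any(vals < 0) || grid_base_frequency <= 0) {
    stop("noise coefficients must be finite and nonnegative (base frequency > 0)",
         call. = FALSE)
  }
  n_rnd <- as.integer(n_rnd)
  if (n_rnd < 0L) stop("`n_rnd` must be >= 0", call. = FALSE)
  structure(
    list(grid_base_frequency = grid_base_frequency,
         grid_amp_coeff = grid_amp_coeff, grid_decay = grid_decay,
         rnd_amp_coeff = rnd_amp_coeff, rnd_decay = rnd_decay,
         n_rnd = n_rnd, seed = seed),
    class = "noise_config"
  )
}

series_amplitude <- function(series) {
  a <- max(series$samples) - min(series$samples)
  if (a <= 0) {
    stop("degenerate input: constant series has zero peak-to-peak amplitude",
         call. = FALSE)
  }
  a
}

#' Add power-grid harmonic noise to a time-series
#'
#' @param series A [dls_time_series()]; must be nonconstant.
#' @param cfg A [noise_config()].
#' @return A new `dls_time_series` with origin `"simulated-noisy"` (the
#'   input's samples plus the grid-noise series).
#' @export
add_power_grid_noise <- function(series, cfg = noise_config()) {
  stopifnot(inherits(series, "dls_time_series"), inherits(cfg, "noise_config"))
  a_ts <- series_amplitude(series)
  if (cfg$grid_amp_coeff == 0) {
    return(dls_time_series(series$samples, series$sampling_frequency,
                           origin = "simulated-noisy"))
  }
  fs <- series$sampling_frequency
  i_max <- round(fs / cfg$grid_base_frequency)
  i <- seq_len(i_max)
  freqs <- cfg$grid_base_frequency * i
  amps <- cfg$grid_amp_coeff * a_ts * exp(-cfg$grid_decay * i)
  phases <- with_seed(cfg$seed, runif(i_max, 0, 2 * pi))
  noise <- .harmonic_sum_fast(length(series$samples), 1 / fs, freqs, amps,
                              phases)
  dls_time_series(series$samples + noise, fs, origin = "simulated-noisy")
}

#' Add broadband random noise to a time-series
#'
#' @inheritParams add_power_grid_noise
#' @return A new `dls_time_series` with origin `"simulated-noisy"`.
#' @export
add_random_noise <- function(series, cfg = noise_config()) {
  stopifnot(inherits(series, "dls_time_series"), inherits(cfg, "noise_config"))
  a_ts <- series_amplitude(series)
  if (cfg$n_rnd == 0L || cfg$rnd_amp_coeff == 0) {
    return(dls_time_series(series$samples, series$sampling_frequency,
                           origin = "simulated-noisy"))
  }
  fs <- series$sampling_frequency
  i <- seq_len(cfg$n_rnd)
  amps <- cfg$rnd_amp_coeff * a_ts * exp(-cfg$rnd_decay * i)
  draws <- with_seed(cfg$seed, {
    f <- runif(cfg$n_rnd, 1, fs)
    ph <- runif(cfg$n_rnd, 0, 2 * pi)
    list(f = f, ph = ph)
  })
  noise <- .harmonic_sum_fast(length(series$samples), 1 / fs, draws$f, amps,
                              draws$ph)
  dls_time_series(series$samples + noise, fs, origin = "simulated-noisy")
}

#' Simulate one noisy DLS series for a given diameter
#'
#' Convenience wrapper: clean spectral synthesis, then grid noise, then
#' broadband noise. The peak-to-peak amplitude driving each noise term
#' is taken from the series as it stands immediately before that term
#' is added.
#'
#' @inheritParams generate_clean_series
#' @param noise A [noise_config()].
#' @return A `dls_time_series` with origin `"simulated-noisy"`.
#' @export
generate_noisy_series <- function(setup, cfg, noise = noise_config()) {
  clean <- generate_clean_series(setup, cfg)
  base_seed <- cfg$seed
  grid_cfg <- noise
  rnd_cfg <- noise
  if (!is.null(base_seed)) {
    grid_cfg$seed <- noise$seed %||% (3 * base_seed + 1)
    rnd_cfg$seed <- if (is.null(noise$seed)) 3 * base_seed + 2 else noise$seed + 1
  }
  noisy <- add_power_grid_noise(clean, grid_cfg)
  add_random_noise(noisy, rnd_cfg)
}
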