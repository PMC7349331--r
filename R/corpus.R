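#' Generate a training corpus of simulated DLS autocorrelations
#'
#' Builds one noisy simulated series per diameter on the grid
#' `seq(d_min, d_max, by = step)`, computes the normalized `n_lags`-lag
#' ACR of each, and sizes each with the reference single-exponential
#' fit. The resulting matrix of ACRs, the ground-truth diameters and
#' the reference-fit diameters (the training targets) form the corpus
#' the network is trained on.
#'
#' The full-scale corpus spans 25-6000 nm in 0.5 nm steps (11,951
#' series); a 5 nm step (1,196 series) preserves the error structure at
#' a fraction of the cost and is the scale used by this package's own
#' validation runs.
#'
#' Reproducibility: series `i` uses phase/frequency seeds derived from
#' `master_seed + i` by a fixed counter scheme, so any row can be
#' regenerated independently.
#'
#' @param setup An [optical_setup()].
#' @param d_min,d_max Diameter grid bounds (m). Defaults 25 nm, 6000 nm.
#' @param step Grid step (m). Default 0.5 nm.
#' @param n_points Samples per series (default 32768).
#' @param a0 Lorentzian amplitude scale (default 50).
#' @param noise A [noise_config()] template (its `seed` is ignored;
#'   per-series seeds are derived from `master_seed`).
#' @param master_seed Integer master seed.
#' @param n_lags ACR lags kept per series (default 350).
#' @param internal_lags Raw lags for baseline estimation (default
#'   `4 * n_lags`).
#' @param search_range Reference-fit diameter bounds (m).
#' @param progress Print a dot every 100 series.
#' @return An object of class `dls_corpus`: `acr` (n x n_lags matrix of
#'   normalized ACRs), `diameters_true`, `diameters_reference`,
#'   `ref_converged`, `setup`, `seeds`, and the generation parameters.
#' @export
generate_training_corpus <- function(setup,
                                     d_min = 25e-9, d_max = 6000e-9,
                                     step = 0.5e-9,
                                     n_points = 32768L, a0 = 50,
                                     noise = noise_config(),
                                     master_seed = 1L,
                                     n_lags = 350L,
                                     internal_lags = 4L * n_lags,
                                     search_range = c(10e-9, 20e-6),
                                     progress = FALSE) {
  validate_optical_setup(setup)
  if (!(d_min < d_max) || step <= 0) {
    stop("need d_min < d_max and step > 0", call. = FALSE)
  }
  diameters <- seq(d_min, d_max, by = step)
  n <- length(diameters)
  if (n < 10L) {
    stop(sprintf(
      "diameter grid yields only %d series; at least 10 are required for a 70/15/15 split",
      n), call. = FALSE)
  }
  master_seed <- as.integer(master_seed) %% .Machine$integer.max
  seeds <- master_seed + seq_len(n)
  acr <- matrix(NA_real_, nrow = n, ncol = n_lags)
  d_ref <- numeric(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    cfg <- synthesis_config(diameters[i], n_points = n_points, a0 = a0,
                            seed = seeds[i])
    series <- generate_noisy_series(setup, cfg, noise)
    curve <- normalized_acr(series, n_lags = n_lags,
                            internal_lags = internal_lags)
    fit <- fit_single_exponential(curve, setup, search_range = search_range)
    acr[i, ] <- curve$values
    d_ref[i] <- fit$diameter
    conv[i] <- fit$converged
    if (progress && i %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(
    list(acr = acr,
         diameters_true = diameters,
         diameters_reference = d_ref,
         ref_converged = conv,
         setup = setup,
         seeds = seeds,
         n_lags = as.integer(n_lags),
         internal_lags = as.integer(internal_lags),
         n_points = as.integer(n_points),
         a0 = a0,
         noise = noise,
         master_seed = master_seed),
    class = "dls_corpus"
  )
}

#' @export
print.dls_corpus <- function(x, ...) {
  cat(sprintf(
    "<dls_corpus> %d series, %d ACR lags, diameters %.4g-%.4g nm (master seed %d)\n",
    nrow(x$acr), ncol(x$acr), min(x$diameters_true) * 1e9,
    max(x$diameters_true) * 1e9, x$master_seed))
  invisible(x)
}

#' Persist a corpus
#'
#' `write_corpus()` stores the full corpus (matrix plus metadata) as a
#' single JSON container; `write_corpus_csv()` writes a flat CSV with
#' one row per series: true diameter (nm), reference diameter (nm) and
#' the 350 normalized ACR lags.
#'
#' @param corpus A `dls_corpus`.
#' @param path Output path.
#' @return The path, invisibly; `read_corpus()` returns a `dls_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "dls_corpus"))
  payload <- list(
    format = "dlsann-corpus", version = 1L,
    setup = unclass(corpus$setup),
    noise = unclass(corpus$noise),
    n_lags = corpus$n_lags, internal_lags = corpus$internal_lags,
    n_points = corpus$n_points, a0 = corpus$a0,
    master_seed = corpus$master_seed, seeds = corpus$seeds,
    diameters_true = corpus$diameters_true,
    diameters_reference = corpus$diameters_reference,
    ref_converged = corpus$ref_converged,
    acr = corpus$acr
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dlsann-corpus")) {
    stop("not a dlsann corpus container: ", path, call. = FALSE)
  }
  noise <- p$noise
  noise$seed <- noise$seed %||% NULL
  structure(
    list(acr = as.matrix(p$acr),
         diameters_true = p$diameters_true,
         diameters_reference = p$diameters_reference,
         ref_converged = p$ref_converged,
         setup = do.call(optical_setup, p$setup),
         seeds = p$seeds,
         n_lags = as.integer(p$n_lags),
         internal_lags = as.integer(p$internal_lags),
         n_points = as.integer(p$n_points),
         a0 = p$a0,
         noise = do.call(noise_config, noise),
         master_seed = as.integer(p$master_seed)),
    class = "dls_corpus"
  )
}

#' @rdname write_corpus
#' @export
write_corpus_csv <- function(corpus, path) {
  stopifnot(inherits(corpus, "dls_corpus"))
  df <- data.frame(diameter_true_nm = corpus$diameters_true * 1e9,
                   diameter_ref_nm = corpus$diameters_reference * 1e9)
  acr <- as.data.frame(corpus$acr)
  names(acr) <- paste0("lag", seq_len(ncol(acr)) - 1L)
  write.csv(cbind(df, acr), path, row.names = FALSE)
  invisible(path)
}
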