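#' Process a long-duration monitoring run
#'
#' Sizes every recorded series in a directory: each file is read,
#' reduced to its normalized 350-lag ACR, and sized with the trained
#' network (and optionally with the reference fit). One record is
#' produced per file; per-file failures are QC-flagged rather than
#' aborting the run. This mirrors a fermentation-monitoring experiment
#' in which an 8 s series is recorded every 30 minutes for days.
#'
#' Elapsed time is `index * interval_minutes / 60` hours (first record
#' at 0) over files sorted by name, unless `manifest` supplies
#' per-file timestamps.
#'
#' QC flags: `short-series` (too few samples for the ACR),
#' `degenerate-acr` (normalization failed), `boundary-fit` (reference
#' fit ended at a search bound), `read-error`.
#'
#' @param directory Directory containing series files.
#' @param model A trained `dls_ann`.
#' @param setup An [optical_setup()]; supplies the sampling frequency
#'   for text/CSV files and the optics for the reference fit.
#' @param interval_minutes Recording cadence (default 30).
#' @param with_reference Also run the reference fit per record.
#' @param manifest Optional data.frame (or CSV path) with columns
#'   `file` and `elapsed_hours`, overriding the uniform cadence; files
#'   are processed in manifest order.
#' @param pattern Regular expression selecting files (default: text,
#'   csv or wav extensions).
#' @param n_lags,internal_lags ACR window (defaults 350 / 1400).
#' @return A data.frame of class `monitoring_records`: `source_file`,
#'   `elapsed_hours`, `diameter_ann` (m), `diameter_ref` (m or NA),
#'   `qc_flags` (`;`-separated, empty when clean).
#' @export
process_run <- function(directory, model, setup, interval_minutes = 30,
                        with_reference = FALSE, manifest = NULL,
                        pattern = "\\.(txt|dat|csv|wav)$",
                        n_lags = 350L, internal_lags = 4L * n_lags) {
  stopifnot(inherits(model, "dls_ann"))
  validate_optical_setup(setup)
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read.csv(manifest)
  }
  if (!is.null(manifest)) {
    if (!all(c("file", "elapsed_hours") %in% names(manifest))) {
      stop("manifest needs columns `file` and `elapsed_hours`", call. = FALSE)
    }
    files <- file.path(directory, manifest$file)
    elapsed <- manifest$elapsed_hours
  } else {
    if (!dir.exists(directory)) {
      stop("directory not found: ", directory, call. = FALSE)
    }
    files <- sort(list.files(directory, pattern = pattern,
                             full.names = TRUE))
    elapsed <- (seq_along(files) - 1) * interval_minutes / 60
  }
  if (length(files) == 0L) {
    stop("no readable series files in ", directory, call. = FALSE)
  }
  records <- lapply(seq_along(files), function(i) {
    rec <- list(source_file = basename(files[i]),
                elapsed_hours = elapsed[i],
                diameter_ann = NA_real_, diameter_ref = NA_real_,
                qc = character())
    series <- tryCatch(
      read_series_file(files[i],
                       sampling_frequency = setup$sampling_frequency),
      error = function(e) e)
    if (inherits(series, "error")) {
      rec$qc <- "read-error"
      return(rec)
    }
    if (length(series$samples) <= internal_lags) {
      rec$qc <- "short-series"
      return(rec)
    }
    curve <- tryCatch(
      normalized_acr(series, n_lags = n_lags, internal_lags = internal_lags),
      error = function(e) e)
    if (inherits(curve, "error")) {
      rec$qc <- "degenerate-acr"
      return(rec)
    }
    rec$diameter_ann <- predict_diameter(model, curve)
    if (with_reference) {
      fit <- fit_single_exponential(curve, setup)
      rec$diameter_ref <- fit$diameter
      if (!fit$converged) rec$qc <- c(rec$qc, "boundary-fit")
    }
    rec
  })
  out <- data.frame(
    source_file = vapply(records, `[[`, "", "source_file"),
    elapsed_hours = vapply(records, `[[`, 0, "elapsed_hours"),
    diameter_ann = vapply(records, `[[`, 0, "diameter_ann"),
    diameter_ref = vapply(records, `[[`, 0, "diameter_ref"),
    qc_flags = vapply(records, function(r) paste(r$qc, collapse = ";"), "")
  )
  if (is.unsorted(out$elapsed_hours)) {
    ord <- order(out$elapsed_hours)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("monitoring_records", "data.frame")
  out
}

#' Summarize diameter plateaus of a monitoring run
#'
#' Median and quartiles of the sized diameters over user-chosen,
#' non-overlapping time intervals (e.g. the stable phases of a
#' fermentation). QC-flagged records are excluded by default.
#'
#' @param records A `monitoring_records` data.frame from
#'   [process_run()].
#' @param intervals List of `c(t_start, t_end)` pairs in hours.
#' @param use One of `"ann"` (default) or `"ref"`: which diameter
#'   column to summarize.
#' @param include_flagged Keep QC-flagged records (default FALSE).
#' @return A data.frame: `t_start`, `t_end`, `n_records`, `median`,
#'   `q1`, `q3` (diameters in metres; NA when the interval is empty).
#' @export
plateau_stats <- function(records, intervals, use = c("ann", "ref"),
                          include_flagged = FALSE) {
  use <- match.arg(use)
  iv <- do.call(rbind, lapply(intervals, function(x) {
    if (length(x) != 2L || !(x[1L] < x[2L])) {
      stop("each interval must be c(t_start, t_end) with t_start < t_end",
           call. = FALSE)
    }
    as.numeric(x)
  }))
  if (nrow(iv) > 1L) {
    o <- order(iv[, 1L])
    if (any(iv[o, 2L][-nrow(iv)] > iv[o, 1L][-1L])) {
      stop("plateau intervals must not overlap", call. = FALSE)
    }
  }
  d <- if (use == "ann") records$diameter_ann else records$diameter_ref
  keep <- !is.na(d)
  if (!include_flagged) keep <- keep & records$qc_flags == ""
  do.call(rbind, lapply(seq_len(nrow(iv)), function(k) {
    sel <- keep & records$elapsed_hours >= iv[k, 1L] &
      records$elapsed_hours <= iv[k, 2L]
    vals <- d[sel]
    data.frame(
      t_start = iv[k, 1L], t_end = iv[k, 2L], n_records = sum(sel),
      median = if (any(sel)) median(vals) else NA_real_,
      q1 = if (any(sel)) unname(quantile(vals, 0.25)) else NA_real_,
      q3 = if (any(sel)) unname(quantile(vals, 0.75)) else NA_real_)
  }))
}

#' Write monitoring records to CSV
#'
#' Columns: `source_file`, `elapsed_hours`, `diameter_ann_nm`,
#' `diameter_ref_nm`, `qc_flags`.
#'
#' @param records A `monitoring_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- data.frame(source_file = records$source_file,
                   elapsed_hours = records$elapsed_hours,
                   diameter_ann_nm = records$diameter_ann * 1e9,
                   diameter_ref_nm = records$diameter_ref * 1e9,
                   qc_flags = records$qc_flags)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
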