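#' Save / load a trained sizing network
#'
#' Models are stored as a versioned JSON container holding the layer
#' sizes, all weights and biases, the input and target scaling maps,
#' the training provenance, and an MD5 checksum of the payload.
#' Floating-point values are encoded as 17-significant-digit decimal
#' strings, which identify IEEE doubles uniquely, so a reloaded model
#' predicts bit-for-bit identically and re-saving a loaded model
#' reproduces the file byte for byte.
#'
#' @param model A `dls_ann`.
#' @param path File path (conventionally `.json`).
#' @return `save_ann()` returns `path` invisibly; `load_ann()` returns
#'   a `dls_ann`. Loading fails on a version mismatch or when the
#'   checksum does not match the payload (e.g. a truncated or edited
#'   file).
#' @export
save_ann <- function(model, path) {
  stopifnot(inherits(model, "dls_ann"))
  enc <- function(x) sprintf("%.17g", x)
  payload <- list(
    format = "dlsann-model",
    version = 1L,
    layer_sizes = model$layer_sizes,
    transfer = model$transfer,
    output_transfer = model$output_transfer,
    hidden_weights = enc(as.numeric(t(model$W1))),  # row-major
    hidden_biases = enc(model$b1),
    output_weights = enc(model$w2),
    output_bias = enc(model$b2),
    input_scale = enc(model$in_scale),
    input_shift = enc(model$in_shift),
    target_slope = enc(model$target_slope),
    target_intercept = enc(model$target_intercept),
    provenance = list(
      corpus_hash = model$provenance$corpus_hash,
      seed = as.integer(model$provenance$seed),
      split_fractions = lapply(model$provenance$split_fractions, enc),
      n_series = as.integer(model$provenance$n_series))
  )
  payload_json <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE))
  writeLines(c(payload_json, paste0("checksum:", text_md5(payload_json))),
             path, sep = "\n")
  invisible(path)
}

text_md5 <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f, sep = "")
  unname(tools::md5sum(f))
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[length(lines)], "checksum:")) {
    stop("model file is truncated or missing its checksum: ", path,
         call. = FALSE)
  }
  payload_json <- paste(lines[-length(lines)], collapse = "\n")
  stored <- sub("^checksum:", "", lines[length(lines)])
  if (!identical(stored, text_md5(payload_json))) {
    stop("model file checksum mismatch (corrupted or edited): ", path,
         call. = FALSE)
  }
  p <- jsonlite::fromJSON(payload_json, simplifyVector = TRUE)
  if (!identical(p$format, "dlsann-model")) {
    stop("not a dlsann model file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(p$version), 1L)) {
    stop(sprintf("unsupported model format version %s", p$version),
         call. = FALSE)
  }
  sizes <- as.integer(p$layer_sizes)
  prov <- p$provenance
  prov$seed <- as.integer(prov$seed)
  prov$split_fractions <- lapply(prov$split_fractions, as.numeric)
  prov$n_series <- as.integer(prov$n_series)
  structure(list(
    layer_sizes = sizes,
    W1 = matrix(as.numeric(p$hidden_weights), nrow = sizes[2L],
                byrow = TRUE),
    b1 = as.numeric(p$hidden_biases),
    w2 = as.numeric(p$output_weights),
    b2 = as.numeric(p$output_bias),
    transfer = p$transfer,
    output_transfer = p$output_transfer,
    in_scale = as.numeric(p$input_scale),
    in_shift = as.numeric(p$input_shift),
    target_slope = as.numeric(p$target_slope),
    target_intercept = as.numeric(p$target_intercept),
    provenance = prov
  ), class = "dls_ann")
}
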