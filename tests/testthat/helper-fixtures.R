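# Shared fixtures, built lazily and memoised for the whole test run.
# Small corpora use shorter series (8192 samples) than the production
# default so the suite stays fast; the ACR window (350 kept / 1400
# internal lags) is unchanged.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

bench_setup <- function() optical_setup()

# 120-series corpus, 25-6000 nm in 50 nm steps, short series.
small_corpus <- function() {
  memo("small_corpus", function() {
    generate_training_corpus(bench_setup(), step = 50e-9,
                             n_points = 8192L, master_seed = 4242L)
  })
}

# Network trained on the small corpus, reused by monitor/CLI tests.
small_model <- function() {
  memo("small_model", function() {
    train_ann(small_corpus(), seed = 7L)
  })
}

# Full desk-scale study: 25-6000 nm in 5 nm steps (1,196 series at the
# production 32,768-sample length), reference-fit targets, trained
# 350-26-1 network. Takes a couple of minutes; built once per run.
acceptance_run <- function() {
  memo("acceptance_run", function() {
    corpus <- generate_training_corpus(bench_setup(), step = 5e-9,
                                       master_seed = 1L)
    trained <- train_ann(corpus, seed = 1L)
    list(corpus = corpus, model = trained$model, report = trained$report,
         errors = evaluate_ann(trained$model, corpus))
  })
}

# Clean-trained vs noise-trained comparison shared by the network and
# acceptance tests. A twin of the acceptance corpus is built from
# noise-free series of the same diameters/seeds and a second network is
# trained on it; both networks are then scored on the NOISY corpus
# ACRs against the noisy reference-fit targets (|relative error| per
# series, in percent).
clean_vs_noisy_errors <- function() {
  memo("clean_vs_noisy", function() {
    run <- acceptance_run()
    setup <- bench_setup()
    noisy_corpus <- run$corpus
    clean_corpus <- noisy_corpus
    for (i in seq_len(nrow(clean_corpus$acr))) {
      s <- generate_clean_series(
        setup, synthesis_config(clean_corpus$diameters_true[i],
                                n_points = clean_corpus$n_points,
                                seed = clean_corpus$seeds[i]))
      cv <- normalized_acr(s)
      clean_corpus$acr[i, ] <- cv$values
      clean_corpus$diameters_reference[i] <-
        fit_single_exponential(cv, setup)$diameter
    }
    m_clean <- train_ann(clean_corpus, seed = 1L)$model
    err_on_noisy <- function(model) {
      abs(relative_error(predict_diameter(model, noisy_corpus$acr),
                         noisy_corpus$diameters_reference))
    }
    list(noisy_trained = err_on_noisy(run$model),
         clean_trained = err_on_noisy(m_clean))
  })
}

# Write n simulated noisy series for diameters `d` (m) as text files
# under dir; returns the file paths in written order.
write_run_files <- function(dir, d, setup = bench_setup(),
                            n_points = 8192L, seed0 = 900L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(d), function(i) {
    s <- generate_noisy_series(
      setup, synthesis_config(d[i], n_points = n_points, seed = seed0 + i))
    path <- file.path(dir, sprintf("rec%03d.txt", i))
    write_series_file(s, path)
    path
  }, "")
}
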