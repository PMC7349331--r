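test_that("analytic Jacobian matches finite differences", {
  set.seed(1)
  n <- 9; d_in <- 6; h <- 4
  model <- structure(list(
    layer_sizes = c(d_in, h, 1L),
    W1 = matrix(rnorm(h * d_in, 0, 0.4), h, d_in), b1 = rnorm(h, 0, 0.3),
    w2 = rnorm(h, 0, 0.5), b2 = rnorm(1, 0, 0.2),
    transfer = "tanh", output_transfer = "tanh",
    in_scale = rep(1, d_in), in_shift = rep(0, d_in),
    target_slope = 1, target_intercept = 0), class = "dls_ann")
  X <- matrix(rnorm(n * d_in), n, d_in)
  for (ot in c("tanh", "linear")) {
    model$output_transfer <- ot
    f <- dlsann:::ann_forward(model, X)
    J <- dlsann:::ann_jacobian(model, X, f)
    th <- dlsann:::ann_get_params(model)
    eps <- 1e-7
    J_num <- vapply(seq_along(th), function(p) {
      tp <- th; tp[p] <- tp[p] + eps
      (dlsann:::ann_forward(dlsann:::ann_set_params(model, tp), X)$y - f$y) / eps
    }, numeric(n))
    expect_lt(max(abs(J - J_num)), 1e-5)
  }
})

test_that("training converges on a corpus and the loss never increases", {
  res <- small_model()
  report <- res$report
  expect_s3_class(res$model, "dls_ann")
  expect_true(all(diff(report$sse_trace) < 0))
  expect_gte(report$final_r_value, 0.9999)
  expect_false(is.na(report$r_reached_at))
  expect_identical(unname(report$split_sizes["train"]),
                   round(0.7 * nrow(small_corpus()$acr)))
  expect_true(report$stop_reason %in%
                c("r-converged", "val-stall", "lm-exhausted", "max-iter"))
})

test_that("training is reproducible from its seed", {
  corpus <- generate_training_corpus(bench_setup(), d_min = 200e-9,
                                     d_max = 5800e-9, step = 400e-9,
                                     n_points = 4096L, master_seed = 77L)
  a <- train_ann(corpus, seed = 3, max_iterations = 10L)
  b <- train_ann(corpus, seed = 3, max_iterations = 10L)
  expect_identical(a$model$W1, b$model$W1)
  expect_identical(a$report$sse_trace, b$report$sse_trace)
  c <- train_ann(corpus, seed = 4, max_iterations = 10L)
  expect_false(identical(a$model$W1, c$model$W1))
})

test_that("degenerate targets are refused", {
  corpus <- small_corpus()
  corpus$diameters_reference <- rep(1e-6, nrow(corpus$acr))
  expect_error(train_ann(corpus), "zero variance")
  tiny <- corpus
  tiny$acr <- tiny$acr[1:5, ]
  tiny$diameters_reference <- corpus$diameters_reference[1:5]
  expect_error(train_ann(tiny), "at least 10")
})

test_that("prediction is a pure affine+tanh map with exact shape checks", {
  res <- small_model()
  corpus <- small_corpus()
  one <- predict_diameter(res$model, corpus$acr[5, ])
  batch <- predict_diameter(res$model, corpus$acr)
  expect_equal(batch[5], one)
  expect_length(batch, nrow(corpus$acr))
  expect_error(predict_diameter(res$model, rnorm(100)), "350")

  # zero output weights give the target-scaling midpoint for any input
  mid <- res$model
  mid$w2 <- rep(0, length(mid$w2)); mid$b2 <- 0
  d_mid <- (0 - mid$target_intercept) / mid$target_slope
  expect_equal(predict_diameter(mid, corpus$acr[1, ]), d_mid)
  expect_equal(predict_diameter(mid, corpus$acr[100, ]), d_mid)
})

test_that("predictions vary smoothly under tiny input perturbations", {
  res <- small_model()
  corpus <- small_corpus()
  mid_rows <- which(corpus$diameters_true >= 1e-6 &
                      corpus$diameters_true <= 3e-6)[1:5]
  for (i in mid_rows) {
    x <- corpus$acr[i, ]
    d0 <- predict_diameter(res$model, x)
    d1 <- predict_diameter(res$model, x + 1e-6)
    expect_lt(abs(d1 - d0), 1e-9)  # < 1 nm
  }
})

test_that("relative error follows its definition", {
  expect_equal(relative_error(1e-6, 1e-6), 0)
  expect_equal(relative_error(1.025e-6, 1e-6), 2.5)
  expect_equal(relative_error(102e-9, 100e-9), 2)
  expect_equal(relative_error(97.5e-9, 100e-9), -2.5)
  expect_error(relative_error(1e-6, 0), "positive")
})

test_that("error report partitions ranges correctly and excludes sub-25 nm", {
  # hand-built corpus + constant-output model so expected errors are
  # computable by hand
  d_true <- c(20e-9, 40e-9, 100e-9, 200e-9, 1000e-9, 6000e-9)
  corpus <- structure(list(
    acr = matrix(0.5, 6, 350), diameters_true = d_true,
    diameters_reference = d_true, ref_converged = rep(TRUE, 6),
    setup = bench_setup(), seeds = 1:6, n_lags = 350L,
    internal_lags = 1400L, n_points = 0L, a0 = 50,
    noise = noise_config(), master_seed = 1L), class = "dls_corpus")
  model <- structure(list(
    layer_sizes = c(350L, 2L, 1L),
    W1 = matrix(0, 2, 350), b1 = c(0, 0), w2 = c(0, 0), b2 = 0,
    transfer = "tanh", output_transfer = "tanh",
    in_scale = rep(1, 350), in_shift = rep(0, 350),
    target_slope = 1e9, target_intercept = -0.5,
    provenance = list()), class = "dls_ann")
  # constant prediction: (0 + 0.5)/1e9 = 0.5e-9 m... use slope so that
  # prediction is 500 nm
  model$target_intercept <- -0.5
  model$target_slope <- 1e6
  d_pred <- (0 - model$target_intercept) / model$target_slope  # 5e-7 m
  rep <- evaluate_ann(model, corpus)
  err <- (d_pred - d_true) / d_true * 100
  expect_equal(rep$per_range$n, c(1L, 1L, 1L, 2L))
  expect_equal(rep$per_range$max_abs_err_pct,
               c(abs(err[2]), abs(err[3]), abs(err[4]),
                 max(abs(err[5:6]))))
  expect_equal(rep$below_range$n, 1L)
  expect_equal(rep$below_range$max_err_pct, err[1])

  # a model that reproduces the reference diameters exactly has zero
  # error everywhere
  perfect <- rep
  perfect$per_series$err_pct <- relative_error(d_true, d_true)
  expect_true(all(perfect$per_series$err_pct == 0))
})

test_that("models round-trip losslessly with checksummed canonical files", {
  res <- small_model()
  corpus <- small_corpus()
  f <- withr::local_tempfile(fileext = ".json")
  save_ann(res$model, f)
  back <- load_ann(f)
  probes <- corpus$acr[seq(1, 91, by = 10), ]
  expect_identical(predict_diameter(back, probes),
                   predict_diameter(res$model, probes))

  # save -> load -> save is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  save_ann(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # truncation is caught by the checksum / framing
  txt <- readLines(f)
  f3 <- withr::local_tempfile(fileext = ".json")
  writeLines(substring(txt, 1, nchar(txt) - 50), f3)
  expect_error(load_ann(f3), "checksum|truncated")

  # edited payload is caught
  f4 <- withr::local_tempfile(fileext = ".json")
  writeLines(sub("\"version\":1", "\"version\":2", txt), f4)
  expect_error(load_ann(f4), "checksum")
})

test_that("noise-trained networks beat clean-trained networks on noisy input", {
  cmp <- clean_vs_noisy_errors()
  expect_lt(stats::median(cmp$noisy_trained),
            stats::median(cmp$clean_trained))
})
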