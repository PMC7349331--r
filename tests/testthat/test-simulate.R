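test_that("spectral synthesis equals the literal harmonic sum", {
  setup <- bench_setup()
  for (seed in c(3, 17, 91)) {
    cfg <- synthesis_config(500e-9, n_points = 64L, n_freqs = 33L,
                            seed = seed)
    fast <- generate_clean_series(setup, cfg, method = "fft")
    slow <- generate_clean_series(setup, cfg, method = "direct")
    expect_lt(max(abs(fast$samples - slow$samples)), 1e-9)
  }
  # mismatched n_freqs is rejected on the FFT path but fine directly
  bad <- synthesis_config(500e-9, n_points = 64L, n_freqs = 20L, seed = 1)
  expect_error(generate_clean_series(setup, bad), "n_freqs")
  expect_silent(generate_clean_series(setup, bad, method = "direct"))
})

test_that("a single harmonic component is a pure sine", {
  n <- 256; fs <- 16000; f0 <- 1250; amp <- 2.5; ph <- 0.8
  x <- dlsann:::.harmonic_sum_exact(n, 1 / fs, f0, amp, ph)
  t <- (0:(n - 1)) / fs
  expect_equal(x, amp * sin(2 * pi * f0 * t + ph), tolerance = 1e-12)
  # recurrence path agrees with the literal path on many components
  set.seed(5)
  fr <- runif(300, 1, fs); am <- runif(300); phs <- runif(300, 0, 2 * pi)
  a <- dlsann:::.harmonic_sum_exact(8192, 1 / fs, fr, am, phs)
  b <- dlsann:::.harmonic_sum_fast(8192, 1 / fs, fr, am, phs)
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("clean synthesis is deterministic given a seed", {
  setup <- bench_setup()
  cfg <- synthesis_config(1e-6, n_points = 1024L, seed = 11)
  s1 <- generate_clean_series(setup, cfg)
  s2 <- generate_clean_series(setup, cfg)
  expect_identical(s1$samples, s2$samples)
  cfg2 <- synthesis_config(1e-6, n_points = 1024L, seed = 12)
  expect_false(identical(s1$samples,
                         generate_clean_series(setup, cfg2)$samples))
})

test_that("clean series periodograms average to the Lorentzian spectrum", {
  setup <- bench_setup()
  d <- 500e-9
  n <- 4096L
  acc <- 0
  for (k in 1:200) {
    s <- generate_clean_series(setup,
                               synthesis_config(d, n_points = n, seed = 600 + k))
    acc <- acc + Mod(fft(s$samples))^2 / n
  }
  pgram <- acc / 200
  fs <- setup$sampling_frequency
  freqs <- (0:(n / 2)) * fs / n
  a1 <- halfwidth_from_diameter(setup, d)
  expected <- lorentzian_spectrum(50, a1, freqs) * n / 4
  # central band: away from DC and Nyquist edge effects
  band <- 10:(n / 2 - 10)
  rel_dev <- abs(pgram[band + 1] - expected[band + 1]) / expected[band + 1]
  expect_lt(stats::median(rel_dev), 0.10)
})

test_that("power grid noise injects the prescribed harmonic comb", {
  setup <- bench_setup()
  clean <- generate_clean_series(setup,
                                 synthesis_config(1e-6, n_points = 2048L,
                                                  seed = 21))
  cfg <- noise_config(seed = 99)
  noisy <- add_power_grid_noise(clean, cfg)
  expect_s3_class(noisy, "dls_time_series")
  expect_identical(noisy$origin, "simulated-noisy")

  # replay: i_max = round(fs/50) = 320 harmonics with amplitudes
  # 0.03 * A_ts * exp(-0.25 i) and the same seeded phases
  a_ts <- max(clean$samples) - min(clean$samples)
  i <- 1:320
  phases <- withr::with_seed(99, runif(320, 0, 2 * pi))
  t <- (0:2047) / 16000
  expected <- rowSums(vapply(i, function(j) {
    0.03 * a_ts * exp(-0.25 * j) * sin(2 * pi * 50 * j * t + phases[j])
  }, numeric(2048)))
  expect_equal(noisy$samples - clean$samples, expected, tolerance = 1e-9)

  # first harmonic coefficient: 0.03 * exp(-0.25) = 0.023364
  expect_equal(0.03 * exp(-0.25), 0.023364, tolerance = 1e-4)

  # zero coefficient is the identity
  none <- add_power_grid_noise(clean, noise_config(grid_amp_coeff = 0))
  expect_identical(none$samples, clean$samples)

  # constant series is degenerate
  flat <- dls_time_series(rep(3, 100), 16000)
  expect_error(add_power_grid_noise(flat, cfg), "degenerate")
})

test_that("broadband noise matches its formula and adds power on average", {
  setup <- bench_setup()
  clean <- generate_clean_series(setup,
                                 synthesis_config(1e-6, n_points = 2048L,
                                                  seed = 31))
  cfg <- noise_config(seed = 77)
  noisy <- add_random_noise(clean, cfg)
  a_ts <- max(clean$samples) - min(clean$samples)
  draws <- withr::with_seed(77, list(f = runif(300, 1, 16000),
                                     ph = runif(300, 0, 2 * pi)))
  t <- (0:2047) / 16000
  expected <- rowSums(vapply(1:300, function(j) {
    0.01 * a_ts * exp(-0.005 * j) * sin(2 * pi * draws$f[j] * t + draws$ph[j])
  }, numeric(2048)))
  expect_equal(noisy$samples - clean$samples, expected, tolerance = 1e-9)

  # component 300 amplitude coefficient: 0.01 * exp(-1.5) = 0.0022313
  expect_equal(0.01 * exp(-1.5), 0.0022313, tolerance = 1e-4)

  # n_rnd = 0 is the identity
  same <- add_random_noise(clean, noise_config(n_rnd = 0))
  expect_identical(same$samples, clean$samples)

  # independent sinusoids add nonnegative power: variance grows on
  # average over seeds
  delta <- vapply(1:50, function(s) {
    stats::var(add_random_noise(clean, noise_config(seed = s))$samples) -
      stats::var(clean$samples)
  }, 0)
  expect_gt(mean(delta), 0)
})

test_that("noisy series decomposes exactly into clean + grid + broadband", {
  setup <- bench_setup()
  cfg <- synthesis_config(1e-6, n_points = 2048L, seed = 41)
  clean <- generate_clean_series(setup, cfg)
  noisy <- generate_noisy_series(setup, cfg)
  grid <- add_power_grid_noise(clean, noise_config(seed = 3 * 41 + 1))
  full <- add_random_noise(grid, noise_config(seed = 3 * 41 + 2))
  expect_identical(noisy$samples, full$samples)
})

test_that("training corpus has the right shape, ordering and determinism", {
  setup <- bench_setup()
  corpus <- generate_training_corpus(setup, d_min = 100e-9, d_max = 5600e-9,
                                     step = 500e-9, n_points = 4096L,
                                     master_seed = 5L)
  expect_equal(nrow(corpus$acr), 12L)
  expect_equal(ncol(corpus$acr), 350L)
  expect_true(all(diff(corpus$diameters_true) > 0))
  expect_true(all(is.finite(corpus$acr)))
  expect_true(all(corpus$acr[, 1] == 1))
  expect_true(all(corpus$diameters_reference > 0))

  again <- generate_training_corpus(setup, d_min = 100e-9, d_max = 5600e-9,
                                    step = 500e-9, n_points = 4096L,
                                    master_seed = 5L)
  expect_identical(corpus$acr, again$acr)
  expect_identical(corpus$diameters_reference, again$diameters_reference)

  # diameter-grid arithmetic: 25-6000 nm at 0.5 / 5 nm steps
  expect_length(seq(25e-9, 6000e-9, by = 0.5e-9), 11951L)
  expect_length(seq(25e-9, 6000e-9, by = 5e-9), 1196L)

  # grids too small for a 70/15/15 split are refused
  expect_error(
    generate_training_corpus(setup, d_min = 1e-6, d_max = 2e-6, step = 1e-6),
    "at least 10")
})

test_that("corpus round-trips through the JSON container and flat CSV", {
  setup <- bench_setup()
  corpus <- generate_training_corpus(setup, d_min = 200e-9, d_max = 5200e-9,
                                     step = 500e-9, n_points = 4096L,
                                     master_seed = 9L)
  f <- withr::local_tempfile(fileext = ".json")
  write_corpus(corpus, f)
  back <- read_corpus(f)
  expect_equal(back$acr, corpus$acr)
  expect_equal(back$diameters_true, corpus$diameters_true)
  expect_equal(back$diameters_reference, corpus$diameters_reference)
  expect_equal(unclass(back$setup), unclass(corpus$setup))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus_csv(corpus, f2)
  df <- read.csv(f2)
  expect_equal(nrow(df), 11L)
  expect_equal(ncol(df), 352L)
  expect_equal(df$diameter_true_nm, corpus$diameters_true * 1e9)
})
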