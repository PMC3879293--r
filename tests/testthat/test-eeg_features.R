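# EEG preprocessing and feature extraction stages.

toy_trialset <- function(X, fs = 250, label = 1L) {
  trial_set(list(X), fs = fs, labels = label)
}

test_that("surface Laplacian subtracts the mean of four neighbors", {
  nm <- list(c3 = c("n1", "n2", "n3", "n4"))
  # constant signal on all channels -> zero on the mapped channel
  Xc <- matrix(2, 5, 10)
  ts <- trial_set(list(Xc), 250, 1L, channel_names = c("c3", paste0("n", 1:4)))
  expect_warning(out <- surface_laplacian(ts, nm), "pass through")
  expect_equal(out$trials[[1]][1, ], rep(0, 10))
  expect_equal(out$trials[[1]][2, ], rep(2, 10))  # unmapped untouched
  # center 4, neighbors 1 -> 3
  X2 <- rbind(rep(4, 5), matrix(1, 4, 5))
  ts2 <- trial_set(list(X2), 250, 1L, channel_names = c("c3", paste0("n", 1:4)))
  expect_equal(suppressWarnings(surface_laplacian(ts2, nm))$trials[[1]][1, ],
               rep(3, 5))
  # values (1, 0, -1, 2) around center 2 -> 2 - 0.5 = 1.5
  X3 <- rbind(rep(2, 3), rep(1, 3), rep(0, 3), rep(-1, 3), rep(2, 3))
  ts3 <- trial_set(list(X3), 250, 1L, channel_names = c("c3", paste0("n", 1:4)))
  expect_equal(suppressWarnings(surface_laplacian(ts3, nm))$trials[[1]][1, ],
               rep(1.5, 3))
  expect_error(surface_laplacian(ts3, list(c3 = c("n1", "n2", "n3", "zz"))),
               "unknown channel")
  expect_error(surface_laplacian(ts3, list(c3 = c("n1", "n2", "n3"))),
               "exactly 4")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mk <- function(f) toy_trialset(matrix(sin(2 * pi * f * t), 1), fs)
  amp <- function(ts) {
    x <- ts$trials[[1]][1, ]
    core <- x[(fs):(length(x) - fs)]        # avoid edge transients
    (max(core) - min(core)) / 2
  }
  in_band <- butterworth_bandpass(mk(10), 5, 30, order = 6)
  expect_equal(amp(in_band), 1, tolerance = 0.05)
  out_band <- butterworth_bandpass(mk(2), 5, 30, order = 6)
  expect_lte(amp(out_band), 0.1)            # >= 90% attenuation
  # oracle: the designed transfer function evaluated at 2 Hz, applied twice
  # (forward-backward filtering squares the magnitude response)
  bf <- signal::butter(3, c(5, 30) / (fs / 2), type = "pass")
  zv <- exp(-1i * 2 * pi * 2 / fs * (seq_along(bf$b) - 1))
  H2 <- abs(sum(bf$b * zv) / sum(bf$a * zv))^2
  expect_equal(amp(out_band), H2, tolerance = max(0.02, 0.5 * H2))
  # stop-band attenuation of >= 20 dB on a 50 Hz tone
  stop_tone <- butterworth_bandpass(mk(50), 5, 30, order = 6)
  expect_lte(amp(stop_tone), 10^(-20 / 20))
  # zero in, zero out
  z <- butterworth_bandpass(toy_trialset(matrix(0, 1, 1000), fs), 5, 30)
  expect_equal(z$trials[[1]], matrix(0, 1, 1000))
  expect_error(butterworth_bandpass(mk(10), 30, 5), "low_hz < high_hz")
  expect_error(butterworth_bandpass(mk(10), 5, 200), "high_hz < fs/2")
})

test_that("epoch extraction uses a half-open 0-based sample window", {
  X <- matrix(seq_len(4 * 250), 1)            # 4 s at 250 Hz
  ts <- toy_trialset(X, 250)
  ep <- extract_epoch(ts, 0.5, 2.5)
  expect_identical(ncol(ep$trials[[1]]), 500L)  # (2.5 - 0.5) * 250
  expect_equal(ep$trials[[1]][1, 1], X[1, 126]) # sample round(0.5*250) 0-based
  full <- extract_epoch(ts, 0, 4)
  expect_identical(full$trials[[1]], X)
  expect_error(extract_epoch(ts, 1, 1), "outside the trial")
  expect_error(extract_epoch(ts, 3.5, 4.5), "outside the trial")
})

test_that("two-class CSP recovers the discriminative axis of a diagonal pencil", {
  # class covariances diag(10, 1) vs diag(1, 10): top filter is axis 1
  withr::with_seed(31, {
    tr1 <- lapply(1:20, function(i)
      rbind(rnorm(200, sd = sqrt(10)), rnorm(200, sd = 1)))
    tr2 <- lapply(1:20, function(i)
      rbind(rnorm(200, sd = 1), rnorm(200, sd = sqrt(10))))
  })
  ts <- trial_set(c(tr1, tr2), 250, rep(1:2, each = 20))
  model <- fit_csp_ovr(ts, m = 1)
  w <- model$filters[, 1]                     # class-1 maximal-variance end
  cosine <- abs(w[1]) / sqrt(sum(w^2))
  expect_gt(cosine, 0.99)
  # 2 classes x 2m filters
  expect_identical(ncol(model$filters), 4L)
})

test_that("one-vs-rest CSP feature count is 2mC", {
  ts <- make_synthetic_trials(n_classes = 4, n_channels = 22, fs = 250,
                              duration_s = 3, band_powers = rep(16, 4),
                              n_trials_per_class = 6, seed = 1)
  ts <- extract_epoch(butterworth_bandpass(ts, 5, 30), 0.5, 2.5)
  model <- fit_csp_ovr(ts, m = 3)
  expect_identical(ncol(model$filters), 24L)
  f <- csp_features(model, ts$trials[[1]])
  expect_length(f, 24L)
  fm <- csp_feature_matrix(model, ts)
  expect_identical(dim(fm), c(24L, 24L))
})

test_that("identical class distributions give near-0.5 eigenvalues", {
  withr::with_seed(32, {
    tr <- lapply(1:30, function(i) matrix(rnorm(4 * 300), 4, 300))
  })
  ts <- trial_set(tr, 250, rep(1:2, each = 15))
  expect_message(model <- fit_csp_ovr(ts, m = 1), "near 0.5")
  expect_true(all(abs(unlist(model$eigenvalues) - 0.5) < 0.05))
})

test_that("log-variance features follow the hand arithmetic", {
  # identity filters on a 2-channel, 4-sample trial
  X <- rbind(c(1, -1, 1, -1), c(2, -2, 2, -2))
  model <- structure(list(filters = diag(2), classes = 1L, m = 1L,
                          n_channels = 2L),
                     class = "csp_model")
  v <- c(stats::var(X[1, ]), stats::var(X[2, ]))
  expect_equal(csp_features(model, X), log(v / sum(v)))
  expect_equal(csp_features(model, X, normalize = FALSE), log(v))
  # amplitude rescaling leaves normalized features unchanged
  expect_equal(csp_features(model, 3.7 * X), csp_features(model, X),
               tolerance = 1e-12)
  # energy concentrated along filter 1 -> feature 1 maximal
  Xc <- rbind(c(10, -10, 10, -10), c(0.1, -0.1, 0.1, -0.1))
  f <- csp_features(model, Xc)
  expect_identical(which.max(f), 1L)
  expect_error(csp_features(model, matrix(0, 2, 4)), "zero total")
  expect_error(csp_features(model, matrix(1, 3, 4)), "channels")
})

test_that("CSP filters are scale-invariant under trace normalization", {
  withr::with_seed(33, {
    tr1 <- lapply(1:15, function(i)
      rbind(rnorm(200, sd = 3), rnorm(200, sd = 1), rnorm(200)))
    tr2 <- lapply(1:15, function(i)
      rbind(rnorm(200, sd = 1), rnorm(200, sd = 3), rnorm(200)))
  })
  ts <- trial_set(c(tr1, tr2), 250, rep(1:2, each = 15))
  m1 <- fit_csp_ovr(ts, m = 1)
  ts_scaled <- ts
  ts_scaled$trials <- lapply(ts$trials, function(X) 5 * X)
  m2 <- fit_csp_ovr(ts_scaled, m = 1)
  for (j in seq_len(ncol(m1$filters))) {
    a <- m1$filters[, j]; b <- m2$filters[, j]
    expect_gt(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1 - 1e-6)
  }
})

test_that("Welch band features have the stated dimensionality and locality", {
  fs <- 512
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  # 8 channels x 12 bins = 96 dimensions
  X <- matrix(rnorm(8 * length(t)), 8)
  f <- psd_features(trial_set(list(X), fs, 1L))
  expect_identical(ncol(f), 96L)
  # pure 10 Hz tone: its bin dominates the channel block
  tone <- rbind(sin(2 * pi * 10 * t), rnorm(length(t), sd = 0.01))
  ft <- psd_features(trial_set(list(tone), fs, 1L))
  block1 <- ft[1, 1:12]                        # bins 8, 10, ..., 30 Hz
  expect_identical(which.max(block1), 2L)      # the 10 Hz bin
  expect_gte(block1[2] / sum(block1), 0.8)
  # zero signal -> all-zero features
  fz <- psd_features(trial_set(list(matrix(0, 2, 1024)), fs, 1L))
  expect_equal(unname(fz), matrix(0, 1, 24))
  expect_error(psd_features(trial_set(list(matrix(0, 1, 100)), fs, 1L)),
               "shorter than")
})

test_that("unit normalization and first-of-k downsampling behave as stated", {
  expect_equal(unit_normalize(c(3, 4)), c(0.6, 0.8))
  expect_error(unit_normalize(c(0, 0)), "zero vector")
  withr::with_seed(34, {
    for (i in 1:20)
      expect_equal(sqrt(sum(unit_normalize(rnorm(10))^2)), 1,
                   tolerance = 1e-12)
  })
  expect_identical(downsample_first_of_k(1:16, 8), c(1L, 9L))
  m <- matrix(1:32, 16, 2)
  expect_identical(downsample_first_of_k(m, 8), m[c(1, 9), ])
})

test_that("trial sets round-trip through the TSV manifest format", {
  ts <- make_synthetic_trials(n_classes = 2, n_channels = 3, fs = 100,
                              duration_s = 0.5, n_trials_per_class = 2,
                              seed = 5)
  dir <- withr::local_tempdir()
  write_trialset(ts, dir)
  ts2 <- read_trialset(dir)
  expect_equal(ts2$labels, ts$labels)
  expect_equal(ts2$fs, ts$fs)
  for (i in seq_along(ts$trials))
    expect_equal(unname(ts2$trials[[i]]), unname(ts$trials[[i]]),
                 tolerance = 1e-6)
})
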