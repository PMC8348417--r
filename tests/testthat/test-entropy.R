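test_that("permutation entropy matches hand-enumerated ordinal patterns", {
  # 5 patterns of [4,7,9,10,6,11,3] at m=3: {012 x2, 201 x2, 102 x1}
  x <- c(4, 7, 9, 10, 6, 11, 3)
  h <- -sum(c(2, 2, 1) / 5 * log(c(2, 2, 1) / 5))
  expect_equal(permutation_entropy(x, 3, 1, normalize = FALSE), h)
  expect_equal(round(permutation_entropy(x, 3, 1, normalize = FALSE), 4), 1.0549)
  expect_equal(round(permutation_entropy(x, 3, 1, normalize = TRUE), 4), 0.5888)
  expect_equal(permutation_entropy(1:10, 3, 1), 0)
  expect_error(permutation_entropy(1:3, 3, 1), "too short")
  withr::with_seed(1, {
    for (i in 1:5) {
      expect_gte(permutation_entropy(runif(10000), 3, 1), 0.99)
    }
  })
})

test_that("SVD entropy reflects embedding rank", {
  expect_equal(svd_entropy(rep(3, 50)), 0)
  t <- (0:499) / 100
  sine <- sin(2 * pi * 3 * t)
  expect_lte(svd_entropy(sine, 3, 1, normalize = FALSE), log(2) + 1e-8)
  withr::with_seed(2, {
    for (i in 1:5) expect_gte(svd_entropy(rnorm(10000), 3, 1), 0.9)
  })
  expect_error(svd_entropy(1:2, 3, 1), "too short")
})

test_that("approximate entropy follows the self-inclusive Pincus convention", {
  expect_equal(approximate_entropy(rep(5, 30)), 0)
  x <- rep(c(1, 2), 4)
  expect_equal(approximate_entropy(x, 2, 0.1, r_absolute = TRUE),
               naive_apen(x, 2, 0.1))
  withr::with_seed(3, {
    for (i in 1:100) {
      v <- rnorm(50)
      expect_gte(approximate_entropy(v, 2, 0.2), -1e-10)
    }
  })
  expect_error(approximate_entropy(1:3, 2), "too short")
})

test_that("sample entropy counts template pairs per Richman-Moorman", {
  x <- rep(c(1, 2), 4)
  # 6 same-parity template pairs match at both lengths: A = B = 6
  expect_equal(sample_entropy(x, 2, 0.1, r_absolute = TRUE), 0)
  expect_equal(eegentropy:::sampen_counts(x, 2L, 0.1), c(6, 6))
  expect_equal(sample_entropy(rep(7, 30)), 0)
  withr::with_seed(4, {
    wins <- 0
    for (i in 1:100) {
      noise <- rnorm(128)
      ph <- runif(1, 0, 2 * pi)
      sine <- sqrt(2) * sin(2 * pi * 10 * (0:127) / 256 + ph)
      if (sample_entropy(noise) > sample_entropy(sine)) wins <- wins + 1
    }
    expect_gte(wins, 95)
  })
  # A = 0 is a flagged sentinel (matches at length m that never extend),
  # B = 0 is undefined
  expect_equal(sample_entropy(c(0, 0, 5, 0, 0, -5, 0), 2, 0.1,
                              r_absolute = TRUE), Inf)
  expect_true(is.na(sample_entropy(c(1, 2, 4, 8, 16, 32, 64), 2, 0.1,
                                   r_absolute = TRUE)))
  expect_error(sample_entropy(1:3, 2), "too short")
})

test_that("spectral entropy separates narrowband from broadband", {
  t <- (0:127) / 256
  sine <- sin(2 * pi * 16 * t)  # bin-centered: 16 Hz = bin 8 of 64
  expect_lte(spectral_entropy(sine, 256), 0.05)
  withr::with_seed(5, {
    for (i in 1:5) expect_gte(spectral_entropy(rnorm(10000), 256), 0.9)
  })
  x <- rnorm(128)
  expect_equal(spectral_entropy(x, 256, normalize = FALSE),
               spectral_entropy(x, 256, normalize = TRUE) * log(64))
  expect_true(is.na(spectral_entropy(rep(0, 128), 256)))
  expect_error(spectral_entropy(1:4, 256), "too short")
})

test_that("wavelet entropy concentrates on tones and spreads on noise", {
  t <- (0:511) / 256
  sine <- sin(2 * pi * 10 * t)
  expect_lte(cwt_entropy(sine, 256), 0.3)
  withr::with_seed(6, {
    for (i in 1:5) expect_gte(cwt_entropy(rnorm(4096), 256), 0.8)
  })
  x <- rnorm(256)
  expect_equal(cwt_entropy(x, 256), cwt_entropy(5.7 * x, 256))
  expect_true(is.na(cwt_entropy(rep(0, 128), 256)))
  expect_error(cwt_entropy(rnorm(128), 256, freq_range = c(1, 200)),
               "fs/2")
})

test_that("optimized implementations equal their naive oracles on random series", {
  withr::with_seed(7, {
    for (i in 1:40) {
      n <- sample(20:64, 1)
      x <- rnorm(n)
      r <- 0.2 * sd(x)
      expect_equal(sample_entropy(x, 2, r, r_absolute = TRUE),
                   naive_sampen(x, 2, r), tolerance = 1e-12)
      expect_equal(approximate_entropy(x, 2, r, r_absolute = TRUE),
                   naive_apen(x, 2, r), tolerance = 1e-12)
      expect_equal(permutation_entropy(x, 3, 1), naive_pe(x, 3, 1),
                   tolerance = 1e-12)
      expect_equal(svd_entropy(x, 3, 1), naive_svdent(x, 3, 1),
                   tolerance = 1e-12)
      expect_equal(spectral_entropy(x, 256), naive_spectral(x),
                   tolerance = 1e-12)
    }
    for (i in 1:6) {
      x <- rnorm(sample(32:64, 1))
      expect_equal(cwt_entropy(x, 256), naive_cwt(x, 256), tolerance = 1e-10)
    }
  })
})

test_that("all measures are offset-invariant; scale enters only through r", {
  withr::with_seed(8, {
    x <- rnorm(128)
    off <- x + 57.3
    expect_equal(permutation_entropy(off), permutation_entropy(x))
    expect_equal(sample_entropy(off), sample_entropy(x), tolerance = 1e-8)
    expect_equal(approximate_entropy(off), approximate_entropy(x),
                 tolerance = 1e-8)
    expect_equal(svd_entropy(off), svd_entropy(x), tolerance = 1e-10)
    expect_equal(spectral_entropy(off, 256), spectral_entropy(x, 256),
                 tolerance = 1e-10)
    expect_equal(cwt_entropy(off, 256), cwt_entropy(x, 256),
                 tolerance = 1e-8)
    # scale invariance (relative r for APE/SAE; by construction otherwise)
    sc <- 12.5 * x
    expect_equal(sample_entropy(sc), sample_entropy(x), tolerance = 1e-8)
    expect_equal(approximate_entropy(sc), approximate_entropy(x),
                 tolerance = 1e-8)
    expect_equal(permutation_entropy(sc), permutation_entropy(x))
    expect_equal(svd_entropy(sc), svd_entropy(x), tolerance = 1e-8)
    expect_equal(spectral_entropy(sc, 256), spectral_entropy(x, 256),
                 tolerance = 1e-10)
    expect_equal(cwt_entropy(sc, 256), cwt_entropy(x, 256),
                 tolerance = 1e-10)
  })
})

test_that("every measure responds monotonically to the noise-to-oscillation ratio", {
  ratios <- c(0.05, 0.1, 0.2, 0.45, 1)
  fs <- 256
  n <- 128 * 100
  withr::with_seed(9, {
    phases <- runif(5, 0, 2 * pi)
    osc <- eegentropy:::rhythm_mixture(n, fs, phases)
    pink <- eegentropy:::pink_noise(n, fs)
    means <- sapply(ratios, function(rho) {
      x <- (osc + rho * pink) / sqrt(1 + rho^2)
      W <- matrix(x, 128)
      c(PEE = mean(apply(W, 2, permutation_entropy)),
        SVE = mean(apply(W, 2, svd_entropy)),
        APE = mean(apply(W, 2, approximate_entropy)),
        SAE = mean(apply(W, 2, sample_entropy)),
        SPE = mean(apply(W, 2, spectral_entropy, fs = fs)),
        CWE = mean(apply(W, 2, cwt_entropy, fs = fs)))
    })
    for (ms in rownames(means)) {
      expect_gte(cor(means[ms, ], seq_along(ratios), method = "spearman"),
                 0.9)
    }
  })
})

test_that("extract_features produces the windows-by-channels table", {
  cfg <- synth_config(n_trials_per_class = 1, trial_duration = 50, seed = 12)
  rec0 <- generate_session(cfg, "S01")
  rec1 <- eegentropy:::new_recording(rec0$subject_id, rec0$trials[1], rec0$fs,
                                     rec0$channel_names)
  ft <- extract_features(segment(rec1), "SAE")
  expect_equal(nrow(ft), 199)
  expect_length(feature_channels(ft), 8)
  vals <- as.matrix(ft[, feature_channels(ft)])
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  expect_identical(attr(ft, "measure"), "SAE")
})

test_that("undefined windows propagate as NA with a reported count", {
  sig <- matrix(rnorm(8 * 256), 8)
  sig[3, ] <- 0  # silent channel: spectral entropy undefined
  rec <- make_recording(list(sig), labels = "neutral",
                        channels = paste0("C", 1:8))
  segs <- segment(rec)
  expect_message(ft <- extract_features(segs, "SPE"), "undefined")
  expect_true(all(is.na(ft$C3)))
  expect_false(anyNA(ft$C1))
})

test_that("feature tables round-trip through delimited text with their config", {
  rec <- small_strong_session()
  segs <- segment(rec)
  ft <- extract_features(segs, "PEE")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(attr(back, "measure"), "PEE")
  expect_equal(as.data.frame(back)$T8, as.data.frame(ft)$T8, tolerance = 1e-12)
})
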