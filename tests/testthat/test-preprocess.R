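tone_recording <- function(freq, fs = 256, dur = 60) {
  t <- (0:(fs * dur - 1)) / fs
  make_recording(list(rbind(sin(2 * pi * freq * t))), fs = fs,
                 labels = "neutral", channels = "A")
}

test_that("band-pass rejects out-of-band tones and passes in-band tones", {
  rec60 <- tone_recording(60)
  out <- bandpass(rec60)
  expect_lte(sd(out$trials[[1]]$samples[1, ]) / sd(rec60$trials[[1]]$samples[1, ]),
             0.05)
  rec10 <- tone_recording(10)
  out10 <- bandpass(rec10)
  ratio <- sd(out10$trials[[1]]$samples[1, ]) / sd(rec10$trials[[1]]$samples[1, ])
  expect_lt(abs(ratio - 1), 0.05)
  expect_error(bandpass(rec10, low = 0), "Band edges")
  expect_error(bandpass(rec10, high = 128), "Band edges")
})

test_that("zero-phase filtering does not shift an in-band tone", {
  rec <- tone_recording(10)
  out <- bandpass(rec)
  x <- rec$trials[[1]]$samples[1, ]; y <- out$trials[[1]]$samples[1, ]
  int <- 2000:13000
  lag <- which.max(ccf(y[int], x[int], lag.max = 5, plot = FALSE)$acf) - 6
  expect_equal(lag, 0)
})

test_that("segmentation reproduces the study's window arithmetic", {
  cfg <- synth_config(n_trials_per_class = 1, trial_duration = 50, seed = 1,
                      channels = "T8", informative_channels = "T8")
  segs <- segment(generate_session(cfg, "S01"))
  expect_equal(nrow(segs$meta), 3 * 199)          # 199 windows per 50 s trial
  expect_equal(segs$window_samples, 128)
  expect_equal(segs$step_samples, 64)
  expect_equal(unique(segs$meta$label[segs$meta$trial == 1]),
               recording_labels(generate_session(cfg, "S01"))[1])
})

test_that("a trial exactly one window long yields one window; shorter errors", {
  rec <- make_recording(list(matrix(rnorm(128), 1)), labels = "neutral")
  segs <- segment(rec, window_s = 0.5)
  expect_equal(nrow(segs$meta), 1)
  rec_short <- make_recording(list(matrix(rnorm(100), 1)), labels = "neutral")
  expect_error(segment(rec_short, window_s = 0.5), "Trial 1")
})

test_that("window count matches a naive start-walking oracle", {
  withr::with_seed(11, {
    for (rep in 1:40) {
      n <- sample(64:2000, 1)
      w <- sample(16:64, 1) * 2
      overlap <- sample(c(0, 0.25, 0.5, 0.75), 1)
      s <- w * (1 - overlap)
      if (s != round(s) || n < w) next
      fs <- w * 2  # so window_s * fs = w
      rec <- make_recording(list(matrix(rnorm(n), 1)), fs = fs,
                            labels = "neutral")
      segs <- segment(rec, window_s = 0.5, overlap = overlap)
      expect_equal(nrow(segs$meta), naive_window_count(n, w, s))
      expect_equal(floor((n - w) / s) + 1, naive_window_count(n, w, s))
    }
  })
})

test_that("min-max normalization maps to [0,1] with the declared degenerate rule", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  x <- c(0, 0.2, 0.9, 1)
  expect_equal(minmax_normalize(x), x)
  expect_equal(minmax_normalize(minmax_normalize(c(-3, 1, 9))),
               minmax_normalize(c(-3, 1, 9)))
  withr::with_seed(2, {
    v <- rnorm(50)
    expect_equal(order(minmax_normalize(v)), order(v))
  })
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("Welch PSD locates tones and is flat for white noise", {
  fs <- 256; t <- (0:(fs * 60 - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(psd$frequency[which.max(psd$power)] - 10), 0.5)

  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t)
  psd2 <- welch_psd(two, fs)
  top2 <- psd2$frequency[order(psd2$power, decreasing = TRUE)[1:2]]
  expect_setequal(round(top2), c(10, 20))

  withr::with_seed(4, {
    for (i in 1:5) {
      psd_w <- welch_psd(rnorm(fs * 60), fs)
      sel <- psd_w$frequency >= 2 & psd_w$frequency <= 40
      expect_lte(max(psd_w$power[sel]) / min(psd_w$power[sel]), 10)
    }
  })
  expect_error(welch_psd(rnorm(100), fs, window_s = 1), "window needs")
})

test_that("alpha_peak finds the in-band maximum and flags flat spectra", {
  psd <- welch_psd(generate_resting_state("closed", 60, seed = 8)$trials[[1]]$samples[1, ],
                   256)
  pk <- alpha_peak(psd)
  expect_lt(abs(as.numeric(pk) - 10), 0.5)
  expect_false(attr(pk, "low_confidence"))
  withr::with_seed(6, {
    flat <- welch_psd(rnorm(256 * 60), 256)
    pk_flat <- alpha_peak(flat)
    expect_true(as.numeric(pk_flat) >= 8 && as.numeric(pk_flat) <= 13)
    expect_true(attr(pk_flat, "low_confidence"))
  })
  expect_error(alpha_peak(psd, band = c(200, 300)), "outside")
})
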