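# Synthetic EEG session generator.
#
# Emulates the acquisition protocol of an 8-channel wearable recorder:
# 30 trials (10 per emotion label) of 50 s at 256 Hz per subject-session.
# Each trial is a sum of band-limited neural-rhythm oscillations plus 1/f
# (pink) background noise; the emotion-class effect is injected as a
# class-dependent noise-to-oscillation ratio on a configurable subset of
# channels, so downstream entropy features respond to irregularity rather
# than amplitude.

# canonical EEG rhythm bands (Hz) with the center frequency and relative
# amplitude of the coherent oscillation emulating each band; weighted toward
# the slow rhythms (as in resting scalp EEG). The oscillatory component is a
# phase-coherent multi-sine, so it is far more regular than the 1/f
# background -- this is what gives the noise-to-oscillation ratio a graded,
# low-variance entropy response.
RHYTHM_BANDS <- data.frame(
  band  = c("delta", "theta", "alpha", "beta", "gamma"),
  low   = c(1, 4, 8, 13, 30),
  high  = c(4, 8, 13, 30, 45),
  center = c(2, 6, 10, 20, 36),
  weight = c(0.25, 0.25, 1.5, 0.1, 0.06)
)

#' Configuration for the synthetic EEG session generator
#'
#' Describes one emulated acquisition campaign: session structure (trials,
#' duration, sampling rate, montage) and the class-complexity model. The
#' emotion effect is parameterized as a noise-to-oscillation ratio per label:
#' a higher ratio yields a more irregular signal and therefore higher entropy
#' on the `informative_channels`; all other channels share `base_ratio` for
#' every label.
#'
#' @param n_subjects Number of subjects the campaign covers.
#' @param n_trials_per_class Trials per emotion label per session (default 10).
#' @param trial_duration Trial length in seconds (default 50).
#' @param fs Sampling rate in Hz (default 256). `trial_duration * fs` must be
#'   a whole number of samples.
#' @param channels Ordered electrode names (default the 8-channel frontal +
#'   temporal montage AF3, AF4, FT7, FT8, T7, T8, TP7, TP8).
#' @param class_complexity Named numeric vector mapping the three labels
#'   `negative`, `neutral`, `positive` to noise-to-oscillation ratios.
#' @param informative_channels Channels on which the class effect is applied
#'   (default `"T8"`); must be a subset of `channels`.
#' @param base_ratio Noise-to-oscillation ratio used on non-informative
#'   channels (and for every label when no effect is wanted).
#' @param amplitude Overall signal scale in microvolts (standard deviation of
#'   a trial before subject offsets).
#' @param subject_heterogeneity Log-normal sigma of per-subject multiplicative
#'   offsets applied to amplitude and noise ratio (0 disables them).
#' @param seed Integer seed; the whole campaign is a deterministic function
#'   of the configuration.
#'
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 42)
#' rec <- generate_session(cfg, subject_id = "S01")
#' rec
synth_config <- function(n_subjects = 8,
                         n_trials_per_class = 10,
                         trial_duration = 50,
                         fs = 256,
                         channels = EEG_CHANNELS,
                         class_complexity = c(negative = 0.2,
                                              neutral = 0.6,
                                              positive = 1.0),
                         informative_channels = "T8",
                         base_ratio = 0.6,
                         amplitude = 20,
                         subject_heterogeneity = 0.15,
                         seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a positive count.")
  }
  if (!is.numeric(n_trials_per_class) || n_trials_per_class < 1) {
    abort("`n_trials_per_class` must be a positive count.")
  }
  if (!is.numeric(trial_duration) || trial_duration <= 0) {
    abort("`trial_duration` must be positive (seconds).")
  }
  if (!is.numeric(fs) || fs <= 0) {
    abort("`fs` must be a positive sampling rate in Hz.")
  }
  n_samp <- trial_duration * fs
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    abort("`trial_duration * fs` must be an integer sample count.")
  }
  class_complexity <- unlist(class_complexity)
  if (!setequal(names(class_complexity), EMOTION_LABELS)) {
    abort("`class_complexity` must name exactly negative, neutral, positive.")
  }
  if (any(class_complexity < 0)) {
    abort("`class_complexity` ratios must be non-negative.")
  }
  if (!all(informative_channels %in% channels)) {
    abort("`informative_channels` must be a subset of `channels`.")
  }
  if (base_ratio < 0 || amplitude <= 0 || subject_heterogeneity < 0) {
    abort("`base_ratio`, `amplitude`, `subject_heterogeneity` must be valid.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_class = as.integer(n_trials_per_class),
      trial_duration = trial_duration,
      fs = fs,
      channels = as.character(channels),
      class_complexity = class_complexity[EMOTION_LABELS],
      informative_channels = as.character(informative_channels),
      base_ratio = base_ratio,
      amplitude = amplitude,
      subject_heterogeneity = subject_heterogeneity,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Strong class-effect preset
#'
#' Noise-to-oscillation ratios spanning oscillation-dominated to
#' noise-dominated regimes (log-spaced across two orders of magnitude), used
#' for parameter-recovery demonstrations where a clearly separable complexity
#' effect is wanted.
#'
#' @return Named numeric vector suitable for `class_complexity`.
#' @export
strong_class_effect <- function() {
  c(negative = 0.05, neutral = 0.5, positive = 5)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  subjects: %d, trials: 3 x %d x %gs @ %g Hz\n",
              x$n_subjects, x$n_trials_per_class, x$trial_duration, x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  class complexity (noise:oscillation): %s\n",
              paste(sprintf("%s=%g", names(x$class_complexity),
                            x$class_complexity), collapse = ", ")))
  cat(sprintf("  informative channels: %s (others at ratio %g)\n",
              paste(x$informative_channels, collapse = ", "), x$base_ratio))
  invisible(x)
}

# run code with a temporary RNG state so generators do not clobber the
# caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit stream seed for a subject within a campaign
subject_seed <- function(seed, subject_id) {
  key <- sum(utf8ToInt(as.character(subject_id)) *
               seq_along(utf8ToInt(as.character(subject_id)))) %% 99991L
  (abs(seed) %% 20000L) * 100000L + key
}

# spectrally shaped noise via random-phase synthesis: the amplitude spectrum
# is the deterministic target shape and only the phases are random. Every
# realization therefore has an identical spectral composition, so per-trial
# band-power fractions do not fluctuate and window statistics carry no
# trial-level random effect (important for treating windows as exchangeable
# observations in the electrode-selection ANOVA).
shaped_noise <- function(n, fs, gain_fun) {
  f <- seq_len(n) - 1L
  f <- pmin(f, n - f) * fs / n
  g <- gain_fun(f)
  g[1L] <- 0  # zero-mean
  half <- (n - 1L) %/% 2L
  phi <- runif(half, 0, 2 * pi)
  X <- complex(length.out = n)
  X[2:(half + 1L)] <- g[2:(half + 1L)] * exp(1i * phi)
  X[n:(n - half + 1L)] <- Conj(X[2:(half + 1L)])
  if (n %% 2L == 0L) {
    X[n / 2L + 1L] <- g[n / 2L + 1L] * (2L * (runif(1) < 0.5) - 1L)
  }
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s < .Machine$double.eps) rep(0, n) else y / s
}

pink_noise <- function(n, fs) {
  shaped_noise(n, fs, function(f) ifelse(f > 0, 1 / sqrt(f), 0))
}

# unit-SD coherent rhythm waveform: one sinusoid per band at its center
# frequency with the given phases (drawn once per subject-channel, so the
# waveform is a stable trait of a channel and window statistics stay
# exchangeable across trials)
rhythm_mixture <- function(n, fs, phases) {
  t <- (seq_len(n) - 1) / fs
  osc <- rep(0, n)
  for (i in seq_len(nrow(RHYTHM_BANDS))) {
    osc <- osc + RHYTHM_BANDS$weight[i] *
      sin(2 * pi * RHYTHM_BANDS$center[i] * t + phases[i])
  }
  osc / sqrt(sum(RHYTHM_BANDS$weight^2) / 2)
}

# one trial-channel: oscillation + ratio * pink noise, unit variance, scaled
synth_channel <- function(n, fs, ratio, amplitude, phases) {
  x <- rhythm_mixture(n, fs, phases) + ratio * pink_noise(n, fs)
  amplitude * x / sqrt(1 + ratio^2)
}

new_recording <- function(subject_id, trials, fs, channel_names) {
  structure(
    list(subject_id = subject_id, trials = trials, fs = fs,
         channel_names = channel_names),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  labs <- vapply(x$trials, `[[`, "", "label")
  ns <- vapply(x$trials, function(tr) ncol(tr$samples), 0L)
  cat("<eeg_recording>\n")
  cat(sprintf("  subject: %s | %d trials | %d channels @ %g Hz\n",
              x$subject_id, length(x$trials), length(x$channel_names), x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  cat(sprintf("  samples per trial: %s\n",
              paste(unique(ns), collapse = ", ")))
  invisible(x)
}

#' Trial labels of a recording
#' @param rec An `eeg_recording`.
#' @return Character vector of per-trial emotion labels.
#' @export
recording_labels <- function(rec) {
  vapply(rec$trials, `[[`, "", "label")
}

#' Generate one synthetic subject-session
#'
#' Produces `3 * n_trials_per_class` trials in randomized order. Every trial
#' is a sum of band-limited rhythm oscillations -- one coherent sinusoid per
#' canonical band (delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma
#' 30-45 Hz) at its center frequency, with phases drawn once per
#' subject-channel -- plus fresh 1/f (pink) noise per trial. On the
#' configured informative channels the noise-to-oscillation ratio follows
#' `class_complexity[label]` (higher ratio, higher irregularity, higher
#' entropy); elsewhere all labels share `base_ratio`, so window statistics
#' on non-informative channels are exchangeable across labels. Per-subject
#' log-normal offsets on amplitude and ratio are drawn once per subject,
#' making subjects heterogeneous for leave-one-subject-out experiments.
#' Deterministic for a fixed config and subject id.
#'
#' @param config A [synth_config()].
#' @param subject_id Subject identifier (used to derive the subject's RNG
#'   stream, so sessions are reproducible subject by subject).
#' @return An `eeg_recording`: list of trials (label + channels x time matrix
#'   in microvolts), sampling rate, channel names.
#' @export
generate_session <- function(config, subject_id = "S01") {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(round(config$trial_duration * config$fs))
  labels <- rep(EMOTION_LABELS, each = config$n_trials_per_class)
  with_local_seed(subject_seed(config$seed, subject_id), {
    labels <- sample(labels)
    amp_mult <- exp(rnorm(1, 0, config$subject_heterogeneity))
    ratio_mult <- exp(rnorm(1, 0, config$subject_heterogeneity))
    phases <- matrix(runif(length(config$channels) * nrow(RHYTHM_BANDS),
                           0, 2 * pi),
                     nrow = length(config$channels))
    informative <- config$channels %in% config$informative_channels
    trials <- lapply(labels, function(lab) {
      samples <- matrix(0, nrow = length(config$channels), ncol = n,
                        dimnames = list(config$channels, NULL))
      for (ci in seq_along(config$channels)) {
        ratio <- if (informative[ci]) config$class_complexity[[lab]]
                 else config$base_ratio
        samples[ci, ] <- synth_channel(n, config$fs, ratio * ratio_mult,
                                       config$amplitude * amp_mult,
                                       phases[ci, ])
      }
      list(label = lab, samples = samples)
    })
    new_recording(subject_id, trials, config$fs, config$channels)
  })
}

#' Generate a resting-state recording for device validation
#'
#' Emulates the classic eyes-closed / eyes-open alpha-blocking check over the
#' occipital electrodes O1 and O2: pink background noise plus a 10 Hz alpha
#' oscillation whose amplitude is strong with eyes closed and attenuated by a
#' factor 10 (100x in power) with eyes open.
#'
#' @param eyes `"closed"` or `"open"`.
#' @param duration Recording length in seconds; at least 4 s so a 1 s Welch
#'   window has segments to average.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param amplitude Microvolt scale of the background noise.
#' @return An `eeg_recording` with one unlabeled trial over channels O1, O2.
#' @export
generate_resting_state <- function(eyes = c("closed", "open"),
                                   duration = 60, fs = 256, seed = 1L,
                                   amplitude = 10) {
  eyes <- match.arg(eyes)
  if (!is.numeric(duration) || duration < 4) {
    abort("`duration` must be at least 4 s for a 1 s Welch window.")
  }
  if (fs <= 0) abort("`fs` must be positive.")
  n <- as.integer(round(duration * fs))
  alpha_amp <- if (eyes == "closed") 2 else 0.2
  with_local_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    samples <- t(vapply(c("O1", "O2"), function(ch) {
      phase <- runif(1, 0, 2 * pi)
      amplitude * (pink_noise(n, fs) +
                     alpha_amp * sqrt(2) * sin(2 * pi * 10 * t + phase))
    }, numeric(n)))
    rownames(samples) <- c("O1", "O2")
    new_recording(paste0("resting_", eyes),
                  list(list(label = eyes, samples = samples)),
                  fs, c("O1", "O2"))
  })
}
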