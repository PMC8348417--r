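# Preprocessing: zero-phase band-pass filtering, sliding-window segmentation,
# min-max normalization, and Welch spectral estimation for the resting-state
# alpha-peak device check.

#' Zero-phase band-pass filter a recording
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' so the magnitude response is squared and no phase shift is introduced.
#' The default order 6 keeps the 1-50 Hz pass band at unity gain while
#' attenuating a 60 Hz mains tone to under 5% RMS at fs = 256 Hz (lower
#' orders leave the stop band above that mark this close to the band edge).
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz (defaults 1-50, the usual broadband EEG
#'   cleanup band). Requires `0 < low < high < fs/2`.
#' @param order Butterworth order per pass.
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low = 1, high = 50, order = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort(sprintf("Band edges must satisfy 0 < low < high < fs/2 = %g Hz.", nyq))
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$trials <- lapply(rec$trials, function(tr) {
    tr$samples <- t(apply(tr$samples, 1, function(x)
      signal::filtfilt(bf, x)))
    tr
  })
  rec
}

#' Segment a recording into overlapping sliding windows
#'
#' Windows are half-open sample ranges `[start, start + w)`; window
#' arithmetic is done in sample counts so no float drift can change the
#' count. For a trial of `N` samples, each channel yields
#' `floor((N - w) / s) + 1` windows with step `s = w * (1 - overlap)`;
#' a partial tail is dropped. Each window inherits its trial's label.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds (default 0.5, i.e. 128 samples
#'   at 256 Hz).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return An `eeg_segments` object: per-channel `w x n_windows` matrices
#'   plus a window metadata tibble (`segment_id`, `trial`, `label`).
#' @export
segment <- function(rec, window_s = 0.5, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- window_s * rec$fs
  if (abs(w - round(w)) > 1e-9) {
    abort("`window_s * fs` must be an integer sample count.")
  }
  w <- as.integer(round(w))
  if (!(overlap >= 0 && overlap < 1)) abort("`overlap` must be in [0, 1).")
  s <- w * (1 - overlap)
  if (abs(s - round(s)) > 1e-9) {
    abort("Window step `w * (1 - overlap)` must be an integer sample count.")
  }
  s <- as.integer(round(s))
  if (s < 1) abort("Window step must be at least one sample.")

  starts_per_trial <- lapply(seq_along(rec$trials), function(ti) {
    n <- ncol(rec$trials[[ti]]$samples)
    if (n < w) {
      abort(sprintf("Trial %d has %d samples, shorter than one %d-sample window.",
                    ti, n, w))
    }
    seq(0L, n - w, by = s)
  })
  n_win <- vapply(starts_per_trial, length, 0L)
  labs <- recording_labels(rec)
  meta <- tibble::tibble(
    segment_id = seq_len(sum(n_win)),
    trial = rep(seq_along(rec$trials), n_win),
    label = rep(labs, n_win)
  )
  data <- lapply(seq_along(rec$channel_names), function(ci) {
    cols <- lapply(seq_along(rec$trials), function(ti) {
      x <- rec$trials[[ti]]$samples[ci, ]
      vapply(starts_per_trial[[ti]], function(st) x[(st + 1):(st + w)],
             numeric(w))
    })
    do.call(cbind, cols)
  })
  names(data) <- rec$channel_names
  structure(
    list(subject_id = rec$subject_id, fs = rec$fs,
         window_samples = w, step_samples = s,
         channels = rec$channel_names, meta = meta, data = data),
    class = "eeg_segments"
  )
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat("<eeg_segments>\n")
  cat(sprintf("  subject: %s | %d windows/channel x %d channels (%d total)\n",
              x$subject_id, nrow(x$meta), length(x$channels),
              nrow(x$meta) * length(x$channels)))
  cat(sprintf("  window: %d samples, step %d samples @ %g Hz\n",
              x$window_samples, x$step_samples, x$fs))
  invisible(x)
}

#' Min-max normalize a vector to [0, 1]
#'
#' Minimum maps to 0 and maximum to 1, preserving order; a constant vector
#' maps to all zeros (documented degenerate rule). Idempotent on inputs that
#' already attain 0 and 1.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) abort("Cannot normalize an empty vector.")
  if (all(is.na(values))) return(values)
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(rng[1])) return(values)
  span <- rng[2] - rng[1]
  if (span < .Machine$double.eps) {
    out <- rep(0, length(values))
    out[is.na(values)] <- NA_real_
    return(out)
  }
  (values - rng[1]) / span
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into `window_s`-second
#' segments with fractional `overlap`, each segment is mean-detrended,
#' Hann-tapered and its one-sided periodogram accumulated.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 1).
#' @param overlap Fractional overlap (default 0.5).
#' @return A `psd_estimate`: tibble-backed object with `frequency` (0 to
#'   fs/2) and `power` columns plus window metadata.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  L <- as.integer(round(window_s * fs))
  if (length(x) < L) {
    abort(sprintf("Signal has %d samples; a %g s window needs %d.",
                  length(x), window_s, L))
  }
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(0L, length(x) - L, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))  # Hann
  norm <- fs * sum(taper^2)
  acc <- numeric(L %/% 2 + 1)
  for (st in starts) {
    seg <- x[(st + 1):(st + L)]
    seg <- (seg - mean(seg)) * taper
    p <- abs(fft(seg))^2 / norm
    p <- p[seq_len(L %/% 2 + 1)]
    # fold two-sided density into one-sided (DC and Nyquist not doubled)
    p[2:(length(p) - 1)] <- 2 * p[2:(length(p) - 1)]
    acc <- acc + p
  }
  structure(
    list(frequency = (0:(L %/% 2)) * fs / L,
         power = acc / length(starts),
         fs = fs, window_s = window_s, overlap = overlap,
         n_segments = length(starts)),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%g Hz (%g s Hann windows, %d averaged)\n",
              length(x$frequency), max(x$frequency), x$window_s, x$n_segments))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.psd_estimate <- function(x, ...) {
  tibble::tibble(frequency = x$frequency, power = x$power)
}

#' Integrated band power of a PSD estimate
#'
#' @param psd A `psd_estimate`.
#' @param low,high Band edges in Hz (inclusive).
#' @return Power integrated over the band (trapezoid-free bin sum times bin
#'   width).
#' @export
band_power <- function(psd, low, high) {
  stopifnot(inherits(psd, "psd_estimate"))
  sel <- psd$frequency >= low & psd$frequency <= high
  if (!any(sel)) abort("Band contains no frequency bins.")
  df <- psd$frequency[2] - psd$frequency[1]
  sum(psd$power[sel]) * df
}

#' Dominant in-band spectral peak
#'
#' Frequency of maximum power inside a band, used as the eyes-closed alpha
#' check. The result carries a `low_confidence` attribute set when the peak
#' power is below 3x the in-band median (no clear peak, e.g. a flat
#' spectrum).
#'
#' @param psd A `psd_estimate`.
#' @param band Length-2 numeric band in Hz (default the alpha band, 8-13).
#' @return Peak frequency in Hz with attributes `peak_power` and
#'   `low_confidence`.
#' @export
alpha_peak <- function(psd, band = c(8, 13)) {
  stopifnot(inherits(psd, "psd_estimate"), length(band) == 2)
  sel <- psd$frequency >= band[1] & psd$frequency <= band[2]
  if (!any(sel)) {
    abort(sprintf("Band %g-%g Hz lies outside the frequency grid (0-%g Hz).",
                  band[1], band[2], max(psd$frequency)))
  }
  f <- psd$frequency[sel]
  p <- psd$power[sel]
  i <- which.max(p)
  structure(f[i],
            peak_power = p[i],
            low_confidence = p[i] < 3 * median(p))
}
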