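# Six entropy measures for short EEG windows.
#
# All measures quantify signal irregularity: low for regular/narrowband
# dynamics, high for broadband noise. Natural logarithm throughout;
# normalized variants divide by the log of the number of states so values
# land in [0, 1]. Defaults are community-standard choices sized to
# 128-sample windows.

# tolerance floor so (near-)constant windows do not divide by zero
r_floor <- function(x) 1e-12 * max(1, abs(mean(x)))

effective_r <- function(x, r, r_absolute) {
  if (r_absolute) return(max(r, r_floor(x)))
  max(r * sd(x), r_floor(x))
}

# delay-embedding matrix: rows are length-m lagged vectors
embed_delay <- function(x, m, tau) {
  n_pat <- length(x) - (m - 1) * tau
  idx <- outer(seq_len(n_pat), (0:(m - 1)) * tau, `+`)
  matrix(x[idx], nrow = n_pat)
}

# ordinal pattern codes for every row of an embedding matrix; ties broken by
# order of occurrence (earlier index ranks lower), vectorized across rows
ordinal_codes <- function(E) {
  m <- ncol(E)
  n <- nrow(E)
  ranks <- matrix(1L, n, m)
  for (k in seq_len(m)) {
    for (l in seq_len(m)) {
      if (l == k) next
      less <- E[, l] < E[, k] | (E[, l] == E[, k] & l < k)
      ranks[, k] <- ranks[, k] + less
    }
  }
  code <- rep(1L, n)
  for (k in seq_len(m)) code <- code + (ranks[, k] - 1L) * m^(k - 1)
  code
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) + 0  # + 0 avoids IEEE negative zero for pure states
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal (rank-order) patterns in
#' delay-embedded windows of the series. Zero for a monotone series (a
#' single pattern), maximal for a series whose patterns are equidistributed.
#' Ties are broken by order of occurrence (stable ranking), which matters on
#' quantized windows.
#'
#' @param x Numeric series of length at least `m * tau + 1`.
#' @param m Embedding order (default 3).
#' @param tau Embedding delay in samples (default 1).
#' @param normalize Divide by `log(m!)` so the result lies in `[0, 1]`.
#' @return Entropy in nats (or normalized).
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, normalize = TRUE) {
  if (m < 2 || tau < 1) abort("Require m >= 2 and tau >= 1.")
  if (length(x) < m * tau + 1) {
    abort(sprintf("Series of length %d too short for m = %d, tau = %d.",
                  length(x), m, tau))
  }
  codes <- ordinal_codes(embed_delay(x, m, tau))
  p <- tabulate(codes, nbins = m^m)
  h <- shannon(p / sum(p))
  if (normalize) h / log(factorial(m)) else h
}

#' Singular-value-decomposition entropy
#'
#' Shannon entropy of the singular-value spectrum of the delay-embedding
#' matrix, with singular values normalized to sum to one. Low for low-rank
#' (regular) dynamics -- a noiseless sinusoid embeds into a rank-2 plane --
#' and high for full-rank noise. The series is mean-centered before
#' embedding so the measure reflects fluctuation structure, not a baseline
#' offset.
#'
#' @inheritParams permutation_entropy
#' @param normalize Divide by `log(m)`.
#' @return Entropy in nats (or normalized).
#' @export
svd_entropy <- function(x, m = 3, tau = 1, normalize = TRUE) {
  if (m < 2 || tau < 1) abort("Require m >= 2 and tau >= 1.")
  if (length(x) < m * tau) {
    abort(sprintf("Series of length %d too short for m = %d, tau = %d.",
                  length(x), m, tau))
  }
  sv <- svd(embed_delay(x - mean(x), m, tau), nu = 0, nv = 0)$d
  if (sum(sv) < .Machine$double.eps) return(0)
  h <- shannon(sv / sum(sv))
  if (normalize) h / log(m) else h
}

#' Approximate entropy
#'
#' Pincus regularity statistic `phi_m - phi_{m+1}` with self-inclusive
#' Chebyshev-distance template matching. Near zero for regular series,
#' larger for unpredictable ones.
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param m Template length (default 2).
#' @param r Tolerance; a fraction of `sd(x)` unless `r_absolute`. Floored at
#'   a tiny positive value so constant windows are well defined.
#' @param r_absolute Interpret `r` as an absolute amplitude.
#' @return Approximate entropy in nats.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2, r_absolute = FALSE) {
  if (length(x) < m + 2) {
    abort(sprintf("Series of length %d too short for m = %d.", length(x), m))
  }
  rr <- effective_r(x, r, r_absolute)
  apen_phi(x, as.integer(m), rr) - apen_phi(x, as.integer(m) + 1L, rr)
}

#' Sample entropy
#'
#' Richman-Moorman statistic `-log(A / B)`: `B` counts template pairs
#' (`i < j`, self-matches excluded, both templates extendable) within
#' Chebyshev tolerance at length `m`, and `A` the same pairs still matching
#' at length `m + 1`. Returns `Inf` when `A = 0` (no extended match: the
#' statistic is a lower bound, flagged rather than fabricated) and `NA` when
#' `B = 0` (undefined).
#'
#' @inheritParams approximate_entropy
#' @return Sample entropy in nats, `Inf`, or `NA`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, r_absolute = FALSE) {
  if (length(x) < m + 2) {
    abort(sprintf("Series of length %d too short for m = %d.", length(x), m))
  }
  rr <- effective_r(x, r, r_absolute)
  ab <- sampen_counts(x, as.integer(m), rr)
  if (ab[2] == 0) return(NA_real_)
  if (ab[1] == 0) return(Inf)
  -log(ab[1] / ab[2]) + 0
}

#' Spectral entropy
#'
#' Shannon entropy of the power spectrum normalized to a probability
#' distribution over positive-frequency bins. Low for narrowband signals
#' (power concentrated in one bin), high for broadband noise.
#'
#' @param x Numeric series (length at least 8).
#' @param fs Sampling rate in Hz (used by the Welch estimator).
#' @param estimator `"fft"` (single periodogram over the window, default) or
#'   `"welch"` (averaged sub-window periodograms).
#' @param normalize Divide by the log of the number of bins.
#' @return Entropy in nats (or normalized); `NA` for an all-zero signal.
#' @export
spectral_entropy <- function(x, fs = 256, estimator = c("fft", "welch"),
                             normalize = TRUE) {
  estimator <- match.arg(estimator)
  if (length(x) < 8) abort("Series too short for spectral entropy (need >= 8).")
  if (all(x == 0)) return(NA_real_)
  if (estimator == "fft") {
    n <- length(x)
    p <- abs(fft(x))^2
    p <- p[2:(n %/% 2 + 1)]  # positive-frequency bins, DC excluded
  } else {
    L <- max(8L, 2^floor(log2(length(x) / 4)))
    psd <- welch_psd(x, fs, window_s = L / fs, overlap = 0.5)
    p <- psd$power[-1]
  }
  tot <- sum(p)
  if (tot < .Machine$double.eps) return(NA_real_)
  h <- shannon(p / tot)
  if (normalize) h / log(length(p)) else h
}

# FFT of the analytic Morlet wavelet at scale a on the length-n grid,
# L1-normalized (the scalogram convention: a pure tone responds with the
# same magnitude whichever scale matches it, so per-scale energies compare
# cleanly across frequencies)
morlet_hat <- function(n, a, omega0 = 10) {
  k <- 0:(n - 1)
  omega <- 2 * pi * k / n
  omega[k > n / 2] <- 0  # analytic: negative frequencies zeroed
  h <- pi^(-0.25) * exp(-(a * omega - omega0)^2 / 2)
  h[k > n / 2] <- 0
  h
}

cwt_scales_for <- function(fs, n_scales, freq_range, omega0 = 10) {
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                   length.out = n_scales))
  list(freqs = freqs, scales = omega0 * fs / (2 * pi * freqs))
}

#' Continuous-wavelet-transform entropy
#'
#' Morlet continuous wavelet transform over log-spaced analysis frequencies;
#' per-scale energies `E_j = sum_t |W(j, t)|^2` are normalized to a
#' probability distribution whose Shannon entropy is returned. Energy
#' concentrated on few scales (a tone) gives low entropy; broadband noise
#' spreads energy over all scales. Invariant to amplitude scaling. The
#' transform is computed in the frequency domain (circular convolution).
#'
#' @param x Numeric series (length at least 16).
#' @param fs Sampling rate in Hz.
#' @param n_scales Number of log-spaced analysis frequencies (default 32).
#' @param freq_range Analyzed frequency range in Hz (default 1-50); must lie
#'   inside `(0, fs/2)`.
#' @param normalize Divide by `log(n_scales)`.
#' @param omega0 Morlet center-frequency parameter (default 10, chosen so
#'   the 32-scale log grid resolves a pure tone to about two adjacent
#'   scales).
#' @return Entropy in nats (or normalized); `NA` for an all-zero signal.
#' @export
cwt_entropy <- function(x, fs = 256, n_scales = 32, freq_range = c(1, 50),
                        normalize = TRUE, omega0 = 10) {
  if (length(x) < 16) abort("Series too short for wavelet entropy (need >= 16).")
  if (freq_range[1] <= 0 || freq_range[2] >= fs / 2) {
    abort("`freq_range` must lie inside (0, fs/2).")
  }
  if (all(x == 0)) return(NA_real_)
  n <- length(x)
  sc <- cwt_scales_for(fs, n_scales, freq_range, omega0)
  xf <- fft(x)
  energy <- vapply(sc$scales, function(a) {
    w <- fft(xf * Conj(morlet_hat(n, a, omega0)), inverse = TRUE) / n
    sum(Mod(w)^2)
  }, 0)
  tot <- sum(energy)
  if (tot < .Machine$double.eps) return(NA_real_)
  h <- shannon(energy / tot)
  if (normalize) h / log(n_scales) else h
}

#' Entropy extraction configuration
#'
#' Bundles one measure tag with its hyperparameters. The underlying study
#' design never fixes these, so the defaults are standard choices for short
#' (128-sample) windows, all overridable.
#'
#' @param measure One of `"PEE"`, `"SVE"`, `"APE"`, `"SAE"`, `"SPE"`,
#'   `"CWE"` (permutation, SVD, approximate, sample, spectral, wavelet
#'   entropy).
#' @param m Embedding order / template length (PEE, SVE: 3; APE, SAE: 2).
#' @param tau Embedding delay in samples (PEE, SVE).
#' @param r Tolerance as a fraction of the window SD (APE, SAE).
#' @param normalize Report normalized values in `[0, 1]` where defined.
#' @param spe_estimator Spectrum estimator for SPE (`"fft"` or `"welch"`).
#' @param cwt_n_scales,cwt_freq_range Morlet scale grid for CWE.
#' @return An `entropy_config`.
#' @export
entropy_config <- function(measure = c("SAE", "PEE", "SVE", "APE", "SPE", "CWE"),
                           m = NULL, tau = 1, r = 0.2, normalize = TRUE,
                           spe_estimator = c("fft", "welch"),
                           cwt_n_scales = 32, cwt_freq_range = c(1, 50)) {
  measure <- match.arg(measure)
  if (is.null(m)) m <- if (measure %in% c("APE", "SAE")) 2 else 3
  if (m < 2 || tau < 1 || r <= 0) {
    abort("Require m >= 2, tau >= 1 and r > 0.")
  }
  structure(
    list(measure = measure, m = as.integer(m), tau = as.integer(tau), r = r,
         normalize = isTRUE(normalize),
         spe_estimator = match.arg(spe_estimator),
         cwt_n_scales = as.integer(cwt_n_scales),
         cwt_freq_range = cwt_freq_range),
    class = "entropy_config"
  )
}

#' @export
print.entropy_config <- function(x, ...) {
  cat(sprintf("<entropy_config> %s (m=%d, tau=%d, r=%g, normalize=%s)\n",
              x$measure, x$m, x$tau, x$r, x$normalize))
  invisible(x)
}

# entropy of every column of a windows matrix (w x n_windows) for one config
entropy_columns <- function(M, cfg, fs) {
  n_win <- ncol(M)
  switch(cfg$measure,
    PEE = vapply(seq_len(n_win), function(j)
      permutation_entropy(M[, j], cfg$m, cfg$tau, cfg$normalize), 0),
    SVE = vapply(seq_len(n_win), function(j)
      svd_entropy(M[, j], cfg$m, cfg$tau, cfg$normalize), 0),
    APE = vapply(seq_len(n_win), function(j)
      approximate_entropy(M[, j], cfg$m, cfg$r), 0),
    SAE = vapply(seq_len(n_win), function(j)
      sample_entropy(M[, j], cfg$m, cfg$r), 0),
    SPE = spectral_entropy_batch(M, fs, cfg),
    CWE = cwt_entropy_batch(M, fs, cfg)
  )
}

# batched single-periodogram spectral entropy across window columns
spectral_entropy_batch <- function(M, fs, cfg) {
  if (cfg$spe_estimator == "welch") {
    return(vapply(seq_len(ncol(M)), function(j)
      spectral_entropy(M[, j], fs, "welch", cfg$normalize), 0))
  }
  n <- nrow(M)
  P <- Mod(mvfft(M))^2
  P <- P[2:(n %/% 2 + 1), , drop = FALSE]
  tot <- colSums(P)
  out <- rep(NA_real_, ncol(M))
  ok <- tot > .Machine$double.eps
  if (any(ok)) {
    p <- sweep(P[, ok, drop = FALSE], 2, tot[ok], `/`)
    h <- -colSums(ifelse(p > 0, p * log(p), 0))
    out[ok] <- if (cfg$normalize) h / log(nrow(P)) else h
  }
  out
}

# batched Morlet wavelet entropy: one forward FFT per window, one inverse
# FFT per (scale, window-set)
cwt_entropy_batch <- function(M, fs, cfg) {
  n <- nrow(M)
  sc <- cwt_scales_for(fs, cfg$cwt_n_scales, cfg$cwt_freq_range)
  XF <- mvfft(M)
  E <- matrix(0, cfg$cwt_n_scales, ncol(M))
  for (j in seq_len(cfg$cwt_n_scales)) {
    H <- Conj(morlet_hat(n, sc$scales[j]))
    W <- mvfft(XF * H, inverse = TRUE) / n
    E[j, ] <- colSums(Mod(W)^2)
  }
  tot <- colSums(E)
  out <- rep(NA_real_, ncol(M))
  ok <- tot > .Machine$double.eps
  if (any(ok)) {
    p <- sweep(E[, ok, drop = FALSE], 2, tot[ok], `/`)
    h <- -colSums(ifelse(p > 0, p * log(p), 0))
    out[ok] <- if (cfg$normalize) h / log(cfg$cwt_n_scales) else h
  }
  out
}

#' Extract an entropy feature table from segmented EEG
#'
#' Applies one configured entropy measure to every (window, channel) pair,
#' yielding one scalar per channel per segment, then min-max normalizes each
#' channel column over all of this subject's segments (so features land in
#' `[0, 1]`). Undefined windows (all-zero, or sample entropy with no extended
#' template match) propagate as `NA` with a reported count.
#'
#' @param segs An `eeg_segments` object from [segment()].
#' @param cfg An [entropy_config()], or a measure tag string.
#' @param normalize_table Min-max normalize each channel column (default
#'   `TRUE`).
#' @return A `feature_table`: tibble with `segment_id`, `subject_id`,
#'   `trial`, `label` and one numeric column per channel; attributes
#'   `measure` and `normalized`.
#' @export
extract_features <- function(segs, cfg = entropy_config("SAE"),
                             normalize_table = TRUE) {
  stopifnot(inherits(segs, "eeg_segments"))
  if (is.character(cfg)) cfg <- entropy_config(cfg)
  stopifnot(inherits(cfg, "entropy_config"))
  vals <- lapply(segs$data, entropy_columns, cfg = cfg, fs = segs$fs)
  vals <- lapply(vals, function(v) {
    v[!is.finite(v)] <- NA_real_
    v
  })
  n_missing <- sum(vapply(vals, function(v) sum(is.na(v)), 0L))
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "extract_features: %d undefined window value(s) propagated as NA.",
      n_missing))
  }
  if (normalize_table) vals <- lapply(vals, minmax_normalize)
  out <- tibble::tibble(
    segment_id = segs$meta$segment_id,
    subject_id = segs$subject_id,
    trial = segs$meta$trial,
    label = segs$meta$label,
    !!!vals
  )
  new_feature_table(out, measure = cfg$measure, normalized = normalize_table)
}

new_feature_table <- function(tbl, measure, normalized) {
  structure(tbl,
            class = c("feature_table", class(tibble::tibble())),
            measure = measure, normalized = normalized)
}

#' Channel columns of a feature table
#' @param ft A `feature_table`.
#' @return Character vector of channel column names.
#' @export
feature_channels <- function(ft) {
  setdiff(names(ft), c("segment_id", "subject_id", "trial", "label"))
}

#' Write / read a feature table as delimited text
#'
#' The table itself is a CSV; the full entropy configuration travels in a
#' YAML sidecar (`<path>.meta.yaml`).
#'
#' @param ft A `feature_table`.
#' @param path CSV path.
#' @return `path` invisibly (`write_feature_table`); a `feature_table`
#'   (`read_feature_table`).
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  yaml::write_yaml(list(measure = attr(ft, "measure"),
                        normalized = attr(ft, "normalized")),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  tbl <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  new_feature_table(tbl, measure = meta$measure, normalized = meta$normalized)
}
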