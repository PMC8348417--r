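# Independent naive oracles: direct-definition implementations used only to
# cross-check the package's optimized paths.

# sample entropy by explicit double loop over template pairs
naive_sampen <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# approximate entropy by explicit self-inclusive match counting
naive_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    N <- n - mm + 1
    s <- 0
    for (i in 1:N) {
      c <- 0
      for (j in 1:N) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) c <- c + 1
      }
      s <- s + log(c / N)
    }
    s / N
  }
  phi(m) - phi(m + 1)
}

# permutation entropy by per-window rank patterns (ties: first occurrence)
naive_pe <- function(x, m, tau, normalize = TRUE) {
  n_pat <- length(x) - (m - 1) * tau
  pats <- character(n_pat)
  for (i in 1:n_pat) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(rank(v, ties.method = "first"), collapse = "")
  }
  p <- table(pats) / n_pat
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

# SVD entropy from an explicitly constructed embedding matrix (mean-centered
# series, matching the measure's definition)
naive_svdent <- function(x, m, tau, normalize = TRUE) {
  x <- x - mean(x)
  n_pat <- length(x) - (m - 1) * tau
  Y <- matrix(0, n_pat, m)
  for (i in 1:n_pat) Y[i, ] <- x[i + (0:(m - 1)) * tau]
  sv <- svd(Y)$d
  sv <- sv / sum(sv)
  sv <- sv[sv > 0]
  h <- -sum(sv * log(sv))
  if (normalize) h / log(m) else h
}

# spectral entropy from the raw periodogram bins
naive_spectral <- function(x, normalize = TRUE) {
  n <- length(x)
  p <- Mod(fft(x))^2
  p <- p[2:(n %/% 2 + 1)]
  p <- p / sum(p)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (normalize) h / log(n %/% 2) else h
}

# wavelet entropy via explicit O(n^2) circular convolution per scale
naive_cwt <- function(x, fs, n_scales = 32, freq_range = c(1, 50),
                      normalize = TRUE, omega0 = 10) {
  n <- length(x)
  sc <- eegentropy:::cwt_scales_for(fs, n_scales, freq_range, omega0)
  energy <- numeric(n_scales)
  for (j in seq_len(n_scales)) {
    H <- Conj(eegentropy:::morlet_hat(n, sc$scales[j], omega0))
    kern <- fft(H, inverse = TRUE) / n  # time-domain kernel
    W <- complex(length.out = n)
    for (t in 0:(n - 1)) {
      idx <- (t - (0:(n - 1))) %% n
      W[t + 1] <- sum(x * kern[idx + 1])
    }
    energy[j] <- sum(Mod(W)^2)
  }
  p <- energy / sum(energy)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  if (normalize) h / log(n_scales) else h
}

# one-way ANOVA F from the textbook sums of squares
naive_anova_f <- function(groups) {
  values <- unlist(groups)
  grand <- mean(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(values) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# max-statistic permutation analog of the Tukey adjustment: the adjusted p
# of a pair is the fraction of label permutations whose studentized range
# of group means exceeds that pair's observed studentized statistic
perm_tukey <- function(groups, B = 10000, seed = 1) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  nper <- lengths(groups)[1]
  qstat <- function(vals) {
    ms <- tapply(vals, g, mean)
    msw <- sum(tapply(vals, g, function(v) sum((v - mean(v))^2))) /
      (length(vals) - length(groups))
    list(range = (max(ms) - min(ms)) / sqrt(msw / nper),
         pairs = c(abs(ms[1] - ms[2]), abs(ms[1] - ms[3]),
                   abs(ms[2] - ms[3])) / sqrt(msw / nper))
  }
  obs <- qstat(values)
  withr::with_seed(seed, {
    exceed <- numeric(3)
    for (b in seq_len(B)) {
      qb <- qstat(values[sample(length(values))])$range
      exceed <- exceed + (qb >= obs$pairs)
    }
    exceed / B
  })
}

# window-count oracle: walk the starts
naive_window_count <- function(n, w, s) {
  count <- 0
  start <- 0
  while (start + w <= n) {
    count <- count + 1
    start <- start + s
  }
  count
}

make_recording <- function(signals, fs = 256, labels = NULL,
                           channels = NULL, subject = "SX") {
  # signals: list of channels x time matrices (one per trial)
  if (is.null(labels)) labels <- rep("neutral", length(signals))
  if (is.null(channels)) channels <- paste0("C", seq_len(nrow(signals[[1]])))
  trials <- lapply(seq_along(signals), function(i) {
    m <- signals[[i]]
    rownames(m) <- channels
    list(label = labels[i], samples = m)
  })
  eegentropy:::new_recording(subject, trials, fs, channels)
}

# small effect-bearing session shared across tests (memoised per test run)
small_strong_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_subjects = 1, trial_duration = 10,
                          n_trials_per_class = 6,
                          class_complexity = strong_class_effect(),
                          seed = 42)
      cache <<- bandpass(generate_session(cfg, "S01"))
    }
    cache
  }
})
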