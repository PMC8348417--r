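# Electrode selection by one-way ANOVA with Tukey HSD post-hoc tests.
#
# For each electrode, the channel's feature values are grouped by the three
# emotion labels; an electrode is adopted only when every pairwise contrast
# (negative-neutral, negative-positive, neutral-positive) is significant at
# the chosen level, i.e. all three Tukey-adjusted p-values are <= alpha
# (inclusive threshold). Windows are treated as independent observations;
# the within-trial autocorrelation this ignores is a documented caveat.

PAIR_COLUMNS <- c("p_neg_neu", "p_neg_pos", "p_neu_pos")

as_label_groups <- function(groups) {
  if (is.null(names(groups))) names(groups) <- EMOTION_LABELS
  if (!setequal(names(groups), EMOTION_LABELS)) {
    abort("Need exactly the three groups negative, neutral, positive.")
  }
  groups <- groups[EMOTION_LABELS]
  if (any(vapply(groups, length, 0L) < 2)) {
    abort("Each group needs at least 2 values.")
  }
  groups
}

#' One-way analysis of variance over three emotion groups
#'
#' Classical one-way F statistic with (k-1, N-k) degrees of freedom and its
#' upper-tail p-value. Zero total variance is reported as the degenerate
#' F = 0, p = 1; zero within-group variance with distinct means as F = Inf,
#' p = 0.
#'
#' @param groups Named list of three numeric vectors (`negative`, `neutral`,
#'   `positive`; unnamed lists are taken in that order).
#' @return A tibble with columns `statistic` (F), `p_value`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  groups <- as_label_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = EMOTION_LABELS)
  k <- 3L
  n <- length(values)
  sst <- sum((values - mean(values))^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  df1 <- k - 1L
  df2 <- n - k
  if (sst < 1e-24) {
    f <- 0; p <- 1
  } else if (ssw < 1e-24) {
    f <- Inf; p <- 0
  } else {
    ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
    f <- unname(ht$statistic); p <- unname(ht$p.value)
  }
  tibble::tibble(statistic = f, p_value = p, df1 = df1, df2 = df2)
}

#' Tukey HSD pairwise comparisons over three emotion groups
#'
#' Studentized-range-adjusted p-values for the three pairwise mean contrasts,
#' using the pooled within-group variance (via `stats::TukeyHSD` on a one-way
#' fit). p-values are clipped to `[1e-16, 1]`. Degenerate inputs follow
#' [anova_oneway()]: identical groups give all p = 1; zero within-group
#' variance gives p = 1 for coincident pairs and the clip floor otherwise.
#'
#' @inheritParams anova_oneway
#' @return A one-row tibble with columns `p_neg_neu`, `p_neg_pos`,
#'   `p_neu_pos`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_label_groups(groups)
  means <- vapply(groups, mean, 0)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  pair_idx <- list(p_neg_neu = c("negative", "neutral"),
                   p_neg_pos = c("negative", "positive"),
                   p_neu_pos = c("neutral", "positive"))
  if (ssw < 1e-24) {
    p <- vapply(pair_idx, function(pr)
      if (isTRUE(all.equal(means[[pr[1]]], means[[pr[2]]]))) 1 else 0, 0)
  } else {
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = EMOTION_LABELS)
    tk <- stats::TukeyHSD(stats::aov(values ~ g))$g
    lookup <- function(a, b) {
      rn <- rownames(tk)
      i <- match(paste0(b, "-", a), rn)
      if (is.na(i)) i <- match(paste0(a, "-", b), rn)
      tk[i, "p adj"]
    }
    p <- vapply(pair_idx, function(pr) lookup(pr[1], pr[2]), 0)
  }
  p <- pmin(pmax(p, 1e-16), 1)
  tibble::tibble(!!!as.list(p))
}

#' Electrode adopt/reject decision
#'
#' Adopt an electrode if and only if no pairwise contrast exceeds the
#' significance level: `max(p) <= alpha` (inclusive threshold). Monotone:
#' lowering any p-value can never flip adopt to reject.
#'
#' @param p Numeric vector of the three pairwise p-values, or a one-row data
#'   frame with columns `p_neg_neu`, `p_neg_pos`, `p_neu_pos`.
#' @param alpha Significance level (default 0.05).
#' @return `"adopt"` or `"reject"`.
#' @export
decide_electrode <- function(p, alpha = 0.05) {
  if (is.data.frame(p)) p <- unlist(p[1, PAIR_COLUMNS])
  p <- as.numeric(p)
  if (length(p) != 3 || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be three probabilities in [0, 1].")
  }
  if (max(p) <= alpha) "adopt" else "reject"
}

#' Select electrodes for one subject and one entropy measure
#'
#' Runs [anova_oneway()] and [tukey_hsd()] per channel on a feature table and
#' applies [decide_electrode()]. `NA` feature values (undefined windows) are
#' dropped channel-wise.
#'
#' @param ft A `feature_table` from [extract_features()].
#' @param alpha Significance level (default 0.05).
#' @return An `electrode_selection` tibble: one row per channel with the
#'   ANOVA F and p, the three Tukey-adjusted pairwise p-values, and the
#'   verdict (`"adopt"`/`"reject"`); attributes `subject_id`, `measure`,
#'   `alpha`.
#' @export
select_electrodes <- function(ft, alpha = 0.05) {
  stopifnot(is.data.frame(ft))
  if (!all(EMOTION_LABELS %in% ft$label)) {
    abort(sprintf("Feature table is missing label(s): %s.",
                  paste(setdiff(EMOTION_LABELS, unique(ft$label)),
                        collapse = ", ")))
  }
  channels <- feature_channels(ft)
  rows <- purrr::map_dfr(channels, function(ch) {
    vals <- ft[[ch]]
    keep <- !is.na(vals)
    groups <- split(vals[keep], factor(ft$label[keep], levels = EMOTION_LABELS))
    an <- anova_oneway(groups)
    tk <- tukey_hsd(groups)
    dplyr::bind_cols(
      tibble::tibble(channel = ch, f_statistic = an$statistic,
                     p_anova = an$p_value),
      tk,
      tibble::tibble(verdict = decide_electrode(tk, alpha))
    )
  })
  structure(rows,
            class = c("electrode_selection", class(tibble::tibble())),
            subject_id = ft$subject_id[1],
            measure = attr(ft, "measure"),
            alpha = alpha)
}

#' Adopted channels of a selection
#' @param selection An `electrode_selection`.
#' @return Character vector of adopted channel names (possibly empty).
#' @export
adopted_channels <- function(selection) {
  selection$channel[selection$verdict == "adopt"]
}

#' Cross-decision electrode adoption frequency
#'
#' Counts how often each electrode is adopted over a set of selection
#' decisions (subjects x measures) and ranks electrodes by adoption count.
#'
#' @param decisions A list of `electrode_selection` tibbles, or one tibble
#'   with columns `channel` and `verdict` (or logical `adopted`).
#' @return Tibble with `channel`, `n_adopted`, `n_decisions`, `rate`, sorted
#'   by decreasing adoption.
#' @export
selection_frequency <- function(decisions) {
  if (is.data.frame(decisions)) decisions <- list(decisions)
  if (length(decisions) == 0) abort("Need at least one selection decision.")
  long <- purrr::map_dfr(decisions, function(d) {
    adopted <- if ("adopted" %in% names(d)) as.logical(d$adopted)
               else d$verdict == "adopt"
    tibble::tibble(channel = d$channel, adopted = adopted)
  })
  long |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(n_adopted = sum(.data$adopted),
                     n_decisions = dplyr::n(),
                     rate = mean(.data$adopted), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_adopted))
}

#' Worked examples of the electrode-selection decision rule
#'
#' `example_selection_pvalues()` returns a reference worked example of the
#' per-electrode pairwise p-values (sample entropy, one subject) with the
#' published adopt/reject decisions, for exercising [decide_electrode()].
#' `example_selection_survey()` returns a reference survey of adopted
#' electrodes for six entropy measures across eight subjects in long format
#' (`subject`, `measure`, `electrode`, `channel`, `adopted`), for exercising
#' [selection_frequency()].
#'
#' @return A tibble (see above).
#' @export
example_selection_pvalues <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "selection_pvalues_worked_example.csv",
                package = "eegentropy"),
    check.names = FALSE))
}

#' @rdname example_selection_pvalues
#' @export
example_selection_survey <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "selection_survey_worked_example.csv",
                package = "eegentropy"),
    check.names = FALSE))
}
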