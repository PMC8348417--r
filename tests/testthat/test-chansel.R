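test_that("one-way ANOVA handles worked examples and degenerate inputs", {
  same <- list(negative = c(1, 2, 3), neutral = c(1, 2, 3),
               positive = c(1, 2, 3))
  an <- anova_oneway(same)
  expect_equal(an$statistic, 0)
  expect_equal(an$p_value, 1)

  # SSB = 4, SSW = 1.5, df = (2, 3) -> F = 4.0 by hand
  g <- list(negative = c(1, 2), neutral = c(2, 3), positive = c(3, 4))
  expect_equal(anova_oneway(g)$statistic, 4.0)

  degen <- list(negative = c(1, 1), neutral = c(2, 2), positive = c(3, 3))
  expect_lt(anova_oneway(degen)$p_value, 1e-12)
  expect_error(anova_oneway(list(negative = 1, neutral = 1:2, positive = 1:2)),
               "at least 2")
})

test_that("module ANOVA F equals the textbook sum-of-squares formula", {
  withr::with_seed(10, {
    for (i in 1:100) {
      g <- list(negative = rnorm(sample(3:20, 1), mean = runif(1, -1, 1)),
                neutral = rnorm(sample(3:20, 1), mean = runif(1, -1, 1)),
                positive = rnorm(sample(3:20, 1), mean = runif(1, -1, 1)))
      expect_equal(anova_oneway(g)$statistic, naive_anova_f(g),
                   tolerance = 1e-10)
    }
  })
})

test_that("Tukey HSD separates a shifted group and spares coincident ones", {
  same <- list(negative = c(1, 2, 3), neutral = c(1, 2, 3),
               positive = c(1, 2, 3))
  tk <- tukey_hsd(same)
  expect_equal(unlist(tk), c(p_neg_neu = 1, p_neg_pos = 1, p_neu_pos = 1))
  withr::with_seed(11, {
    p_null <- numeric(20)
    for (i in 1:20) {
      g <- list(negative = rnorm(30, 0, 0.1), neutral = rnorm(30, 0, 0.1),
                positive = rnorm(30, 5, 0.1))
      tk <- tukey_hsd(g)
      expect_lte(tk$p_neg_pos, 0.001)
      expect_lte(tk$p_neu_pos, 0.001)
      expect_gte(tk$p_neg_neu, 0.05)  # coincident pair never significant
      p_null[i] <- tk$p_neg_neu
    }
    expect_gte(mean(p_null), 0.5)
  })
})

test_that("Tukey p-values agree with a permutation studentized-range oracle", {
  withr::with_seed(12, {
    for (i in 1:3) {
      g <- list(negative = rnorm(10, 0), neutral = rnorm(10, 0.5),
                positive = rnorm(10, 1))
      tk <- unlist(tukey_hsd(g))
      po <- perm_tukey(g, B = 10000, seed = i)
      expect_true(all(abs(tk - po) <= 0.02))
    }
  })
})

test_that("Tukey pairwise p-values are super-uniform on exchangeable data", {
  withr::with_seed(13, {
    hits <- 0; total <- 0
    for (i in 1:300) {
      v <- rnorm(60)
      g <- split(v, rep(c("negative", "neutral", "positive"), each = 20))
      hits <- hits + sum(unlist(tukey_hsd(g)) <= 0.05)
      total <- total + 3
    }
    expect_lte(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
  })
})

test_that("the adopt/reject rule is inclusive at alpha and monotone", {
  expect_equal(decide_electrode(c(0.001, 0.8130, 0.001)), "reject")
  expect_equal(decide_electrode(c(0.001, 0.001, 0.001)), "adopt")
  expect_equal(decide_electrode(c(0.05, 0.05, 0.05)), "adopt")
  withr::with_seed(14, {
    for (i in 1:50) {
      p <- runif(3)
      v1 <- decide_electrode(p)
      p_lower <- p * runif(3)
      if (v1 == "adopt") expect_equal(decide_electrode(p_lower), "adopt")
    }
  })
  expect_error(decide_electrode(c(0.1, 0.2)), "three probabilities")
})

test_that("select_electrodes adopts the informative channel on effect data", {
  ft <- extract_features(segment(small_strong_session()), "SAE")
  sel <- select_electrodes(ft)
  expect_s3_class(sel, "electrode_selection")
  expect_true("T8" %in% adopted_channels(sel))
  expect_identical(sel$verdict,
                   ifelse(pmax(sel$p_neg_neu, sel$p_neg_pos, sel$p_neu_pos)
                          <= 0.05, "adopt", "reject"))
  ft_missing <- ft[ft$label != "neutral", ]
  attr(ft_missing, "measure") <- "SAE"
  expect_error(select_electrodes(ft_missing), "missing label")
})

test_that("the published decision column is reproduced from the printed p-values", {
  tbl <- example_selection_pvalues()
  verdicts <- vapply(seq_len(nrow(tbl)), function(i)
    decide_electrode(c(tbl$p_neg_neu[i], tbl$p_neg_pos[i], tbl$p_neu_pos[i])),
    "")
  expect_identical(verdicts, tbl$decision)
  expect_identical(verdicts,
                   rep(c("reject", "adopt"), 4))
})

test_that("selection frequency ranks T8 first on the published survey", {
  survey <- example_selection_survey()
  freq <- selection_frequency(survey)
  expect_identical(freq$channel[1], "T8")
  expect_equal(freq$n_adopted[1], 32)
  expect_equal(unique(freq$n_decisions), 48)

  one <- tibble::tibble(channel = c("A", "B"), verdict = c("adopt", "adopt"))
  expect_equal(selection_frequency(one)$n_adopted, c(1, 1))
  none <- tibble::tibble(channel = c("A", "B"), verdict = c("reject", "reject"))
  expect_equal(selection_frequency(none)$n_adopted, c(0, 0))
  expect_error(selection_frequency(list()), "at least one")
})
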