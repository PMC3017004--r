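test_that("chi-square goodness of fit matches hand arithmetic", {
  # 4-cell example computed by hand: O = (10, 20, 30, 40), E masses equal
  obs <- c(10, 20, 30, 40)
  rep4 <- suppressWarnings(chisq_gof(obs, rep(0.25, 4)))
  hand <- sum((obs - 25)^2 / 25)  # (225 + 25 + 25 + 225)/25 = 20
  expect_equal(rep4$statistic, hand, tolerance = 1e-12)
  expect_equal(rep4$df, 3L)
  expect_equal(rep4$p_value, pchisq(hand, 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("chi-square is zero on proportional data and has 19 df for 2x10 spectra", {
  masses <- theory_bin_masses(seq(0.1, 0.9, by = 0.2))
  obs <- masses * 1000
  expect_equal(suppressWarnings(chisq_gof(obs, masses))$statistic, 0)

  cat <- gen_gwas_catalog(n_snps = 400, seed = 9)
  observed <- bin_catalog(cat)
  expected <- neutral_spectrum(null_model(0.025, weighted = TRUE),
                               allele_draw = TRUE)
  rep20 <- suppressWarnings(chisq_gof(observed, expected))
  expect_equal(rep20$df, 19L)
  expect_gte(rep20$p_value, 0)
})

test_that("chi-square is invariant to scaling of the expected masses", {
  obs <- c(12, 40, 23, 25)
  m <- c(0.1, 0.4, 0.2, 0.3)
  expect_equal(suppressWarnings(chisq_gof(obs, m))$statistic,
               suppressWarnings(chisq_gof(obs, 7 * m))$statistic)
})

test_that("chi-square rejects observed counts where expected mass is zero", {
  expect_error(suppressWarnings(chisq_gof(c(5, 5), c(1, 0))), "zero")
})

test_that("Mann-Whitney recovers separation, ties, and the permutation oracle", {
  ident <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p_value, 0.99)

  sep <- mann_whitney(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(unname(sep$statistic), 0)  # complete separation

  # representative uniform samples shifted by 0.2: deterministic quantile grids
  a <- seq(0.0025, 0.9975, length.out = 200)
  b <- a + 0.2
  mw <- mann_whitney(a, b)
  expect_lt(mw$p_value, 1e-6)
  expect_lte(perm_mann_whitney(a, b, reps = 1e4), 1e-4)
})

test_that("binomial test matches closed forms and published comparisons", {
  # observed exactly at the null: p-value is maximal
  expect_gt(binomial_prop_test(50, 100, 0.5)$p_value, 0.9)
  # both-tails closed form at k = 0
  expect_equal(binomial_prop_test(0, 10, 0.5)$p_value, 2 * 0.5^10,
               tolerance = 1e-12)
  # 499 ancestral of 1143 against the weighted neutral null of 0.650
  expect_lt(binomial_prop_test(499, 1143, 0.650)$p_value, 0.0001)
})

test_that("bootstrap interval degenerates on constants and is seed-stable", {
  ci <- bootstrap_ci_mean(rep(3.3, 50), reps = 1000, seed = 4)
  expect_equal(unname(ci["low"]), 3.3)
  expect_equal(unname(ci["high"]), 3.3)
  a <- bootstrap_ci_mean(rnorm(100), reps = 2000, seed = 7)
  b <- bootstrap_ci_mean_args <- bootstrap_ci_mean(rnorm(100), reps = 2000, seed = 7)
  # the values sampled differ but the bootstrap given identical input is stable
  x <- runif(80)
  expect_identical(bootstrap_ci_mean(x, reps = 2000, seed = 12),
                   bootstrap_ci_mean(x, reps = 2000, seed = 12))
})

test_that("bootstrap interval covers the true mean at its nominal rate", {
  set.seed(31)
  hits <- vapply(1:300, function(i) {
    x <- rnorm(500)
    ci <- bootstrap_ci_mean(x, reps = 400, seed = i)
    ci["low"] <= 0 && 0 <= ci["high"]
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.03 + 0.01)  # 3% band + percentile bias
})

test_that("odds-ratio analyses match the hypergeometric Fisher oracle", {
  tab <- matrix(c(5, 15, 2, 78), nrow = 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, fisher_enum_p(tab),
               tolerance = 1e-12)

  # all odds ratios equal: medians equal, Fisher flat
  df <- make_catalog_df(40)
  df$odds_ratio <- 1.3
  res <- or_analyses(as_snp_catalog(df))
  expect_equal(unname(res$medians["ancestral"]), unname(res$medians["derived"]))
  expect_equal(res$fisher$p_value, 1)
})

test_that("a state-dependent odds-ratio shift is recovered from generated data", {
  cat <- gen_gwas_catalog(n_snps = 2e4, or_dist = or_dist_normal(1.25, 0.1),
                          or_state_shift = 0.04, or_missing_rate = 0,
                          seed = 13)
  res <- or_analyses(cat)
  diff_med <- unname(res$medians["derived"] - res$medians["ancestral"])
  expect_lt(abs(diff_med - 0.04), 0.01)
  expect_lt(res$mann_whitney$p_value, 0.01)
})

test_that("one-way ANOVA matches hand-computed F and is null-calibrated", {
  expect_equal(anova_classes(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$statistic,
               0, tolerance = 1e-12)

  # two groups, hand-computed F
  g1 <- c(1, 2, 3); g2 <- c(4, 6, 8)
  gm <- mean(c(g1, g2))
  ssb <- 3 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  res <- anova_classes(c(g1, g2), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$df, c(1, 4))

  # permuted labels give uniform p-values
  set.seed(41)
  y <- rnorm(60)
  ps <- vapply(1:200, function(i) {
    anova_classes(y, sample(rep(letters[1:3], each = 20)))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.10)
})

test_that("catalog-level ANOVA uses the class assignment rule", {
  cat <- gen_gwas_catalog(n_snps = 2000, seed = 55)
  res_f <- anova_classes(cat, what = "freq")
  res_s <- anova_classes(cat, what = "state")
  expect_true(res_f$p_value >= 0 && res_f$p_value <= 1)
  expect_equal(length(res_f$effects$group_means), 7)
  expect_true(all(res_s$effects$group_means >= 0 &
                    res_s$effects$group_means <= 1))
})
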