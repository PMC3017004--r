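test_that("power of the allelic test behaves at its boundaries", {
  dm <- detection_model()
  expect_equal(gwas_power(0.5, 1, dm), 5e-8)
  expect_equal(gwas_power(0.3, 1, dm), 5e-8)
  expect_equal(gwas_power(0, 1.5, dm), 5e-8)   # monomorphic: nothing to detect
  expect_equal(gwas_power(1, 1.5, dm), 5e-8)
  expect_gt(gwas_power(0.5, 2, dm), 0.999)
  expect_error(gwas_power(0.5, 0.8, dm), "fold")
  expect_error(gwas_power(1.2, 1.5, dm), "\\[0, 1\\]")
})

test_that("analytic power matches a Monte-Carlo simulation of the test", {
  dm <- detection_model()
  for (case in list(c(0.4, 1.25), c(0.2, 1.4), c(0.5, 1.25))) {
    ana <- gwas_power(case[1], case[2], dm)
    mc <- mc_power(case[1], case[2], reps = 1e4)
    se <- sqrt(max(ana * (1 - ana), 1e-6) / 1e4)
    expect_lt(abs(ana - mc), 3 * se + 0.005)
  }
  expect_equal(mc_power(0.5, 2, reps = 2000), 1, tolerance = 1e-3)
})

test_that("power is monotone in effect size and rises toward intermediate frequencies", {
  dm <- detection_model()
  ors <- seq(1, 2, by = 0.05)
  expect_true(all(diff(gwas_power(0.3, ors, dm)) >= 0))
  # monotone away from the boundary; the surface's maximum sits slightly
  # below x = 0.5 because the odds-ratio contrast is not exactly symmetric
  xs <- seq(0.02, 0.45, by = 0.01)
  expect_true(all(diff(gwas_power(xs, 1.3, dm)) >= 0))
  peak_region <- gwas_power(seq(0.4, 0.6, by = 0.005), 1.3, dm)
  expect_lt(max(peak_region) - gwas_power(0.5, 1.3, dm), 0.01)
})

test_that("relabeling alleles maps (x, or) to (1 - x, 1/or) with equal power", {
  dm <- detection_model()
  xs <- seq(0.05, 0.95, by = 0.05)
  for (or in c(1.1, 1.3, 1.8)) {
    expect_equal(gwasnull:::power_kernel(xs, or, dm),
                 gwasnull:::power_kernel(1 - xs, 1 / or, dm),
                 tolerance = 1e-12)
  }
})

test_that("low odds ratios are only detectable at intermediate frequencies", {
  dm <- detection_model()
  for (or in c(1.1, 1.3, 1.5)) {
    expect_lt(gwas_power(0.015, or, dm), 0.01)
    expect_lt(gwas_power(0.985, or, dm), 0.01)
  }
})

test_that("detection probability marginalizes correctly over effect sizes", {
  xg <- seq(0.05, 0.95, by = 0.05)
  dm_delta <- detection_model(or_dist = or_dist_delta(1.25))
  expect_equal(detection_probability(xg, dm_delta),
               gwas_power(xg, 1.25, dm_delta))

  dm_unif <- detection_model(or_dist = or_dist_uniform(1.0, 1.5))
  pu <- detection_probability(xg, dm_unif)
  expect_true(all(pu >= gwas_power(xg, 1, dm_unif) - 1e-12))
  expect_true(all(pu <= gwas_power(xg, 1.5, dm_unif) + 1e-12))

  # Gauss-Legendre marginal over the truncated normal matches Monte Carlo
  dm_norm <- detection_model(or_dist = or_dist_normal(1.25, 0.1))
  set.seed(3)
  draws <- sample_or(or_dist_normal(1.25, 0.1), 1e5)
  for (x in c(0.3, 0.5)) {
    pows <- gwas_power(x, draws, dm_norm)
    mc <- mean(pows)
    se <- sd(pows) / sqrt(length(pows))
    expect_lt(abs(detection_probability(x, dm_norm) - mc), 3 * se)
  }
})

test_that("uniform and truncated-normal detection profiles are similar and heterozygosity-shaped", {
  xg <- seq(0.01, 0.99, by = 0.01)
  pu <- detection_probability(xg, detection_model(or_dist = or_dist_uniform(1, 1.5)))
  pn <- detection_probability(xg, detection_model(or_dist = or_dist_normal(1.25, 0.1)))
  pd <- detection_probability(xg, detection_model(or_dist = or_dist_delta(1.25)))
  expect_lt(max(abs(pu - pn)), 0.15)
  sub <- xg >= 0.05 & xg <= 0.95
  for (p in list(pd, pu, pn)) {
    expect_gt(cor(p[sub], approx_detection(xg[sub])), 0.95)
  }
})

test_that("the heterozygosity approximation is 2x(1 - x)", {
  expect_equal(approx_detection(0.5), 0.5)
  expect_equal(approx_detection(0), 0)
  expect_equal(approx_detection(0.1), 0.18)
  expect_error(approx_detection(1.5), "\\[0, 1\\]")
})

test_that("truncated-normal odds-ratio draws never fall below one", {
  set.seed(8)
  draws <- sample_or(or_dist_normal(1.05, 0.2), 5000)
  expect_true(all(draws >= 1))
  expect_equal(length(draws), 5000)
})

test_that("r-squared follows the haplotype-frequency definition", {
  expect_equal(r_squared(0.3, 0.3, 1, 0), 1)           # perfect LD
  expect_equal(r_squared(0.3, 0.4, 0.4, 0.4), 0)       # independence
  expect_equal(r_squared(0.2, 0.4, 1, 0.25), 0.375)
  expect_error(r_squared(0.2, 0.5, 1, 0.25), "inconsistent")
  expect_error(r_squared(0.2, 1, 1, 1), "monomorphic")
})

test_that("spectrum reweighting matches the analytically weighted null", {
  m_unw <- null_model(0.025)
  m_w <- null_model(0.025, weighted = TRUE)
  # state-conditional spectra
  sp <- weight_spectrum(neutral_spectrum(m_unw), approx_detection)
  ref <- neutral_spectrum(m_w)
  expect_lt(max(abs(sp$mass - ref$mass)), 1e-6)
  # allele-draw spectra: weighting lowers the ancestral share from 0.741 to 0.650
  spd <- neutral_spectrum(m_unw, allele_draw = TRUE)
  spdw <- weight_spectrum(spd, approx_detection)
  refd <- neutral_spectrum(m_w, allele_draw = TRUE)
  expect_lt(max(abs(spdw$mass - refd$mass)), 1e-6)
  expect_lt(state_shares(spdw)["ancestral"], state_shares(spd)["ancestral"])
})

test_that("a constant weight leaves a spectrum unchanged", {
  sp <- neutral_spectrum(null_model(0.025))
  expect_equal(weight_spectrum(sp, function(x) 0.7)$mass, sp$mass,
               tolerance = 1e-10)
  # empirical spectrum without attached densities: midpoint weighting
  emp <- binned_spectrum(c(0, 0.5), c(0.5, 1), c("derived", "ancestral"),
                         c(0.4, 0.6))
  expect_equal(weight_spectrum(emp, function(x) 2)$mass, emp$mass)
})
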