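# Independent oracles used to cross-check the package's closed forms and
# test kernels. These deliberately avoid the code paths they verify.

# P(ancestral, unweighted): ratio of integrals of x/(1-x) and 1/(1-x)
quad_prob_anc_unweighted <- function(d) {
  num <- integrate(function(x) x / (1 - x), d, 1 - d, rel.tol = 1e-12)$value
  den <- integrate(function(x) 1 / (1 - x), d, 1 - d, rel.tol = 1e-12)$value
  num / den
}

# P(ancestral, weighted): ratio of integrals of 2x^2 and 2x
quad_prob_anc_weighted <- function(d) {
  num <- integrate(function(x) 2 * x^2, d, 1 - d, rel.tol = 1e-12)$value
  den <- integrate(function(x) 2 * x, d, 1 - d, rel.tol = 1e-12)$value
  num / den
}

# two-sided permutation p-value for the rank-sum statistic
perm_mann_whitney <- function(a, b, reps = 1e4, seed = 99) {
  set.seed(seed)
  pooled <- c(a, b)
  n_a <- length(a)
  obs <- sum(rank(pooled)[seq_len(n_a)])
  perm <- replicate(reps, {
    r <- rank(pooled)[sample.int(length(pooled))]
    sum(r[seq_len(n_a)])
  })
  mu <- n_a * (length(pooled) + 1) / 2
  mean(abs(perm - mu) >= abs(obs - mu) - 1e-9)
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  row1 <- sum(tab[1, ]); col1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, row1 + col1 - n):min(row1, col1)
  probs <- dhyper(support, col1, n - col1, row1)
  p_obs <- dhyper(a, col1, n - col1, row1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo power of the allelic two-proportion test under the
# multiplicative disease model
mc_power <- function(x, or, n_cases = 2500, n_controls = 2500, alpha = 5e-8,
                     reps = 1e4, seed = 11) {
  set.seed(seed)
  p1 <- or * x / (1 + x * (or - 1))
  m1 <- 2 * n_cases; m0 <- 2 * n_controls
  k1 <- rbinom(reps, m1, p1); k0 <- rbinom(reps, m0, x)
  ph1 <- k1 / m1; ph0 <- k0 / m0
  pb <- (k1 + k0) / (m1 + m0)
  se <- sqrt(pb * (1 - pb) * (1 / m1 + 1 / m0))
  z <- abs(ph1 - ph0) / se
  mean(z > qnorm(1 - alpha / 2), na.rm = TRUE)
}

# small synthetic catalog data frame for I/O tests
make_catalog_df <- function(n = 50, seed = 5) {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("rs%05d", seq_len(n)),
    risk_freq = round(runif(n, 0.05, 0.95), 4),
    state = sample(c("ancestral", "derived"), n, replace = TRUE),
    odds_ratio = round(runif(n, 1, 2), 3),
    p_value = 10^-round(runif(n, 5, 12), 2),
    classes = sample(c("cancer", "neurological", "cancer;metabolism"),
                     n, replace = TRUE),
    platform = sample(c("affymetrix", "illumina"), n, replace = TRUE),
    n_genotyped_band = "<500k",
    pub_half_year = "2008H1",
    non_european = FALSE,
    n_studies = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
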