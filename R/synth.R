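#' Synthetic control SNP panel
#'
#' Draws derived-allele frequencies from the truncated `1/x` neutral law via
#' its closed-form quantile `x = d ((1-d)/d)^u`, `u ~ Uniform(0, 1)`, and
#' optionally thins low-minor-allele-frequency sites to emulate the
#' ascertainment bias of SNP panels discovered from small samples.
#'
#' @param n_snps Number of panel SNPs.
#' @param d Polymorphism threshold (default 0.025).
#' @param ascertainment_depletion Acceptance probability applied to draws with
#'   minor allele frequency below 0.1, in `[0, 1]`; 1 (default) keeps the pure
#'   `1/x` law, 0 removes all MAF < 0.1 sites.
#' @param seed Integer seed; panels are deterministic given the seed.
#' @return A [snp_panel()].
#' @examples
#' panel <- gen_panel(100, seed = 1)
#' range(panel$derived_freq)
#' @export
gen_panel <- function(n_snps, d = 0.025, ascertainment_depletion = 1,
                      seed = 1) {
  check_threshold(d)
  stopifnot(n_snps >= 1, ascertainment_depletion >= 0,
            ascertainment_depletion <= 1)
  set.seed(seed)
  z <- numeric(0)
  while (length(z) < n_snps) {
    draw <- d * ((1 - d) / d)^stats::runif(n_snps)
    maf <- pmin(draw, 1 - draw)
    keep <- maf >= 0.1 | stats::runif(n_snps) < ascertainment_depletion
    z <- c(z, draw[keep])
  }
  snp_panel(sprintf("panel_snp_%06d", seq_len(n_snps)), z[seq_len(n_snps)])
}

# Quadrature helpers over the detection-weighted truncated null ------------

# density of the SNP derived frequency for a given detection rule
synth_z_density <- function(d, detection) {
  base <- function(z) 1 / z
  w <- if (identical(detection, "eq6")) function(z) 2 * z * (1 - z)
       else if (identical(detection, "none")) function(z) 1
       else if (inherits(detection, "detection_model"))
         function(z) detection_probability(z, detection)
       else stop("detection must be 'eq6', 'none', or a detection_model",
                 call. = FALSE)
  norm <- stats::integrate(function(z) base(z) * w(z), d, 1 - d,
                           rel.tol = 1e-10)$value
  function(z) base(z) * w(z) / norm
}

# Solve the logistic state tilt P(derived risk | z) = plogis(a - b(2z - 1))
# so that E[pi] = 1 - target_prop_anc and, when target_mean is given,
# E[pi z + (1 - pi)(1 - z)] = target_mean. Returns c(a, b).
calibrate_state_tilt <- function(target_prop_anc, target_mean, dens, d) {
  stopifnot(target_prop_anc > 0, target_prop_anc < 1)
  p_der <- 1 - target_prop_anc
  e_pi <- function(a, b) stats::integrate(
    function(z) stats::plogis(a - b * (2 * z - 1)) * dens(z),
    d, 1 - d, rel.tol = 1e-10)$value
  solve_a <- function(b) stats::uniroot(
    function(a) e_pi(a, b) - p_der, c(-(abs(b) + 40), abs(b) + 40),
    tol = 1e-12)$root
  if (is.null(target_mean)) return(c(a = solve_a(0), b = 0))
  e_mean <- function(a, b) stats::integrate(
    function(z) {
      pi_z <- stats::plogis(a - b * (2 * z - 1))
      (pi_z * z + (1 - pi_z) * (1 - z)) * dens(z)
    }, d, 1 - d, rel.tol = 1e-10)$value
  gap <- function(b) e_mean(solve_a(b), b) - target_mean
  # mean is monotone decreasing in the tilt strength b
  b <- stats::uniroot(gap, c(-50, 300), tol = 1e-10, extendInt = "no")$root
  c(a = solve_a(b), b = b)
}

#' Synthetic GWAS-like disease-SNP catalog
#'
#' Generates a catalog with the statistical structure the analysis assumes:
#' SNP derived frequencies are drawn from the truncated `1/x` neutral law and
#' accepted with probability proportional to a detection weight; the risk
#' allele at each SNP is the derived allele with probability
#' `plogis(a - b(2z - 1))`, where `(a, b)` are calibrated by quadrature so the
#' catalog's expected proportion of ancestral risk alleles, and optionally its
#' expected mean risk-allele frequency, match the requested targets; recorded
#' states are then flipped at the mislabeling rate. Defaults reproduce the
#' marginals of the empirical catalog the package models: 1143 SNPs,
#' proportion ancestral 0.437, mean risk frequency 0.394, point-mass odds
#' ratio 1.25 available for 530/1143 of records, 92/1143 non-European,
#' 142/1143 replicated, and seven phenotypic classes with the empirical
#' weights.
#'
#' @param n_snps Number of records (default 1143).
#' @param d Polymorphism threshold (default 0.025).
#' @param or_dist Odds-ratio distribution (default point mass at 1.25).
#' @param detection `"eq6"` (accept with probability proportional to
#'   `2z(1 - z)`; default), `"none"`, or a [detection_model()].
#' @param mislabel_rate Probability of flipping the recorded
#'   ancestral/derived label, in `[0, 0.5)`.
#' @param target_prop_ancestral Expected share of ancestral risk alleles;
#'   `NULL` means the risk allele is a frequency-weighted random allele
#'   (derived with probability `z`), which recovers the detection-weighted
#'   null spectrum.
#' @param target_mean_freq Expected mean risk-allele frequency (requires
#'   `target_prop_ancestral`); `NULL` leaves the frequency untargeted.
#' @param or_missing_rate Share of records without odds-ratio data
#'   (default `1 - 530/1143`).
#' @param or_state_shift Additive shift applied to derived-allele odds ratios
#'   (default 0); used to build state-dependent effect sizes.
#' @param class_weights Named weights over phenotypic classes; the
#'   `"multiple"` class receives two distinct classes.
#' @param replicated_rate,non_european_rate Metadata rates.
#' @param seed Integer seed.
#' @return A `snp_catalog`.
#' @export
gen_gwas_catalog <- function(n_snps = 1143, d = 0.025,
                             or_dist = or_dist_delta(1.25),
                             detection = "eq6",
                             mislabel_rate = 0,
                             target_prop_ancestral = 0.437,
                             target_mean_freq = 0.394,
                             or_missing_rate = 1 - 530 / 1143,
                             or_state_shift = 0,
                             class_weights = c(cancer = 112,
                                               cardiovascular = 145,
                                               metabolism = 160,
                                               "miscellaneous disease" = 290,
                                               morphological = 276,
                                               neurological = 135,
                                               multiple = 25),
                             replicated_rate = 142 / 1143,
                             non_european_rate = 92 / 1143,
                             seed = 1) {
  check_threshold(d)
  stopifnot(n_snps >= 1, inherits(or_dist, "or_dist"),
            mislabel_rate >= 0, mislabel_rate < 0.5)
  if (!is.null(target_mean_freq) && is.null(target_prop_ancestral))
    stop("target_mean_freq requires target_prop_ancestral", call. = FALSE)

  # calibrate before touching the RNG so the seed governs draws only
  tilt <- if (!is.null(target_prop_ancestral)) {
    dens <- synth_z_density(d, detection)
    calibrate_state_tilt(target_prop_ancestral, target_mean_freq, dens, d)
  } else NULL

  set.seed(seed)
  # detection weight and rejection envelope
  wfun <- if (identical(detection, "eq6")) function(z) 2 * z * (1 - z)
          else if (identical(detection, "none")) function(z) rep(1, length(z))
          else function(z) detection_probability(z, detection)
  wmax <- max(wfun(seq(d, 1 - d, length.out = 501)))
  z <- numeric(0)
  while (length(z) < n_snps) {
    draw <- d * ((1 - d) / d)^stats::runif(n_snps)
    keep <- stats::runif(n_snps) < wfun(draw) / wmax
    z <- c(z, draw[keep])
  }
  z <- z[seq_len(n_snps)]

  p_derived <- if (is.null(tilt)) z
               else stats::plogis(tilt["a"] - tilt["b"] * (2 * z - 1))
  derived <- stats::runif(n_snps) < p_derived
  state <- ifelse(derived, "derived", "ancestral")
  risk_freq <- ifelse(derived, z, 1 - z)
  if (mislabel_rate > 0) {
    flip <- stats::runif(n_snps) < mislabel_rate
    state[flip] <- ifelse(state[flip] == "derived", "ancestral", "derived")
  }

  odds_ratio <- sample_or(or_dist, n_snps) +
    ifelse(state == "derived", or_state_shift, 0)
  odds_ratio[stats::runif(n_snps) < or_missing_rate] <- NA_real_

  singles <- setdiff(names(class_weights), "multiple")
  lab <- sample(names(class_weights), n_snps, replace = TRUE,
                prob = class_weights / sum(class_weights))
  classes <- vapply(lab, function(l) {
    if (l == "multiple") paste(sort(sample(singles, 2)), collapse = ";") else l
  }, character(1))

  catalog <- data.frame(
    snp_id = sprintf("synth_snp_%06d", seq_len(n_snps)),
    risk_freq = risk_freq,
    state = state,
    odds_ratio = odds_ratio,
    p_value = 10^-stats::runif(n_snps, 5, 40),
    classes = classes,
    platform = sample(c("affymetrix", "illumina", "perlegen", "multiple"),
                      n_snps, replace = TRUE,
                      prob = c(638, 852, 90, 430)),
    n_genotyped_band = sample(c("<500k", "500k-1M", ">1M"), n_snps,
                              replace = TRUE, prob = c(597, 205, 322)),
    pub_half_year = sample(paste0(rep(2005:2009, each = 2), c("H1", "H2")),
                           n_snps, replace = TRUE),
    non_european = stats::runif(n_snps) < non_european_rate,
    n_studies = 1L + stats::rbinom(n_snps, 1L, replicated_rate),
    stringsAsFactors = FALSE
  )
  out <- as_snp_catalog(catalog)
  attr(out, "generator") <- list(seed = seed, d = d, detection =
                                   if (is.character(detection)) detection
                                   else "detection_model",
                                 mislabel_rate = mislabel_rate,
                                 target_prop_ancestral = target_prop_ancestral,
                                 target_mean_freq = target_mean_freq,
                                 tilt = tilt)
  out
}
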