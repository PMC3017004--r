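#' Comparison reports
#'
#' Lightweight container for the outcome of one statistical test: name,
#' statistic, degrees of freedom where applicable, p-value, group sizes and
#' any effect summaries.
#'
#' @param test Test name.
#' @param statistic Test statistic (may be `NA`).
#' @param df Degrees of freedom (or `NA`).
#' @param p_value P-value in `[0, 1]` (or `NA`).
#' @param n Sample size(s).
#' @param ... Further named effect summaries.
#' @param detail Optional data frame of per-cell / per-group detail.
#' @return Object of class `comparison_report`.
#' @export
comparison_report <- function(test, statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, n = NA_real_, ...,
                              detail = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]", call. = FALSE)
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, n = n, effects = list(...),
                 detail = detail),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(x$test, "\n")
  if (!all(is.na(x$statistic)))
    cat("  statistic:", format(x$statistic, digits = 6),
        if (!all(is.na(x$df))) paste0("(df = ", paste(x$df, collapse = ", "), ")"),
        "\n")
  if (!all(is.na(x$p_value))) cat("  p-value:", format(x$p_value, digits = 4), "\n")
  for (nm in names(x$effects))
    cat("  ", nm, ": ", paste(format(x$effects[[nm]], digits = 5),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Chi-square goodness of fit between an observed and an expected spectrum
#'
#' Observed counts per cell against expected masses, with `cells - 1` degrees
#' of freedom; for the standard 10-bin two-state spectra this is 19 df.
#' Expected masses are renormalized internally, so the statistic is invariant
#' to their scaling. Cells with expected count below 5 trigger a warning but
#' are not merged.
#'
#' @param observed A [binned_spectrum()] carrying counts, or a numeric vector
#'   of counts.
#' @param expected A [binned_spectrum()] with the same cell structure, or a
#'   numeric vector of masses.
#' @return A `comparison_report`.
#' @export
chisq_gof <- function(observed, expected) {
  if (inherits(observed, "binned_spectrum")) {
    if (all(is.na(observed$count)))
      stop("observed spectrum carries no counts; the observed side must be counts",
           call. = FALSE)
    obs <- observed$count
  } else obs <- as.numeric(observed)
  if (inherits(expected, "binned_spectrum")) {
    if (inherits(observed, "binned_spectrum") &&
        !(all(observed$bin_low == expected$bin_low) &&
          all(observed$state == expected$state)))
      stop("observed and expected spectra have different cell structure",
           call. = FALSE)
    exp_mass <- expected$mass
  } else exp_mass <- as.numeric(expected)
  if (length(obs) != length(exp_mass))
    stop("observed and expected must have the same number of cells", call. = FALSE)
  exp_mass <- exp_mass / sum(exp_mass)
  n <- sum(obs)
  if (any(exp_mass == 0 & obs > 0))
    stop(paste("expected mass is zero in a cell with observed counts;",
               "restrict both spectra to [d, 1 - d] before comparing"),
         call. = FALSE)
  keep <- exp_mass > 0
  e <- n * exp_mass[keep]
  if (any(e < 5))
    warning(sum(e < 5), " cell(s) have expected count < 5; chi-square may be inaccurate")
  stat <- sum((obs[keep] - e)^2 / e)
  df <- length(obs) - 1L
  comparison_report("chi-square goodness of fit", statistic = stat, df = df,
                    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                    n = n)
}

#' Mann-Whitney U test for two frequency samples
#'
#' Two-sided rank-sum test via [stats::wilcox.test()], using the normal
#' approximation with tie correction by default (sample sizes here are
#' typically in the hundreds); set `exact = TRUE` for small samples.
#'
#' @param a,b Numeric samples.
#' @param exact Use the exact distribution (no ties, small n)?
#' @return A `comparison_report` with the U statistic for sample `a`.
#' @export
mann_whitney <- function(a, b, exact = FALSE) {
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  comparison_report("Mann-Whitney U (two-sided)",
                    statistic = unname(wt$statistic),
                    p_value = wt$p.value, n = c(length(a), length(b)),
                    median_a = stats::median(a), median_b = stats::median(b))
}

#' Exact binomial test of a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null proportion.
#' @return A `comparison_report` (two-sided exact p-value).
#' @export
binomial_prop_test <- function(k, n, p0) {
  bt <- stats::binom.test(k, n, p0)
  comparison_report("exact binomial test (two-sided)", statistic = k,
                    p_value = bt$p.value, n = n,
                    proportion = k / n, null_proportion = p0)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples with replacement, deterministic given the seed.
#'
#' @param values Numeric sample.
#' @param reps Bootstrap replicates (default 1e5).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(low, high)` with attributes `mean`,
#'   `reps`, `seed`.
#' @export
bootstrap_ci_mean <- function(values, reps = 1e5, level = 0.95, seed = 1) {
  stopifnot(length(values) >= 1, reps >= 1, level > 0, level < 1)
  set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(reps),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  structure(c(low = ci[1], high = ci[2]), mean = mean(values),
            reps = reps, seed = seed)
}

#' Odds-ratio analyses by allelic state and minor-allele frequency
#'
#' For the subset of records with odds-ratio data: medians by ancestral vs
#' derived state with a Mann-Whitney comparison, and Fisher's exact test of
#' the 2x2 table (minor allele frequency <= `maf_cut`) x (odds ratio >
#' `or_cut`). MAF is `min(risk_freq, 1 - risk_freq)`.
#'
#' @param catalog A `snp_catalog`.
#' @param maf_cut MAF threshold (default 0.2).
#' @param or_cut Odds-ratio threshold (default 2).
#' @return List with `medians` (named vector), `mann_whitney`
#'   (`comparison_report`), `fisher` (`comparison_report` with the table),
#'   and `prop_or_gt` (share of OR > `or_cut` within each MAF stratum).
#' @export
or_analyses <- function(catalog, maf_cut = 0.2, or_cut = 2) {
  stopifnot(inherits(catalog, "snp_catalog"))
  has_or <- !is.na(catalog$odds_ratio)
  if (!any(has_or)) stop("no odds-ratio data in catalog", call. = FALSE)
  cc <- catalog[has_or, , drop = FALSE]
  medians <- tapply(cc$odds_ratio, factor(cc$state, c("ancestral", "derived")),
                    stats::median)
  mw <- mann_whitney(cc$odds_ratio[cc$state == "ancestral"],
                     cc$odds_ratio[cc$state == "derived"])
  maf <- pmin(cc$risk_freq, 1 - cc$risk_freq)
  low <- maf <= maf_cut
  high_or <- cc$odds_ratio > or_cut
  tab <- table(factor(low, c(TRUE, FALSE), c("maf_low", "maf_high")),
               factor(high_or, c(TRUE, FALSE), c("or_high", "or_low")))
  ft <- stats::fisher.test(tab)
  prop <- c(maf_low = mean(high_or[low]), maf_high = mean(high_or[!low]))
  list(medians = medians,
       mann_whitney = mw,
       fisher = comparison_report("Fisher's exact test (MAF x OR, two-sided)",
                                  p_value = ft$p.value, n = nrow(cc),
                                  odds_ratio_estimate = unname(ft$estimate),
                                  detail = as.data.frame.matrix(tab)),
       prop_or_gt = prop)
}

#' One-way ANOVA across phenotypic classes
#'
#' Standard F test of equality of group means via [stats::aov()]. For a
#' catalog the response is either the risk-allele frequency or the
#' ancestral-state indicator, with groups given by [class_assignment()].
#'
#' @param values Numeric response vector, or a `snp_catalog`.
#' @param groups Group labels (ignored when `values` is a catalog).
#' @param what For a catalog: `"freq"` (risk frequency) or `"state"`
#'   (ancestral indicator).
#' @return A `comparison_report` with the F statistic and both df.
#' @export
anova_classes <- function(values, groups = NULL, what = c("freq", "state")) {
  if (inherits(values, "snp_catalog")) {
    what <- match.arg(what)
    groups <- class_assignment(values)
    values <- if (what == "freq") values$risk_freq
              else as.numeric(values$state == "ancestral")
    keep <- !is.na(groups)
    values <- values[keep]; groups <- groups[keep]
  }
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- stats::anova(fit)
  comparison_report("one-way ANOVA", statistic = tab$`F value`[1],
                    df = c(tab$Df[1], tab$Df[2]),
                    p_value = tab$`Pr(>F)`[1], n = length(values),
                    group_means = tapply(values, groups, mean))
}
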