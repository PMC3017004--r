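#' Odds-ratio distributions for detection-probability calculations
#'
#' Effect sizes of disease-associated alleles are modelled on the odds-ratio
#' scale with support above 1: a point mass (`or_dist_delta`), a uniform
#' distribution (`or_dist_uniform`), or a normal distribution truncated below
#' at 1 and renormalized (`or_dist_normal`).
#'
#' @param value Point-mass location (> 1 allowed; >= 1 required).
#' @param lo,hi Uniform bounds, `1 <= lo < hi`.
#' @param mean,sd Normal location and scale before truncation at 1.
#' @return An object of class `or_dist`.
#' @export
or_dist_delta <- function(value = 1.25) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 1)
  structure(list(kind = "delta", value = value), class = "or_dist")
}

#' @rdname or_dist_delta
#' @export
or_dist_uniform <- function(lo = 1.0, hi = 1.5) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo >= 1, hi > lo)
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "or_dist")
}

#' @rdname or_dist_delta
#' @export
or_dist_normal <- function(mean = 1.25, sd = 0.1) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(list(kind = "normal", mean = mean, sd = sd), class = "or_dist")
}

#' @export
print.or_dist <- function(x, ...) {
  cat("Odds-ratio distribution:", x$kind,
      switch(x$kind,
             delta   = paste0("(", x$value, ")"),
             uniform = paste0("(", x$lo, ", ", x$hi, ")"),
             normal  = paste0("(mean ", x$mean, ", sd ", x$sd, ", truncated at 1)")),
      "\n")
  invisible(x)
}

#' Sample odds ratios from an `or_dist`
#'
#' Truncated-normal draws use rejection below 1.
#'
#' @param dist An `or_dist`.
#' @param n Number of draws.
#' @return Numeric vector of odds ratios (all >= 1).
#' @export
sample_or <- function(dist, n) {
  stopifnot(inherits(dist, "or_dist"))
  switch(dist$kind,
         delta = rep(dist$value, n),
         uniform = stats::runif(n, dist$lo, dist$hi),
         normal = {
           out <- numeric(0)
           while (length(out) < n) {
             draw <- stats::rnorm(n, dist$mean, dist$sd)
             out <- c(out, draw[draw >= 1])
           }
           out[seq_len(n)]
         })
}

#' Case-control GWAS detection model
#'
#' Bundles the study design (cases, controls, genome-wide significance level,
#' genetic model) with an odds-ratio distribution. Defaults follow the common
#' design of 2500 cases and 2500 controls tested at `alpha = 5e-8` under a
#' multiplicative model with the marker fully linked to the causal allele.
#'
#' @param n_cases,n_controls Numbers of cases and controls (>= 1).
#' @param alpha Two-sided significance level, in `(0, 1)`.
#' @param or_dist An `or_dist` (default point mass at 1.25).
#' @param dominance Genetic model tag; only `"multiplicative"` is implemented.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(n_cases = 2500, n_controls = 2500, alpha = 5e-8,
                            or_dist = or_dist_delta(1.25),
                            dominance = "multiplicative") {
  stopifnot(n_cases >= 1, n_controls >= 1, alpha > 0, alpha < 1,
            inherits(or_dist, "or_dist"))
  dominance <- match.arg(dominance, "multiplicative")
  structure(list(n_cases = n_cases, n_controls = n_controls, alpha = alpha,
                 or_dist = or_dist, dominance = dominance),
            class = "detection_model")
}

#' Statistical power of the allelic case-control test
#'
#' Two-proportion normal-approximation power for the allelic test. Under the
#' multiplicative model with complete linkage, a risk allele at population
#' frequency `x` with odds ratio `or` has expected case allele frequency
#' `or * x / (1 + x * (or - 1))` and control frequency `x`; the test compares
#' the two proportions over `2 * n_cases` and `2 * n_controls` alleles at the
#' two-sided level `alpha`. Relabeling the alleles maps `(x, or)` to
#' `(1 - x, 1/or)` and leaves power unchanged.
#'
#' @param x Risk-allele frequency in `[0, 1]` (vectorized; monomorphic values
#'   return `alpha`).
#' @param or Odds ratio, `>= 1` (vectorized). Fold effects below 1 onto the
#'   complementary allele before calling.
#' @param model A [detection_model()].
#' @return Power in `[alpha, 1]`.
#' @export
gwas_power <- function(x, or, model = detection_model()) {
  stopifnot(inherits(model, "detection_model"))
  if (any(or < 1)) stop("odds ratios must be >= 1; fold or < 1 onto 1/or",
                        call. = FALSE)
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]", call. = FALSE)
  power_kernel(x, or, model)
}

# normal-approximation power of the two-proportion allelic test; accepts any
# positive odds ratio (the public gwas_power restricts to or >= 1)
power_kernel <- function(x, or, model) {
  n <- max(length(x), length(or))
  x <- rep_len(x, n); or <- rep_len(or, n)
  m1 <- 2 * model$n_cases
  m0 <- 2 * model$n_controls
  p0 <- x
  p1 <- or * x / (1 + x * (or - 1))
  delta <- p1 - p0
  pbar <- (m1 * p1 + m0 * p0) / (m1 + m0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m0))
  se1 <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  zc <- stats::qnorm(1 - model$alpha / 2)
  pow <- stats::pnorm((abs(delta) - zc * se0) / se1) +
    stats::pnorm((-abs(delta) - zc * se0) / se1)
  pow <- pmax(pmin(pow, 1), model$alpha)
  pow[x <= 0 | x >= 1] <- model$alpha
  pow
}

#' Marginal probability of detecting a disease-associated allele
#'
#' Integrates [gwas_power()] over the model's odds-ratio distribution by
#' 64-point Gauss-Legendre quadrature (point-mass distributions are evaluated
#' directly; the truncated normal is integrated over `[1, mean + 8 sd]` with
#' its renormalized density).
#'
#' @param x Risk-allele frequencies (vectorized).
#' @param model A [detection_model()].
#' @return Detection probability in `[alpha, 1]` for each `x`.
#' @export
detection_probability <- function(x, model = detection_model()) {
  stopifnot(inherits(model, "detection_model"))
  dist <- model$or_dist
  if (dist$kind == "delta") return(gwas_power(x, dist$value, model))
  if (dist$kind == "uniform") {
    gl <- pracma::gaussLegendre(64, dist$lo, dist$hi)
    wts <- gl$w / (dist$hi - dist$lo)
  } else {
    hi <- dist$mean + 8 * dist$sd
    gl <- pracma::gaussLegendre(64, 1, hi)
    dens <- stats::dnorm(gl$x, dist$mean, dist$sd)
    wts <- gl$w * dens / sum(gl$w * dens)
  }
  vapply(x, function(xi) sum(wts * gwas_power(xi, gl$x, model)), numeric(1))
}

#' Heterozygosity approximation to the detection probability
#'
#' For the default design (2500/2500, `alpha = 5e-8`, multiplicative model,
#' odds ratios below about 1.5) the detection probability is well approximated
#' by `2x(1 - x)` -- coincidentally the expected heterozygosity.
#'
#' @param x Frequency in `[0, 1]` (vectorized).
#' @return `2 * x * (1 - x)`.
#' @export
approx_detection <- function(x) {
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]", call. = FALSE)
  2 * x * (1 - x)
}

#' Linkage disequilibrium r-squared between causal and marker loci
#'
#' For a causal locus with risk allele `A` at frequency `y` and a marker locus
#' with allele `B` at frequency `x`,
#' `r^2 = (P(B|A) - P(B|a))^2 * y(1 - y) / (x(1 - x))`.
#' The haplotype probabilities must satisfy
#' `x = y * P(B|A) + (1 - y) * P(B|a)`.
#'
#' @param y Causal-allele frequency in `(0, 1)`.
#' @param x Marker-allele frequency in `(0, 1)`.
#' @param p_B_given_A,p_B_given_a Conditional probabilities of carrying the
#'   marker allele on causal-`A` and causal-`a` haplotypes.
#' @param tol Tolerance for the consistency constraint.
#' @return r-squared, in `[0, 1]`.
#' @export
r_squared <- function(y, x, p_B_given_A, p_B_given_a, tol = 1e-8) {
  vals <- c(y, x, p_B_given_A, p_B_given_a)
  if (any(vals < 0 | vals > 1)) stop("all inputs must lie in [0, 1]", call. = FALSE)
  if (x <= 0 || x >= 1 || y <= 0 || y >= 1)
    stop("monomorphic locus: x and y must lie strictly in (0, 1)", call. = FALSE)
  implied <- y * p_B_given_A + (1 - y) * p_B_given_a
  if (abs(implied - x) > tol)
    stop(sprintf("inconsistent haplotype frequencies: implied x = %.8f, given x = %.8f",
                 implied, x), call. = FALSE)
  (p_B_given_A - p_B_given_a)^2 * y * (1 - y) / (x * (1 - x))
}
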