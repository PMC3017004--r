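#' Truncated neutral null model for allele frequencies
#'
#' Under the constant-size infinite-sites neutral model the density of a
#' derived allele segregating at frequency `x` is proportional to `1/x`.
#' Because that density diverges as `x -> 0`, polymorphisms are only
#' considered when the minor allele frequency exceeds a threshold `d`, so all
#' frequencies live on `[d, 1 - d]`. A detection-weighted variant multiplies
#' the spectrum by the approximate probability `2x(1 - x)` that an allele is
#' detectable in a genome-wide case-control study and renormalizes, which
#' shifts mass toward intermediate frequencies.
#'
#' @param d Polymorphism threshold frequency, `0 < d < 0.5`. Default 0.025.
#' @param weighted Logical; apply the `2x(1 - x)` detection weighting?
#' @return An object of class `null_model`: a list with elements `d`,
#'   `weighted`, and the joint normalizing constant `C` for the per-state
#'   allele-frequency densities.
#' @examples
#' m <- null_model(0.025)
#' prob_ancestral(m)                 # 0.741
#' prob_ancestral(null_model(0.025, weighted = TRUE))  # 0.650
#' @export
null_model <- function(d = 0.025, weighted = FALSE) {
  check_threshold(d)
  stopifnot(is.logical(weighted), length(weighted) == 1L)
  C <- if (weighted) {
    # states: 2(1-x) derived and 2x ancestral; joint integral = 2(1 - 2d)
    1 / (2 * (1 - 2 * d))
  } else {
    # states: C/x derived and C/(1-x) ancestral; joint integral = 2 log((1-d)/d)
    1 / (2 * log((1 - d) / d))
  }
  structure(list(d = d, weighted = weighted, C = C), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("Truncated neutral null model (",
      if (x$weighted) "detection-weighted" else "unweighted",
      "), d = ", x$d, ", C = ", format(x$C, digits = 7), "\n", sep = "")
  invisible(x)
}

check_threshold <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0 || d >= 0.5)
    stop("threshold `d` must lie strictly between 0 and 0.5", call. = FALSE)
  invisible(d)
}

#' Per-state allele-frequency density of the null model
#'
#' The density of the frequency of an allele of a given state, normalized
#' jointly over both states on `[d, 1 - d]` (so each state carries mass 1/2 by
#' the mirror symmetry of the two forms). Unweighted: proportional to `1/x`
#' for derived and `1/(1 - x)` for ancestral alleles; detection-weighted:
#' proportional to `2(1 - x)` and `2x`.
#'
#' @param model A [null_model()].
#' @param x Frequencies in `[d, 1 - d]` (vectorized).
#' @param state `"derived"` or `"ancestral"`.
#' @return Probability density per unit frequency.
#' @export
null_density <- function(model, x, state = c("derived", "ancestral")) {
  stopifnot(inherits(model, "null_model"))
  state <- match.arg(state)
  if (any(x < model$d - 1e-12 | x > 1 - model$d + 1e-12))
    stop("frequency outside [d, 1 - d]", call. = FALSE)
  if (state == "ancestral") x <- 1 - x
  if (model$weighted) model$C * 2 * (1 - x) else model$C / x
}

#' SNP-level derived-allele frequency density
#'
#' The density of the derived-allele frequency of a segregating site,
#' integrating to 1 on `[d, 1 - d]`: proportional to `1/z` unweighted and to
#' `(1/z) * 2z(1 - z) = 2(1 - z)` after detection weighting.
#'
#' @inheritParams null_density
#' @param z Derived-allele frequencies in `[d, 1 - d]`.
#' @export
snp_density <- function(model, z) {
  stopifnot(inherits(model, "null_model"))
  d <- model$d
  if (any(z < d - 1e-12 | z > 1 - d + 1e-12))
    stop("frequency outside [d, 1 - d]", call. = FALSE)
  if (model$weighted) 2 * (1 - z) / (1 - 2 * d)
  else 1 / (z * log((1 - d) / d))
}

#' Probability that a randomly chosen neutral allele is ancestral
#'
#' A random allele at a site with derived frequency `z` is ancestral with
#' probability `1 - z` (equivalently, an allele's probability of being
#' ancestral equals its own frequency). Averaging over the truncated SNP
#' density gives, in closed form,
#' `1 + (2d - 1) / (log(1 - d) - log(d))` unweighted and
#' `(2/3)(d^2 - d + 1)` after detection weighting.
#'
#' @param model A [null_model()]; or, for the convenience wrappers, the
#'   threshold `d` directly.
#' @return Probability in `(0.5, 1)`.
#' @examples
#' prob_ancestral_unweighted(0.025)  # 0.7406912
#' prob_ancestral_weighted(0.025)    # 0.6504167
#' @export
prob_ancestral <- function(model) {
  stopifnot(inherits(model, "null_model"))
  if (model$weighted) prob_ancestral_weighted(model$d)
  else prob_ancestral_unweighted(model$d)
}

#' @rdname prob_ancestral
#' @param d Polymorphism threshold frequency, `0 < d < 0.5`.
#' @export
prob_ancestral_unweighted <- function(d) {
  check_threshold(d)
  1 + (2 * d - 1) / (log(1 - d) - log(d))
}

#' @rdname prob_ancestral
#' @export
prob_ancestral_weighted <- function(d) {
  check_threshold(d)
  (2 / 3) * (d^2 - d + 1)
}

#' Mean frequency of a randomly chosen allele
#'
#' A frequency-weighted random allele at a site with derived frequency `z` has
#' frequency `z` with probability `z` and `1 - z` otherwise, so its expected
#' frequency is `E[z^2 + (1 - z)^2]` under the SNP density. Computed by
#' adaptive quadrature. By the symmetry of the truncation this equals
#' [prob_ancestral()] for the same model.
#'
#' @param model A [null_model()].
#' @return Expected frequency, in `[0.5, 1)`.
#' @export
mean_random_allele_frequency <- function(model) {
  stopifnot(inherits(model, "null_model"))
  d <- model$d
  stats::integrate(function(z) (z^2 + (1 - z)^2) * snp_density(model, z),
                   d, 1 - d, rel.tol = 1e-10)$value
}

#' Binned spectrum of the null model
#'
#' Integrates the model densities over frequency bins. Two conventions are
#' available. The default (`allele_draw = FALSE`) bins the per-state
#' allele-frequency densities of [null_density()], under which each state
#' carries total mass 1/2. With `allele_draw = TRUE` the spectrum describes a
#' frequency-weighted random allele drawn at each SNP (the construction behind
#' the panel comparisons): the joint density is `x * f(x)` for a derived and
#' `x * f(1 - x)` for an ancestral allele at frequency `x`, where `f` is
#' [snp_density()], so the ancestral share equals [prob_ancestral()].
#'
#' @param model A [null_model()].
#' @param n_bins Number of equal-width frequency bins on `[0, 1]` (>= 2).
#' @param allele_draw Use the frequency-weighted random-allele joint density?
#' @return A [binned_spectrum()] whose masses sum to 1; bins are clipped to
#'   `[d, 1 - d]` before integration, and the continuous densities are
#'   attached so that [weight_spectrum()] can reweight exactly.
#' @export
neutral_spectrum <- function(model, n_bins = 10, allele_draw = FALSE) {
  stopifnot(inherits(model, "null_model"))
  if (!is.numeric(n_bins) || n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  d <- model$d
  edges <- seq(0, 1, length.out = n_bins + 1)
  lo <- rep(edges[-(n_bins + 1)], times = 2)
  hi <- rep(edges[-1], times = 2)
  st <- rep(c("derived", "ancestral"), each = n_bins)
  clip_lo <- pmax(lo, d)
  clip_hi <- pmin(hi, 1 - d)
  dens <- if (allele_draw) {
    list(derived   = function(x) x * snp_density(model, x),
         ancestral = function(x) x * snp_density(model, 1 - x))
  } else {
    list(derived   = function(x) null_density(model, x, "derived"),
         ancestral = function(x) null_density(model, x, "ancestral"))
  }
  mass <- mapply(function(a, b, s) {
    if (b <= a) return(0)
    stats::integrate(dens[[s]], a, b, rel.tol = 1e-10)$value
  }, clip_lo, clip_hi, st)
  out <- binned_spectrum(lo, hi, st, mass / sum(mass))
  attr(out, "density") <- dens
  attr(out, "clip_low") <- clip_lo
  attr(out, "clip_high") <- clip_hi
  out
}
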