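#' Allele-age model
#'
#' Grids and sample size for frequency-based allele-age estimation under the
#' neutral model. Ages on the reporting grid are measured in units of `N_e`
#' generations (`N_e` the effective population size); the underlying
#' cumulative distribution [age_cdf()] uses the natural diffusion scale of
#' `2 N_e` generations, and the conversion between the two (a factor of 2) is
#' applied internally and documented here rather than hidden.
#'
#' @param n Sample size (chromosomes) entering [age_cdf()]; default 2500.
#' @param t_max Upper end of the age grid, in `N_e` generations (default 8).
#' @param t_step Grid spacing, in `N_e` generations (default 0.04).
#' @param x_grid Derived-allele frequency grid to which observed frequencies
#'   are snapped (default 0.05 to 0.95 in steps of 0.10).
#' @return Object of class `age_model`.
#' @export
age_model <- function(n = 2500, t_max = 8, t_step = 0.04,
                      x_grid = seq(0.05, 0.95, by = 0.10)) {
  stopifnot(n >= 2, t_step > 0, t_max > t_step, length(x_grid) >= 1,
            all(x_grid > 0 & x_grid < 1))
  structure(list(n = n, t_grid = seq(0, t_max, by = t_step),
                 x_grid = sort(x_grid)),
            class = "age_model")
}

#' Expected age of a derived allele at frequency x
#'
#' Under neutrality the expected age of an allele observed at derived
#' frequency `x` is `-2 x log(x) / (1 - x)`, in units of `2 N_e` generations.
#' Strictly increasing in `x`, with limit 2 as `x -> 1`.
#'
#' @param x Derived-allele frequency in `(0, 1)` (vectorized; exactly 1 is
#'   mapped to the limit 2).
#' @return Expected age in `2 N_e` generations.
#' @examples
#' expected_age(0.5)   # 2 log 2
#' @export
expected_age <- function(x) {
  if (any(x <= 0 | x > 1)) stop("frequency must lie in (0, 1]", call. = FALSE)
  out <- ifelse(x == 1, 2, -2 * x * log(x) / (1 - x))
  out
}

#' Cumulative distribution of allele age given frequency
#'
#' `P(age <= t | x) ~= (1 - x)^(-1 + n / (1 + n t / 2))` for a sample of `n`
#' chromosomes, with `t` in units of `2 N_e` generations. The expression is an
#' approximation whose `t -> Inf` limit is `(1 - x)^(-1)`, not 1, so densities
#' derived from it are renormalized over a finite grid (see [age_density()]).
#'
#' @param t Age in `2 N_e` generations (vectorized, >= 0).
#' @param x Derived-allele frequency in `(0, 1)`.
#' @param n Sample size in chromosomes (>= 2).
#' @return Non-decreasing, non-negative values (not guaranteed <= 1).
#' @export
age_cdf <- function(t, x, n = 2500) {
  if (any(t < 0)) stop("age must be non-negative", call. = FALSE)
  if (x <= 0 || x >= 1) stop("frequency must lie strictly in (0, 1)", call. = FALSE)
  stopifnot(n >= 2)
  (1 - x)^(-1 + n / (1 + n * t / 2))
}

#' Normalized allele-age density on the model grid
#'
#' Forward differences of [age_cdf()] over consecutive grid ages (evaluated on
#' the `2 N_e` scale, i.e. at `t/2` for grid ages `t` in `N_e` generations),
#' floored at zero and renormalized to sum to 1. Mass is attributed to the
#' midpoints of the grid intervals.
#'
#' @param x Derived-allele frequency in `(0, 1)`.
#' @param model An [age_model()].
#' @return Data frame with `t` (interval midpoints, `N_e` generations) and
#'   `density` (probability mass per interval, summing to 1).
#' @export
age_density <- function(x, model = age_model()) {
  stopifnot(inherits(model, "age_model"))
  tg <- model$t_grid
  if (length(tg) < 2) stop("degenerate age grid", call. = FALSE)
  cdf <- age_cdf(tg / 2, x, model$n)
  mass <- diff(cdf)
  mass[mass < 0] <- 0
  total <- sum(mass)
  if (total <= 0) stop("age density vanished on the grid", call. = FALSE)
  data.frame(t = (tg[-1] + tg[-length(tg)]) / 2, density = mass / total)
}

#' Mixture age distribution for a frequency spectrum
#'
#' Snaps each derived-allele frequency to the nearest point of the model's
#' `x_grid` (ties round down), averages the per-frequency age densities with
#' the supplied weights, and reports the grid mean of the mixture.
#'
#' @param derived_freqs Derived-allele frequencies in `(0, 1)`.
#' @param model An [age_model()].
#' @param weights Optional non-negative per-SNP weights (e.g. detection
#'   weights for a panel); default equal weights.
#' @return List with `mean_age` (`N_e` generations), `density` (data frame
#'   `t`, `density`), and `grid_weights` (mixture weight per `x_grid` point).
#' @export
mean_age_for_spectrum <- function(derived_freqs, model = age_model(),
                                  weights = NULL) {
  stopifnot(inherits(model, "age_model"))
  if (any(derived_freqs <= 0 | derived_freqs >= 1))
    stop("derived frequencies must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(derived_freqs))
  stopifnot(length(weights) == length(derived_freqs), all(weights >= 0),
            sum(weights) > 0)
  xg <- model$x_grid
  # nearest grid point; exact midpoints round down
  idx <- vapply(derived_freqs, function(f) {
    dist <- abs(xg - f)
    cand <- which(dist <= min(dist) + 1e-12)
    cand[1]
  }, integer(1))
  gw <- vapply(seq_along(xg), function(i) sum(weights[idx == i]), numeric(1))
  gw <- gw / sum(gw)
  dens_list <- lapply(xg[gw > 0], function(x) age_density(x, model))
  mix <- Reduce(`+`, Map(function(d, w) d$density * w, dens_list, gw[gw > 0]))
  tmid <- dens_list[[1]]$t
  list(mean_age = sum(tmid * mix),
       density = data.frame(t = tmid, density = mix),
       grid_weights = stats::setNames(gw, xg))
}
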