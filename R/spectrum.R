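#' Binned allele-frequency spectrum
#'
#' The common currency of the package: probability mass over frequency bins,
#' split by allelic state (`ancestral` vs `derived`). Model-derived spectra
#' carry masses only; empirical spectra additionally carry integer counts so
#' they can serve as the observed side of a goodness-of-fit test.
#'
#' @param bin_low,bin_high Numeric vectors of bin edges. Bins are half-open
#'   `[low, high)`; the bin ending at 1 is closed.
#' @param state Character vector, `"ancestral"` or `"derived"`, one per row.
#' @param mass Numeric vector of probability masses (must sum to 1 up to
#'   numerical tolerance unless `normalize = TRUE`).
#' @param count Optional numeric vector of observed counts per cell.
#' @param normalize If `TRUE`, rescale `mass` to sum to 1.
#' @return A data frame of class `binned_spectrum` with columns `bin_low`,
#'   `bin_high`, `state`, `mass` and (optionally `NA`) `count`.
#' @seealso [neutral_spectrum()], [bin_catalog()], [weight_spectrum()]
#' @export
binned_spectrum <- function(bin_low, bin_high, state, mass, count = NA_real_,
                            normalize = FALSE) {
  state <- match.arg(state, c("ancestral", "derived"), several.ok = TRUE)
  if (!(length(bin_low) == length(bin_high) &&
        length(bin_low) == length(state) &&
        length(bin_low) == length(mass))) {
    stop("bin_low, bin_high, state and mass must have equal length", call. = FALSE)
  }
  if (any(bin_high <= bin_low)) stop("bin_high must exceed bin_low", call. = FALSE)
  if (any(mass < 0)) stop("masses must be non-negative", call. = FALSE)
  if (normalize) mass <- mass / sum(mass)
  out <- data.frame(
    bin_low = as.numeric(bin_low), bin_high = as.numeric(bin_high),
    state = as.character(state), mass = as.numeric(mass),
    count = rep_len(as.numeric(count), length(mass)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("binned_spectrum", "data.frame")
  out
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat("Binned allele-frequency spectrum (", nrow(x), " cells, total mass ",
      format(sum(x$mass), digits = 7), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Total probability mass per allelic state
#'
#' @param spectrum A [binned_spectrum()].
#' @return Named numeric vector with the `ancestral` and `derived` shares.
#' @export
state_shares <- function(spectrum) {
  stopifnot(inherits(spectrum, "binned_spectrum"))
  tapply(spectrum$mass, spectrum$state, sum)[c("ancestral", "derived")]
}

#' Reweight a spectrum by a frequency-dependent detection weight
#'
#' Multiplies the spectrum by `weight_fn(x)` and renormalizes jointly over both
#' states. For spectra produced by [neutral_spectrum()] the underlying
#' continuous densities are carried along, and the weight is applied inside the
#' per-bin integral; for purely empirical spectra the weight is applied at bin
#' midpoints. Weighting a spectrum whose high-frequency mass is ancestral
#' shifts mass toward intermediate frequencies and lowers the ancestral share.
#'
#' @param spectrum A [binned_spectrum()].
#' @param weight_fn Function mapping frequency in `[0, 1]` to a non-negative
#'   weight, e.g. [approx_detection()].
#' @return A reweighted `binned_spectrum` (masses sum to 1; counts dropped).
#' @export
weight_spectrum <- function(spectrum, weight_fn) {
  stopifnot(inherits(spectrum, "binned_spectrum"), is.function(weight_fn))
  dens <- attr(spectrum, "density")
  if (is.null(dens)) {
    mid <- (spectrum$bin_low + spectrum$bin_high) / 2
    w <- vapply(mid, weight_fn, numeric(1))
    if (any(w < 0)) stop("weight_fn returned a negative weight", call. = FALSE)
    mass <- spectrum$mass * w
  } else {
    # dens is a list of per-state density functions over the clipped support
    mass <- mapply(function(lo, hi, st) {
      if (hi <= lo) return(0)
      stats::integrate(function(x) dens[[st]](x) * weight_fn(x), lo, hi,
                       rel.tol = 1e-10)$value
    }, attr(spectrum, "clip_low"), attr(spectrum, "clip_high"), spectrum$state)
  }
  if (sum(mass) <= 0) stop("weighting removed all mass", call. = FALSE)
  binned_spectrum(spectrum$bin_low, spectrum$bin_high, spectrum$state,
                  mass / sum(mass))
}

#' Write / read a spectrum as TSV or JSON
#'
#' TSV columns are `bin_low`, `bin_high`, `state`, `mass`, `count`.
#'
#' @param spectrum A [binned_spectrum()].
#' @param path Output (input) file path; format chosen by `.json` extension.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns
#'   a `binned_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "binned_spectrum"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(spectrum), path, digits = NA)
  } else {
    utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  binned_spectrum(df$bin_low, df$bin_high, df$state, df$mass,
                  count = if ("count" %in% names(df)) df$count else NA_real_)
}
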