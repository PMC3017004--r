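#' Summary table: disease-associated alleles vs. null expectations
#'
#' Builds the headline comparison: mean frequency of a randomly chosen allele
#' and proportion ancestral for (i) the panel, unweighted and
#' detection-weighted, (ii) the theoretical neutral null, unweighted and
#' weighted, (iii) each phenotypic class, (iv) all catalog alleles, and (v)
#' the replicated subset; with Mann-Whitney and binomial comparisons of the
#' catalog against both nulls.
#'
#' Panel rows are exact per-SNP expectations of the frequency-weighted random
#' allele draw: at a SNP with derived frequency `z` the drawn allele has
#' expected frequency `z^2 + (1 - z)^2` and is ancestral with probability
#' `1 - z`; detection weighting multiplies each SNP's contribution by
#' `2z(1 - z)`. The Mann-Whitney comparisons, which need samples rather than
#' expectations, use one seeded allele draw per panel SNP (for the weighted
#' null, panel SNPs are first resampled proportionally to their detection
#' weight).
#'
#' @param catalog A `snp_catalog`.
#' @param panel A `snp_panel`.
#' @param d Polymorphism threshold of the theoretical null (default 0.025).
#' @param seed Seed for the panel allele draws used in rank tests.
#' @param bootstrap_reps Replicates for the bootstrap CI of the catalog mean
#'   frequency (default 1e5).
#' @return Object of class `table1_report`: list with `rows` (data frame:
#'   label, n, mean_freq, prop_ancestral), `comparisons` (data frame of
#'   p-values), `bootstrap_ci`, and the run parameters.
#' @export
run_table1 <- function(catalog, panel, d = 0.025, seed = 1,
                       bootstrap_reps = 1e5) {
  stopifnot(inherits(catalog, "snp_catalog"), inherits(panel, "snp_panel"))
  z <- panel$derived_freq
  w <- approx_detection(z)
  panel_rows <- data.frame(
    label = c("panel (unweighted)", "panel (weighted)"),
    n = nrow(panel),
    mean_freq = c(mean(z^2 + (1 - z)^2),
                  sum(w * (z^2 + (1 - z)^2)) / sum(w)),
    prop_ancestral = c(mean(1 - z), sum(w * (1 - z)) / sum(w)),
    stringsAsFactors = FALSE
  )
  neutral_rows <- do.call(rbind, lapply(c(FALSE, TRUE), function(wt) {
    m <- null_model(d, weighted = wt)
    data.frame(label = paste0("neutral (", if (wt) "weighted" else "unweighted", ")"),
               n = NA_real_,
               mean_freq = mean_random_allele_frequency(m),
               prop_ancestral = prob_ancestral(m),
               stringsAsFactors = FALSE)
  }))

  cls <- class_assignment(catalog)
  class_rows <- do.call(rbind, lapply(sort(unique(cls[!is.na(cls)])), function(cl) {
    sub <- catalog[!is.na(cls) & cls == cl, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(label = paste0("class: ", cl), n = nrow(sub),
               mean_freq = mean(sub$risk_freq),
               prop_ancestral = mean(sub$state == "ancestral"),
               stringsAsFactors = FALSE)
  }))
  repl <- filter_catalog(catalog, replicated = TRUE)
  all_rows <- data.frame(
    label = c("all catalog alleles", "replicated subset"),
    n = c(nrow(catalog), nrow(repl)),
    mean_freq = c(mean(catalog$risk_freq),
                  if (nrow(repl)) mean(repl$risk_freq) else NA_real_),
    prop_ancestral = c(mean(catalog$state == "ancestral"),
                       if (nrow(repl)) mean(repl$state == "ancestral") else NA_real_),
    stringsAsFactors = FALSE
  )
  rows <- rbind(panel_rows, neutral_rows, class_rows, all_rows)
  rownames(rows) <- NULL

  # seeded draws for the rank-based comparisons
  set.seed(seed)
  draw_unw <- sample_allele(panel)
  idx_w <- sample.int(nrow(panel), nrow(panel), replace = TRUE, prob = w)
  draw_w <- sample_allele(panel[idx_w, , drop = FALSE])
  k_anc <- sum(catalog$state == "ancestral")
  comparisons <- data.frame(
    comparison = c("freq vs panel unweighted (Mann-Whitney)",
                   "freq vs panel weighted (Mann-Whitney)",
                   "prop ancestral vs neutral unweighted (binomial)",
                   "prop ancestral vs neutral weighted (binomial)",
                   "prop ancestral vs panel unweighted (binomial)",
                   "prop ancestral vs panel weighted (binomial)"),
    p_value = c(mann_whitney(catalog$risk_freq, draw_unw$freq)$p_value,
                mann_whitney(catalog$risk_freq, draw_w$freq)$p_value,
                binomial_prop_test(k_anc, nrow(catalog),
                                   prob_ancestral_unweighted(d))$p_value,
                binomial_prop_test(k_anc, nrow(catalog),
                                   prob_ancestral_weighted(d))$p_value,
                binomial_prop_test(k_anc, nrow(catalog),
                                   panel_rows$prop_ancestral[1])$p_value,
                binomial_prop_test(k_anc, nrow(catalog),
                                   panel_rows$prop_ancestral[2])$p_value),
    stringsAsFactors = FALSE
  )
  ci <- bootstrap_ci_mean(catalog$risk_freq, reps = bootstrap_reps, seed = seed)
  structure(list(rows = rows, comparisons = comparisons, bootstrap_ci = ci,
                 d = d, seed = seed),
            class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Disease-associated alleles vs. null expectations (d =", x$d,
      ", seed", x$seed, ")\n\n")
  print.data.frame(x$rows, row.names = FALSE, digits = 4)
  cat("\n95% bootstrap CI of catalog mean frequency: [",
      format(x$bootstrap_ci[["low"]], digits = 4), ", ",
      format(x$bootstrap_ci[["high"]], digits = 4), "]\n\n", sep = "")
  print.data.frame(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stratified control analyses
#'
#' Summaries (n, mean risk frequency, proportion ancestral, median odds
#' ratio) stratified by genotyping platform, number-of-genotyped-SNPs band,
#' and six-month publication interval. Strata with no records are omitted.
#'
#' @param catalog A `snp_catalog`.
#' @return List of data frames, one per stratification variable.
#' @export
run_controls <- function(catalog) {
  stopifnot(inherits(catalog, "snp_catalog"))
  strat <- function(var) {
    vals <- catalog[[var]]
    lv <- sort(unique(vals[!is.na(vals)]))
    out <- do.call(rbind, lapply(lv, function(v) {
      sub <- catalog[!is.na(vals) & vals == v, , drop = FALSE]
      data.frame(stratum = as.character(v), n = nrow(sub),
                 mean_freq = mean(sub$risk_freq),
                 prop_ancestral = mean(sub$state == "ancestral"),
                 median_or = if (all(is.na(sub$odds_ratio))) NA_real_
                             else stats::median(sub$odds_ratio, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    out
  }
  list(platform = strat("platform"),
       n_genotyped_band = strat("n_genotyped_band"),
       pub_half_year = strat("pub_half_year"))
}

#' Allele-age distributions for catalog and weighted panel
#'
#' Mixture age densities and means (in `N_e` generations) for the catalog's
#' derived-frequency spectrum and for the panel's derived-frequency spectrum
#' weighted by the detection probability `2z(1 - z)`.
#'
#' @param catalog A `snp_catalog`.
#' @param panel A `snp_panel`.
#' @param model An [age_model()].
#' @return List with `catalog` and `panel` (each a [mean_age_for_spectrum()]
#'   result) and `densities`, a long data frame (`t`, `density`, `which`)
#'   ready for plotting or TSV export.
#' @export
run_ages <- function(catalog, panel, model = age_model()) {
  stopifnot(inherits(catalog, "snp_catalog"), inherits(panel, "snp_panel"))
  cat_age <- mean_age_for_spectrum(derived_freq(catalog), model)
  pan_age <- mean_age_for_spectrum(panel$derived_freq, model,
                                   weights = approx_detection(panel$derived_freq))
  dens <- rbind(cbind(cat_age$density, which = "catalog"),
                cbind(pan_age$density, which = "panel_weighted"))
  list(catalog = cat_age, panel = pan_age, densities = dens)
}

#' Serialize a report to JSON
#'
#' @param report A `table1_report`, `comparison_report`, or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       force = TRUE, na = "null")
  invisible(path)
}
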