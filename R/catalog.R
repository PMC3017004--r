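#' Disease-associated SNP catalogs and control SNP panels
#'
#' A catalog row describes one disease-associated marker SNP: the reported
#' risk-allele frequency, whether the risk allele is ancestral or derived
#' (shared with the outgroup or not), and optional study metadata. A panel row
#' describes one control locus by its derived-allele frequency. Canonical
#' catalog columns: `snp_id`, `risk_freq`, `state`, `odds_ratio`, `p_value`,
#' `classes` (semicolon-separated phenotypic classes), `platform`,
#' `n_genotyped_band`, `pub_half_year`, `non_european`, `n_studies`.
#'
#' @name snp_catalog
NULL

catalog_columns <- c("snp_id", "risk_freq", "state", "odds_ratio", "p_value",
                     "classes", "platform", "n_genotyped_band",
                     "pub_half_year", "non_european", "n_studies")

#' Coerce a data frame to a canonical SNP catalog
#'
#' Fills missing optional columns with `NA`, validates frequencies and states,
#' and stamps the `snp_catalog` class. Used by [read_catalog()] and the
#' synthetic generator.
#'
#' @param df Data frame with at least `snp_id`, `risk_freq`, `state`.
#' @return A `snp_catalog` data frame.
#' @export
as_snp_catalog <- function(df) {
  stopifnot(all(c("snp_id", "risk_freq", "state") %in% names(df)))
  for (col in catalog_columns) {
    if (!col %in% names(df)) {
      df[[col]] <- switch(col,
                          non_european = FALSE,
                          n_studies = 1L,
                          NA)
    }
  }
  df <- df[, catalog_columns]
  if (any(df$risk_freq < 0 | df$risk_freq > 1, na.rm = TRUE))
    stop("risk_freq must lie in [0, 1]", call. = FALSE)
  bad <- !df$state %in% c("ancestral", "derived")
  if (any(bad)) stop("state must be 'ancestral' or 'derived' (drop unknowns first)",
                     call. = FALSE)
  class(df) <- c("snp_catalog", "data.frame")
  df
}

#' Read a disease-SNP catalog from delimited text
#'
#' Reads a TSV/CSV table, maps its columns onto the canonical layout, merges
#' rows that share a SNP id (mean risk frequency and odds ratio, union of
#' phenotypic classes, summed study count), and drops rows whose ancestral
#' vs. derived state is unknown or internally conflicting. Dropped and merged
#' rows are reported via [message()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (see [snp_catalog]) to the file's column names, e.g.
#'   `c(snp_id = "SNP", risk_freq = "RAF")`. Unmapped canonical columns are
#'   taken from identically named file columns when present.
#' @param sep Field separator; default inferred from the extension
#'   (`","` for `.csv`, otherwise tab).
#' @return A `snp_catalog` with one row per unique SNP id.
#' @export
read_catalog <- function(path, column_map = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("mapped column '%s' not found in %s", src, path), call. = FALSE)
      raw[[canon]] <- raw[[src]]
    }
  }
  if (!all(c("snp_id", "risk_freq", "state") %in% names(raw)))
    stop("catalog must provide snp_id, risk_freq and state columns", call. = FALSE)

  raw$risk_freq <- suppressWarnings(as.numeric(raw$risk_freq))
  n_badfreq <- sum(is.na(raw$risk_freq))
  if (n_badfreq > 0) {
    message(n_badfreq, " row(s) dropped: unparseable risk_freq")
    raw <- raw[!is.na(raw$risk_freq), , drop = FALSE]
  }
  raw$state <- tolower(trimws(as.character(raw$state)))
  known <- raw$state %in% c("ancestral", "derived")
  if (any(!known)) {
    message(sum(!known), " row(s) dropped: ancestral/derived state unknown")
    raw <- raw[known, , drop = FALSE]
  }
  if (!"n_studies" %in% names(raw)) raw$n_studies <- 1L
  if (!"classes" %in% names(raw)) raw$classes <- NA_character_

  merged <- lapply(split(raw, raw$snp_id), function(rows) {
    if (length(unique(rows$state)) > 1) return(NULL)  # conflicting polarity
    first <- rows[1, , drop = FALSE]
    first$risk_freq <- mean(rows$risk_freq)
    first$n_studies <- sum(rows$n_studies)
    cls <- unique(unlist(strsplit(rows$classes[!is.na(rows$classes)], ";")))
    first$classes <- if (length(cls)) paste(sort(cls), collapse = ";") else NA_character_
    if ("odds_ratio" %in% names(rows))
      first$odds_ratio <- if (all(is.na(rows$odds_ratio))) NA_real_
                          else mean(rows$odds_ratio, na.rm = TRUE)
    first
  })
  n_conflict <- sum(vapply(merged, is.null, logical(1)))
  if (n_conflict > 0)
    message(n_conflict, " SNP(s) dropped: conflicting ancestral/derived states")
  n_merged <- length(merged) - nrow(raw) # negative: rows collapsed
  if (nrow(raw) > length(merged) - n_conflict)
    message(nrow(raw) - (length(merged) - n_conflict),
            " duplicate row(s) merged into multi-study records")
  out <- do.call(rbind, merged[!vapply(merged, is.null, logical(1))])
  rownames(out) <- NULL
  as_snp_catalog(out)
}

#' Write a catalog (or panel) to TSV
#'
#' @param x A `snp_catalog` or `snp_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Derived-allele frequency of each catalog record
#'
#' `risk_freq` if the risk allele is derived, else `1 - risk_freq`.
#'
#' @param catalog A `snp_catalog`.
#' @return Numeric vector.
#' @export
derived_freq <- function(catalog) {
  stopifnot(inherits(catalog, "snp_catalog"))
  ifelse(catalog$state == "derived", catalog$risk_freq, 1 - catalog$risk_freq)
}

#' Bin a catalog into a frequency-by-state spectrum
#'
#' Risk-allele frequencies are binned into half-open intervals of the given
#' width (the bin ending at 1 is closed), separately for ancestral and derived
#' risk alleles. Counts are preserved alongside masses for chi-square use.
#'
#' @param catalog A `snp_catalog`.
#' @param bin_width Bin width on `[0, 1]`; must divide 1 evenly. Default 0.10.
#' @return A [binned_spectrum()] with both `mass` and `count`.
#' @export
bin_catalog <- function(catalog, bin_width = 0.10) {
  stopifnot(inherits(catalog, "snp_catalog"), bin_width > 0, bin_width <= 0.5)
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9)
    stop("bin_width must divide [0, 1] evenly", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(catalog$risk_freq, edges,
                           rightmost.closed = TRUE), n_bins)
  counts <- table(factor(catalog$state, c("derived", "ancestral")),
                  factor(idx, seq_len(n_bins)))
  cnt <- c(counts["derived", ], counts["ancestral", ])
  binned_spectrum(rep(edges[-(n_bins + 1)], 2), rep(edges[-1], 2),
                  rep(c("derived", "ancestral"), each = n_bins),
                  mass = cnt / sum(cnt), count = cnt)
}

#' Subset a catalog by study metadata
#'
#' All filters are optional and combined with AND. Phenotypic class matching
#' uses the semicolon-separated `classes` field (a record matches if any of
#' its classes equals `class`).
#'
#' @param catalog A `snp_catalog`.
#' @param replicated Keep only records implicated in >= 2 studies.
#' @param class Keep records carrying this phenotypic class.
#' @param platform,n_genotyped_band,pub_half_year Exact-match filters.
#' @param exclude_non_european Drop records flagged `non_european`.
#' @param max_p Keep records with `p_value <= max_p`.
#' @return The filtered `snp_catalog`.
#' @export
filter_catalog <- function(catalog, replicated = FALSE, class = NULL,
                           platform = NULL, n_genotyped_band = NULL,
                           pub_half_year = NULL, exclude_non_european = FALSE,
                           max_p = NULL) {
  stopifnot(inherits(catalog, "snp_catalog"))
  keep <- rep(TRUE, nrow(catalog))
  if (replicated) keep <- keep & catalog$n_studies >= 2
  if (!is.null(class)) {
    keep <- keep & vapply(strsplit(ifelse(is.na(catalog$classes), "",
                                          catalog$classes), ";"),
                          function(cl) class %in% cl, logical(1))
  }
  if (!is.null(platform)) keep <- keep & !is.na(catalog$platform) &
      catalog$platform == platform
  if (!is.null(n_genotyped_band)) keep <- keep & !is.na(catalog$n_genotyped_band) &
      catalog$n_genotyped_band == n_genotyped_band
  if (!is.null(pub_half_year)) keep <- keep & !is.na(catalog$pub_half_year) &
      catalog$pub_half_year == pub_half_year
  if (exclude_non_european) keep <- keep & !catalog$non_european
  if (!is.null(max_p)) keep <- keep & !is.na(catalog$p_value) &
      catalog$p_value <= max_p
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' Phenotypic class assignment with a "multiple" category
#'
#' Records carrying two or more phenotypic classes are assigned to the
#' `"multiple"` category; single-class records keep their class. This rule is
#' used for the per-class rows of the summary table and for the across-class
#' ANOVA.
#'
#' @param catalog A `snp_catalog`.
#' @return Character vector, one label per record (`NA` if no class recorded).
#' @export
class_assignment <- function(catalog) {
  stopifnot(inherits(catalog, "snp_catalog"))
  vapply(strsplit(ifelse(is.na(catalog$classes), "", catalog$classes), ";"),
         function(cl) {
           cl <- cl[nzchar(cl)]
           if (length(cl) == 0) NA_character_
           else if (length(cl) >= 2) "multiple"
           else cl
         }, character(1))
}

#' Construct / coerce a control SNP panel
#'
#' @param snp_id Identifiers.
#' @param derived_freq Derived-allele frequencies, strictly in `(0, 1)`.
#' @param position Optional data frame with `chrom` and `pos` for spacing
#'   checks; SNPs on one chromosome must then be at least `min_spacing` apart.
#' @param min_spacing Minimum within-chromosome spacing in bp (default 2e5).
#' @return A `snp_panel` data frame.
#' @export
snp_panel <- function(snp_id, derived_freq, position = NULL,
                      min_spacing = 2e5) {
  stopifnot(length(snp_id) == length(derived_freq))
  if (any(derived_freq <= 0 | derived_freq >= 1))
    stop("panel derived_freq must lie strictly in (0, 1)", call. = FALSE)
  out <- data.frame(snp_id = as.character(snp_id),
                    derived_freq = as.numeric(derived_freq),
                    stringsAsFactors = FALSE)
  if (!is.null(position)) {
    stopifnot(all(c("chrom", "pos") %in% names(position)),
              nrow(position) == nrow(out))
    for (ch in unique(position$chrom)) {
      p <- sort(position$pos[position$chrom == ch])
      if (length(p) > 1 && min(diff(p)) < min_spacing)
        stop(sprintf("panel SNPs closer than %g bp on chromosome %s",
                     min_spacing, ch), call. = FALSE)
    }
    out$chrom <- position$chrom
    out$pos <- position$pos
  }
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Read a control panel from TSV
#'
#' Expects columns `snp_id` and `derived_freq` (plus optional `chrom`, `pos`).
#'
#' @param path Input TSV path.
#' @return A `snp_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos <- if (all(c("chrom", "pos") %in% names(df)))
    df[, c("chrom", "pos")] else NULL
  snp_panel(df$snp_id, df$derived_freq, position = pos)
}

#' Frequency-weighted random allele draw at each panel SNP
#'
#' At a SNP with derived-allele frequency `z`, the derived allele is drawn
#' with probability `z` and the ancestral allele otherwise (a SNP with allele
#' frequencies 0.80/0.20 yields its major allele 80% of the time). The drawn
#' allele's own frequency is reported.
#'
#' @param panel A `snp_panel`.
#' @param seed Optional integer seed for reproducible draws.
#' @return Data frame with `snp_id`, `state` of the drawn allele, and `freq`,
#'   the drawn allele's frequency.
#' @export
sample_allele <- function(panel, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!is.null(seed)) set.seed(seed)
  derived <- stats::runif(nrow(panel)) < panel$derived_freq
  data.frame(snp_id = panel$snp_id,
             state = ifelse(derived, "derived", "ancestral"),
             freq = ifelse(derived, panel$derived_freq, 1 - panel$derived_freq),
             stringsAsFactors = FALSE)
}
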