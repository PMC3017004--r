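test_that("duplicate SNP ids merge with mean frequency and study counting", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(snp_id = c("rs1", "rs1", "rs2"),
                   risk_freq = c(0.3, 0.5, 0.7),
                   state = c("derived", "derived", "ancestral"),
                   classes = c("cancer", "metabolism", NA),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(cat <- read_catalog(path))
  expect_equal(nrow(cat), 2)
  rs1 <- cat[cat$snp_id == "rs1", ]
  expect_equal(rs1$risk_freq, 0.4)
  expect_equal(rs1$n_studies, 2)
  expect_equal(rs1$classes, "cancer;metabolism")
  unlink(path)
})

test_that("rows with unknown or conflicting states are dropped with a notice", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs3"),
                   risk_freq = c(0.3, 0.4, 0.5, 0.6),
                   state = c("derived", "", "ancestral", "derived"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(cat <- read_catalog(path), "state unknown")
  expect_equal(cat$snp_id, "rs1")  # rs2 unknown state; rs3 conflicting
  unlink(path)
})

test_that("unparseable frequencies reject the row, not the file", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("snp_id,risk_freq,state",
               "rs1,0.35,derived",
               "rs2,not_a_number,ancestral"), path)
  expect_message(cat <- read_catalog(path), "unparseable")
  expect_equal(cat$snp_id, "rs1")
  unlink(path)
})

test_that("catalogs survive a write/read round trip and row order", {
  df <- make_catalog_df(50)
  cat1 <- as_snp_catalog(df)
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat1, path)
  suppressMessages(cat2 <- read_catalog(path))
  cat2 <- cat2[match(cat1$snp_id, cat2$snp_id), ]
  rownames(cat2) <- NULL
  expect_equal(cat2$risk_freq, cat1$risk_freq)
  expect_equal(cat2$state, cat1$state)
  expect_equal(cat2$odds_ratio, cat1$odds_ratio)
  expect_equal(cat2$classes, cat1$classes)

  # shuffled input rows produce the same merged catalog
  path2 <- tempfile(fileext = ".tsv")
  set.seed(2)
  write.table(df[sample(nrow(df)), ], path2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  suppressMessages(cat3 <- read_catalog(path2))
  cat3 <- cat3[match(cat1$snp_id, cat3$snp_id), ]
  expect_equal(cat3$risk_freq, cat1$risk_freq)
  unlink(c(path, path2))
})

test_that("derived frequency is the exact complement for ancestral alleles", {
  cat <- as_snp_catalog(make_catalog_df(30))
  df <- derived_freq(cat)
  other <- ifelse(cat$state == "derived", 1 - cat$risk_freq, cat$risk_freq)
  expect_equal(df + other, rep(1, 30))
})

test_that("binning uses half-open intervals with the last bin closed", {
  cat <- as_snp_catalog(data.frame(
    snp_id = c("a", "b", "c"),
    risk_freq = c(0.05, 0.10, 1.0),
    state = c("derived", "derived", "ancestral"),
    stringsAsFactors = FALSE))
  sp <- bin_catalog(cat)
  expect_equal(sum(sp$count), 3)
  expect_equal(sp$count[sp$state == "derived" & sp$bin_low == 0], 1)
  expect_equal(sp$count[sp$state == "derived" & sp$bin_low == 0.1], 1)
  expect_equal(sp$count[sp$state == "ancestral" & sp$bin_high == 1], 1)
  expect_equal(sum(sp$mass), 1)
})

test_that("binning recovers a constructed composition exactly", {
  freqs <- c(rep(0.05, 4), rep(0.55, 2), rep(0.95, 3))
  states <- c(rep("derived", 4), rep("ancestral", 2), rep("ancestral", 3))
  cat <- as_snp_catalog(data.frame(snp_id = paste0("s", 1:9),
                                   risk_freq = freqs, state = states,
                                   stringsAsFactors = FALSE))
  sp <- bin_catalog(cat)
  expect_equal(sp$count[sp$state == "derived" & sp$bin_low == 0], 4)
  expect_equal(sp$count[sp$state == "ancestral" & sp$bin_low == 0.5], 2)
  expect_equal(sp$count[sp$state == "ancestral" & sp$bin_low == 0.9], 3)
  expect_equal(sum(sp$count), 9)
})

test_that("frequency-weighted allele draws follow the 80/20 rule", {
  panel <- snp_panel("s1", 0.8)
  big <- panel[rep(1, 1e5), ]
  class(big) <- class(panel)
  draws <- sample_allele(big, seed = 6)
  share <- mean(draws$state == "derived")
  se <- sqrt(0.8 * 0.2 / 1e5)
  expect_lt(abs(share - 0.8), 3 * se)
  expect_equal(unique(draws$freq[draws$state == "derived"]), 0.8)
  expect_equal(unique(draws$freq[draws$state == "ancestral"]), 0.2)
  # expected drawn-allele frequency is z^2 + (1 - z)^2
  expect_lt(abs(mean(draws$freq) - (0.8^2 + 0.2^2)), 3 * se)
  # near-fixed derived allele is essentially always drawn
  hi <- snp_panel("s2", 1 - 1e-12)
  expect_true(all(sample_allele(hi, seed = 1)$state == "derived"))
})

test_that("metadata filters subset exactly and idempotently", {
  df <- make_catalog_df(40)
  df$n_studies <- c(rep(2, 12), rep(1, 28))
  cat <- as_snp_catalog(df)
  expect_equal(nrow(filter_catalog(cat, replicated = TRUE)), 12)
  expect_equal(nrow(filter_catalog(cat, exclude_non_european = TRUE)), 40)
  c1 <- filter_catalog(cat, class = "cancer")
  c2 <- filter_catalog(c1, class = "cancer")
  expect_equal(c1, c2)
  expect_true(all(grepl("cancer", c1$classes)))
  # p-value threshold
  expect_true(all(filter_catalog(cat, max_p = 1e-8)$p_value <= 1e-8))
})

test_that("multi-class records map to the multiple category", {
  df <- make_catalog_df(20)
  df$classes <- c(rep("cancer", 10), rep("cancer;metabolism", 6), rep(NA, 4))
  lab <- class_assignment(as_snp_catalog(df))
  expect_equal(sum(lab == "cancer", na.rm = TRUE), 10)
  expect_equal(sum(lab == "multiple", na.rm = TRUE), 6)
  expect_equal(sum(is.na(lab)), 4)
})

test_that("panel construction enforces frequency bounds and SNP spacing", {
  expect_error(snp_panel("a", 0), "strictly")
  pos <- data.frame(chrom = c("1", "1"), pos = c(1e6, 1e6 + 5e4))
  expect_error(snp_panel(c("a", "b"), c(0.3, 0.4), position = pos), "closer")
  ok <- snp_panel(c("a", "b"), c(0.3, 0.4),
                  position = data.frame(chrom = c("1", "1"),
                                        pos = c(1e6, 1.5e6)))
  expect_s3_class(ok, "snp_panel")
  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  write_catalog(ok, path)
  back <- read_panel(path)
  expect_equal(back$derived_freq, ok$derived_freq)
  unlink(path)
})
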