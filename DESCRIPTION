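Package: gwasnull
Title: Disease-Associated Allele Spectra Against Neutral and SNP-Panel Null Expectations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the frequency spectrum and ancestral/derived composition of
    disease-associated alleles from genome-wide association studies against two
    null expectations: a truncated infinite-sites neutral model and a random SNP
    panel, both before and after weighting by the probability that an allele is
    detectable in a case-control study. Provides closed-form and quadrature
    implementations of the truncated neutral null, case-control power and
    detection-probability curves, a recycling Wright-Fisher simulator verifying
    the 1/x occupancy law, frequency-based allele-age estimation, catalog and
    panel data handling, seeded synthetic-data generators, and the accompanying
    statistical test battery (chi-square goodness of fit, Mann-Whitney, binomial,
    bootstrap, Fisher's exact, one-way ANOVA).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
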