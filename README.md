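# gwasnull

Do the alleles implicated in genome-wide association studies (GWAS) look
like the rest of the genome? `gwasnull` is an R package for population
geneticists and statistical geneticists who want to compare the frequency
spectrum, ancestral/derived composition, effect sizes, and estimated ages of
disease-associated marker alleles against two null expectations — the
truncated infinite-sites neutral model and a random SNP-panel sample — after
making the comparison fair by weighting the nulls with the probability that
an allele of a given frequency is detectable in a case-control study.

## The model at its core

Under the constant-size neutral infinite-sites model the density of sites
with derived-allele frequency *x* is ∝ 1/*x*, truncated to
[*d*, 1 − *d*] (default *d* = 0.025) to keep it integrable. An allele's
probability of being ancestral equals its own frequency, which yields closed
forms for the probability that a frequency-weighted random allele is
ancestral:

- unweighted: P(ancestral) = 1 + (2*d* − 1)/(ln(1 − *d*) − ln *d*) = **0.741** at *d* = 0.025,
- detection-weighted by 2*x*(1 − *x*): P(ancestral) = (2/3)(*d*² − *d* + 1) = **0.650**,

each equal to the mean frequency of a randomly chosen allele under the same
model. Around this core the package provides:

- `null_model()`, `null_density()`, `neutral_spectrum()`, `weight_spectrum()` — the
  truncated null, its binned spectra, and detection reweighting;
- `gwas_power()`, `detection_probability()`, `approx_detection()`, `r_squared()` —
  case-control power as a function of frequency and odds ratio, marginals
  over odds-ratio distributions, and the LD attenuation relation;
- `wf_simulate()`, `wf_compare_theory()` — a recycling Wright–Fisher
  simulator verifying the 1/*x* occupancy law;
- `expected_age()`, `age_cdf()`, `age_density()`, `mean_age_for_spectrum()` —
  frequency-based allele-age estimation and mixture age distributions;
- `read_catalog()`, `bin_catalog()`, `filter_catalog()`, `sample_allele()` —
  catalog/panel I/O, binning, and the frequency-weighted allele draw;
- `chisq_gof()`, `mann_whitney()`, `binomial_prop_test()`, `bootstrap_ci_mean()`,
  `or_analyses()`, `anova_classes()` — the statistical test battery;
- `gen_panel()`, `gen_gwas_catalog()` — seeded synthetic generators so the
  whole pipeline is testable without any download;
- `run_table1()`, `run_controls()`, `run_ages()` — the assembled analyses.

## Worked example

Generate a synthetic catalog at the package's default study conditions
(1143 SNPs calibrated to mean risk-allele frequency 0.394 and ancestral
share 0.437, odds ratio 1.25) with a 1000-SNP neutral panel, and compare:

```r
library(gwasnull)
catalog <- gen_gwas_catalog(n_snps = 1143, seed = 42)
panel   <- gen_panel(1000, seed = 42)
run_table1(catalog, panel, seed = 42)
```

```
Disease-associated alleles vs. null expectations (d = 0.025 , seed 42 )

                        label    n mean_freq prop_ancestral
           panel (unweighted) 1000    0.7468         0.7474
             panel (weighted) 1000    0.6559         0.6499
         neutral (unweighted)   NA    0.7407         0.7407
           neutral (weighted)   NA    0.6504         0.6504
                class: cancer  111    0.4140         0.4324
        class: cardiovascular  162    0.3733         0.4691
            class: metabolism  159    0.3857         0.4843
 class: miscellaneous disease  290    0.3786         0.4483
         class: morphological  285    0.3922         0.4632
              class: multiple   14    0.4315         0.5000
          class: neurological  122    0.4089         0.4508
          all catalog alleles 1143    0.3895         0.4593
            replicated subset  130    0.4142         0.4385

95% bootstrap CI of catalog mean frequency: [0.3748, 0.4042]

                                      comparison    p_value
         freq vs panel unweighted (Mann-Whitney) 1.018e-134
           freq vs panel weighted (Mann-Whitney) 1.178e-111
 prop ancestral vs neutral unweighted (binomial)  2.466e-90
   prop ancestral vs neutral weighted (binomial)  1.229e-39
   prop ancestral vs panel unweighted (binomial)  2.441e-95
     prop ancestral vs panel weighted (binomial)  2.047e-39
```

Reading the output: the panel rows recover the theoretical neutral values
(0.741/0.741 unweighted, 0.650/0.650 weighted) to sampling error, confirming
the nulls agree with each other; the catalog rows sit far below both
(mean ≈ 0.39, ancestral share ≈ 0.46 in this single 1143-SNP draw of a
0.394/0.437-calibrated generator), and every comparison p-value is
vanishingly small — disease-associated alleles are enriched for
low-frequency derived alleles relative to either null. The age analysis
makes the same point on the time axis:

```r
ages <- run_ages(catalog, panel)
round(c(catalog = ages$catalog$mean_age, panel_weighted = ages$panel$mean_age), 2)
#>        catalog panel_weighted
#>           2.38           2.36
```

with the catalog's density carrying more mass below 1 effective-population-size
generation (young alleles) than the detection-weighted panel.

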