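---
title: "Comparing disease-associated alleles with neutral and panel null expectations"
author: "gwasnull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing disease-associated alleles with neutral and panel null expectations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasnull)
```

## The question

Marker alleles implicated in genome-wide association studies (GWAS) can be
characterized by three evolutionary coordinates: their population frequency,
whether they are ancestral (shared with an outgroup such as chimpanzee) or
derived (arisen by mutation since the split), and their effect size (odds
ratio). `gwasnull` asks whether the joint distribution of these coordinates
among disease-associated alleles differs from what one would see at random
SNPs — either theoretical neutral loci or a random genotyping-panel sample —
once the comparison is made fair by accounting for the probability that an
allele of a given frequency is detectable at all in a case-control study.

## The truncated neutral null

Under the constant-size infinite-sites neutral model, the density of sites
segregating a derived allele at frequency $x$ is proportional to $1/x$.
Because this diverges at 0, the model is truncated: only sites whose minor
allele frequency exceeds a threshold $d$ (default $0.025$) are considered,
so frequencies live on $[d, 1-d]$. Two layers of the model are exposed:

* **Per-state allele-frequency densities** (`null_density`): proportional to
  $1/x$ for derived and $1/(1-x)$ for ancestral alleles, normalized jointly
  over both states. These are the spectra one plots per state.
* **The random-allele construction**: a frequency-weighted random allele at
  a site with derived frequency $z$ is ancestral with probability $1-z$ (an
  allele's chance of being ancestral equals its own frequency, i.e. its
  fixation probability). Averaging over the truncated site density gives the
  closed forms
  $$P(\text{ancestral}) = 1 + \frac{2d-1}{\ln(1-d)-\ln d}
    \quad\text{(unweighted)},\qquad
    P(\text{ancestral}) = \tfrac{2}{3}(d^2-d+1)
    \quad\text{(weighted)},$$
  implemented in `prob_ancestral_unweighted()` and
  `prob_ancestral_weighted()` and cross-checked in the test suite against
  adaptive quadrature of the defining integrals (relative tolerance
  $10^{-10}$; agreement required to $10^{-8}$).

A useful identity, verified numerically on a grid of thresholds: the mean
frequency of a frequency-weighted random allele, $E[z^2+(1-z)^2]$, equals
$P(\text{ancestral})$ for the same model. Both are 0.741 (unweighted) and
0.650 (weighted) at $d = 0.025$.

```{r nulls}
prob_ancestral_unweighted(0.025)
mean_random_allele_frequency(null_model(0.025, weighted = TRUE))
```

## Detection weighting

Case-control power depends strongly on allele frequency, so raw genomic
spectra are not comparable with a GWAS catalog. The power kernel
(`gwas_power`) is a two-proportion normal-approximation test: under the
multiplicative model with the marker fully linked to the causal allele, the
case allele frequency is $p_1 = \mathrm{or}\,x/(1+x(\mathrm{or}-1))$ against
a control frequency $p_0 = x$, compared over $2n_\text{cases}$ and
$2n_\text{controls}$ alleles at a two-sided genome-wide level
(default $\alpha = 5\times10^{-8}$, 2500 cases and controls). Design notes:

* The kernel is validated in the tests against a Monte-Carlo simulation of
  the test it approximates.
* Allele relabeling maps $(x, \mathrm{or})$ to $(1-x, 1/\mathrm{or})$ and
  leaves power exactly invariant; the public API restricts to
  $\mathrm{or} \ge 1$ and asks the caller to fold smaller effects onto the
  complementary allele. Note that $(x,\mathrm{or})$ and $(1-x,\mathrm{or})$
  are *different* alternatives: the power surface is only approximately
  symmetric in $x$, with its maximum near $x \approx 0.47$ rather than at
  $0.5$, a consequence of the odds-ratio parameterization.
* Whether the original power computations used a trend or genotypic test is
  not knowable from the published description; the two-proportion allelic
  kernel is this package's documented choice.

`detection_probability()` marginalizes power over an odds-ratio distribution
(point mass, uniform, or normal truncated below 1 and renormalized —
untruncated draws would put mass where "odds ratio < 1" is undefined for a
risk allele) using 64-point Gauss–Legendre quadrature; Monte-Carlo
integration appears only as a test oracle. For the default design the
profile is well approximated by the heterozygosity curve
$2x(1-x)$ (`approx_detection`), which is the weight used throughout the
weighted nulls. Because power is steep in the odds ratio, the profile for a
point mass at 1.25 differs appreciably (by up to $\approx 0.23$ in absolute
detection probability at mid-low frequencies) from the profile averaged over
a uniform distribution on $[1.0, 1.5]$, even though all profiles share the
$2x(1-x)$ shape (correlation $> 0.95$); the uniform and truncated-normal
profiles agree much more closely.

`weight_spectrum()` applies a weight function to a binned spectrum. Spectra
produced by `neutral_spectrum()` carry their continuous densities, so the
weight is applied inside the per-bin integrals and reweighting the
unweighted null reproduces the analytically weighted null to $10^{-6}$;
purely empirical spectra are reweighted at bin midpoints.

## Wright–Fisher verification of the 1/x law

`wf_simulate()` checks the occupancy law by forward simulation: the derived
allele count is binomially resampled each generation out of $N$ gene copies
(default $10^4$; the published description does not state ploidy, and the
occupancy shape is $N$-free, so gene copies are the recorded convention),
frequencies are recorded after sampling, and on fixation or loss a single
copy re-enters. Absorbing generations are excluded from the polymorphic
occupancy. Runs are deterministic given the seed.

Occupancy along a single trajectory is heavily autocorrelated:
high-frequency bins are visited only by the rare (probability $\sim 1/N$)
excursions that approach fixation, so their occupancy shares converge very
slowly. Replicate runs at $10^6$ steps show per-bin relative deviations
from the $1/x$ masses of 35% and more in the extreme bins, and even the
full $10^7$-step setting leaves 10–25% deviations there. The package's
routine tests therefore verify the law through bin-*ratio* statistics in the
body of the distribution with Monte-Carlo standard errors estimated from
replicate trajectories, at test scales of $2\times10^5$–$10^6$ steps;
`wf_compare_theory()` reports a chi-square discrepancy whose p-value is
explicitly flagged as approximate for this reason.

## Allele ages

Under neutrality the expected age of an allele at derived frequency $x$ is
$-2x\ln(x)/(1-x)$ in units of $2N_e$ generations (`expected_age`). For
distributions of ages the package uses the approximate cumulative
distribution $P(\tau \le t \mid x) \approx (1-x)^{-1+n/(1+nt/2)}$ with
sample size $n = 2500$ chromosomes by default. Conventions, all explicit in
the API:

* `age_cdf()` takes time in the natural diffusion units of $2N_e$
  generations. The reporting grid of `age_model()` is labelled in $N_e$
  generations (0 to 8 by 0.04), and the factor-2 conversion is applied
  internally — consistent with the expected-age formula, whose $2N_e$-unit
  values double when quoted in $N_e$ generations.
* The cumulative expression tends to $(1-x)^{-1}$, not 1, as
  $t \to \infty$; grid densities (forward differences, floored at zero) are
  therefore renormalized over the finite grid. The truncation at 8 $N_e$
  generations is part of the procedure and shortens the heavy upper tail.
* `mean_age_for_spectrum()` snaps each derived frequency to the nearest
  point of the 0.05–0.95 grid (ties round down) and mixes the per-frequency
  densities with optional per-SNP weights, e.g. detection weights
  $2z(1-z)$ for a panel (`run_ages`).

Because the synthetic generator's derived-frequency spectrum is the pure
detection-weighted neutral density (mean $\approx 0.35$), synthetic mean
ages are somewhat younger than those of empirical panels, whose
ascertainment-biased derived spectra sit higher; the qualitative contrast —
low-frequency-derived-enriched catalogs carry more age mass below
1 $N_e$ generation than a weighted panel — is what the tests assert.

## Catalogs, panels, and the test battery

`read_catalog()` ingests delimited catalogs through a configurable column
map, averages the risk-allele frequency (and odds ratio) over rows sharing
a SNP id, unions their phenotypic classes, counts studies, and drops —
with logged counts — rows whose ancestral/derived state is unknown or
conflicting. Frequencies are kept at the precision given. Records carrying
two or more phenotypic classes are assigned to a `"multiple"` category for
the per-class rows and the across-class ANOVA (`class_assignment`); the
rule is a package decision, recorded here, since class multiplicities make
any partition convention somewhat arbitrary.

For the goodness-of-fit comparisons one side must be counts: empirical
spectra from `bin_catalog()` carry counts (half-open bins, the bin ending
at 1 closed), and model spectra supply expected masses, renormalized
internally so the statistic is scale-invariant. Cells with expected count
below 5 warn but are not merged. For 10 bins by two states the test has 19
degrees of freedom. Other choices: Mann–Whitney uses the normal
approximation with tie correction (samples here are typically hundreds;
an exact option exists for small samples), binomial and Fisher tests are
exact, the bootstrap of the mean is the seeded percentile interval with
$10^5$ replicates by default, and no multiple-testing correction is applied
— reports carry raw p-values.

Table-style summaries (`run_table1`) compute the panel rows as exact
per-SNP expectations of the random-allele draw
($\tfrac1n\sum_i [z_i^2+(1-z_i)^2]$ and $\tfrac1n\sum_i (1-z_i)$, detection-
weighted versions weighting each SNP by $2z_i(1-z_i)$) rather than one
random draw per SNP; the rank-based comparisons, which need samples, use
seeded draws. Reports are byte-identical given the same inputs and seed.

## The synthetic generator

`gen_panel()` draws panel frequencies from the truncated $1/x$ law by its
closed-form quantile $x = d((1-d)/d)^u$, optionally thinning minor allele
frequencies below 0.1 to emulate ascertainment bias. `gen_gwas_catalog()`
draws SNP derived frequencies from the same law, accepts them with
probability proportional to a detection weight (the $2x(1-x)$ curve by
default), and then decides which allele is the risk allele. Defaults are the
study conditions the package models: 1143 records, $d = 0.025$, point-mass
odds ratio 1.25 present for 530/1143 records, 92/1143 non-European,
142/1143 replicated, and the seven phenotypic classes at their empirical
weights (112, 145, 160, 290, 276, 135, 25 — which sum exactly to 1143).

A frequency-independent choice of risk-allele state cannot match the
empirical catalog: fixing the ancestral share at 0.437 would force the mean
risk frequency to 0.481 under the weighted null, while the observed mean is
0.394 (ancestral risk alleles are on average common, derived ones rare).
The generator therefore uses a logistic frequency tilt,
$$P(\text{risk allele is derived} \mid z) = \mathrm{logit}^{-1}\!\big(a - b(2z-1)\big),$$
with $(a, b)$ solved by quadrature and nested root finding so that the
expected ancestral share and mean risk frequency hit their targets exactly;
at the default targets the attainable mean range is roughly 0.29–0.48, so
0.394 is comfortably interior. Recorded states can then be flipped at a
mislabeling rate, which symmetrizes the ancestral share toward 0.5 and
shifts the apparent spectrum toward high-frequency derived alleles — the
signature of ancestral-state misidentification.

What the generator does *not* emulate: real LD structure between causal and
marker loci (the $r^2$ relation is exercised analytically in
`r_squared()`), non-equilibrium demography, winner's-curse inflation of
odds ratios at low frequency, and the empirical panel's detailed
ascertainment profile. Passing the recovery tests therefore shows the
pipeline is unbiased and correctly calibrated under the stated model — not
that real catalogs satisfy that model.

## Problem sizes and numerical choices

Quadrature is `stats::integrate()` at relative tolerance $10^{-10}$
(closed forms are the public API; quadrature is the cross-check).
Odds-ratio marginals use 64 Gauss–Legendre nodes. Routine tests use panels
of $10^3$–$10^5$ SNPs, catalogs of $10^3$–$4\times10^4$ records,
Wright–Fisher runs of $2\times10^5$–$10^6$ steps, and bootstrap sizes of
$10^3$–$10^5$; all are package choices balancing Monte-Carlo error floors
(3 standard errors wherever a stochastic quantity is compared) against
runtime. Degenerate inputs error early: thresholds outside $(0, 0.5)$,
frequencies outside the truncated support, monomorphic loci in $r^2$,
expected-zero cells in the chi-square, and inconsistent haplotype
frequencies all raise informative conditions rather than propagating NaN.

## Known limitations

* The neutral null is constant-size; growth or bottlenecks are out of
  scope, and conclusions about real data should note that expansion also
  enriches low-frequency derived alleles genome-wide.
* Only the multiplicative dominance model is implemented in the power
  kernel.
* The age distribution rests on an approximate cumulative expression and
  neutrality; directional selection would make both catalogs and panels
  younger than reported.
* Chi-square p-values for simulated occupancy understate uncertainty
  because trajectory autocorrelation is ignored; they are labelled
  approximate.
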