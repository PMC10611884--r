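---
title: "Methods: the aquatic-risk score and its threshold engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the aquatic-risk score and its threshold engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdst)
```

## The score

`pdst` ranks pesticide active ingredients (PAIs) by a single aquatic-risk
value, the product of two measures computed per formulation row:

* **Measure of effect** `= application rate (umol/ha) / threshold (umol/ML)`.
  The application rate is the label product rate times the AI mass fraction
  (times density for volumetric labels), annualized for slow-release
  products, converted to moles. The threshold is a chronic freshwater
  guideline or ecotoxicity threshold value; dividing by it after a
  umol/L → umol/ML conversion makes the measure the megalitres of dilution
  water needed per treated hectare. It is linear in the rate and inverse in
  the threshold, so a spray regime treating a fraction *f* of the field
  scales it (and the final risk) by exactly *f*.
* **Measure of mobility and persistence**
  `= DT50_soil x DT50_water x p(Koc)`, with
  `p(Koc) = (-10.076 log10(Koc) + 39.123) / 100` clamped to `[floor, 1]`.
  The line is an empirical regression of percent runoff loss on log10 Koc
  from rainfall-simulation field trials on a poorly drained hydrosol; the
  package treats its two coefficients as fixed model constants and offers
  `fit_loss_regression()` to re-derive them from trial data.

The product is a unitless likelihood-style score for ranking; it predicts no
concentration. The conventional report scale divides by 100, which is how
the bundled reference table prints risks.

Both measures enter multiplicatively and untransformed, giving them equal
weight: if A is ten times more mobile and persistent than B at equal effect,
A's risk is ten times B's.

## Assumptions worth stating

* The maximum permitted label rate and a broadcast regime are the default
  exposure surrogate, so all PAIs are compared on a common worst-case basis;
  `rate_bound = "min"`/`"mean"` recompute under other label bounds, and
  `rate_sensitivity()` quantifies how little the *ranking* depends on that
  choice (Spearman rho >= 0.98 across bounds on the bundled dataset, in line
  with the >= 0.95 reported for the original tables).
* Koc as the sole mobility driver ignores pH-dependent sorption of
  ionizable compounds and sediment-phase transport of strongly sorbed
  cations (pKa is stored but unused by the score).
* Chronic thresholds (not acute endpoints) are used throughout, matching a
  long-exposure protection goal.
* Tank-mix totals assume additivity of component risks — an indicative
  screen, not mixture toxicology.

## Threshold derivation

`derive_etv()` reproduces the guideline-style pipeline:

1. `species_values()`: one value per species — the geometric mean of
   quality-accepted records (the usual choice for multiplicative toxicity
   data; `aggregate = "minimum"` is available for conservatism). Quality
   screening itself is out of scope: records arrive with a
   `quality_accepted` flag.
2. `select_sensitive_subset()`: if the caller declares the dataset bimodal,
   only the mode-of-action-sensitive group is retained (phototrophs for
   herbicides, arthropods for insecticides; configurable). Bimodality is a
   declaration, not a detection — expert grouping decides it in practice —
   though `bimodality_gap()` provides an advisory gap statistic on log10
   values.
3. `check_minimum_data()`: the SSD route requires at least 5 species from 4
   taxonomic groups.
4. SSD route: `fit_ssd()` fits by maximum likelihood on log-transformed
   values, log-logistic below 8 species and Burr III at 8 or more
   (`auto_distribution_threshold`). `select_percentile()` picks PC95, or
   PC99 when log Kow >= 4 (boundary included), because bioaccumulating
   compounds warrant protecting more of the community; assessment-factor
   thresholds carry no percentile. The protective concentration PCp is the
   (100 - p)/100 quantile of the fitted distribution.
5. Fallback route: `assessment_factor_etv()` divides the lowest species
   value by a factor keyed to that value's endpoint class (defaults 10
   chronic / 20 chronic-estimated / 100 converted-acute). The factor table
   is an explicit reconstruction of common guideline practice, shipped as
   editable YAML (`derivation_config.yaml`), since the authoritative values
   are not republished here.
6. `classify_reliability()`: a monotone points rubric over species count,
   group count, endpoint mix and fit quality (Kolmogorov–Smirnov distance
   bands 0.1/0.2). The rubric, too, is a configurable reconstruction; it is
   guaranteed monotone (more data or better fit never lowers the class) and
   is exercised property-style in the tests.

The distribution policy approximates the behaviour of the commonly used SSD
software for this derivation style (a three-parameter Burr family for rich
datasets, a two-parameter fallback for sparse ones) without attempting
bit-exact replication of any particular program.

### Numerical choices

* Log-logistic MLE is a logistic fit to log values (location = log alpha,
  scale = 1/beta), Nelder-Mead from moment starts.
* Burr III (`F(x) = (1 + (b/x)^c)^-k`) is optimised over log-parameters
  with multiple starts; the first start is the fitted log-logistic at
  `k = 1`, which is exactly the Burr III subfamily it belongs to. Interior
  terms are evaluated in log space (`log1p(exp(z))` with a linear guard for
  large `z`) to avoid overflow.
* If no Burr start converges, the engine falls back to the log-logistic fit
  and sets `convergence_flag = FALSE` rather than failing.
* Degenerate inputs (fewer than two distinct values) raise a classed error;
  quantile coherence PC99 <= PC95 <= PC90 <= PC80 holds by construction and
  is re-asserted on random data in the tests.
* Ranking ties share average ranks (needed for rank correlations);
  dominance ties in `compare_pais()` fall back to the smaller scalar risk.
* The runoff line crosses zero at log10 Koc ≈ 3.883. The transported
  proportion clamps at a configurable `mobility_floor`, default 0: the
  package does not invent runoff for strongly sorbed compounds. The
  published reference table instead prints mobility ≈ 0.01 for its six
  log Koc > 4 members; those stored values are kept as data in
  `reference_measures.csv`, and plots based on recomputed measures simply
  omit zero-mobility rows (a log axis cannot show them).

## The bundled reference dataset

`pdst_reference_data()` ships 47 PAIs (48 rows; liquid and slow-release
imidacloprid) with thresholds, derivation metadata, physicochemical
properties and application rates. Thresholds and the per-row reference
measures are the published values; application rates and water half-lives
were **back-calculated** from the published measures (label-verbatim rates
were not available), so they are reconstructions flagged as such. Several
anchors support the reconstruction: back-computed rates match in-text label
rates for diuron (1.9 kg/ha x 0.90), ametryn (2.0 kg AI/ha), MSMA
(4.75 kg AI/ha) and metsulfuron-methyl (0.007 kg AI/ha). The engine
reproduces the stored effect column on all 48 rows and the stored mobility
column on the 42 runoff-mobile rows to within 1e-5 relative; the identity
`risk = effect x mobility` is exact by construction.

```{r reference}
risk <- pdst_compute(pdst_reference_data())
head(risk[order(risk$rank_by_risk), c("label", "aquatic_risk_reported")])
```

## What the synthetic generators emulate

* `generate_fixture_table()` draws properties log-uniformly over the ranges
  spanned by the reference data (Koc 1–1e6 L/kg, DT50 0.1–1e4 d, thresholds
  1e-7–10 umol/L). It emulates the *spread* of real registries, not their
  correlation structure (e.g. real Koc and log Kow are correlated;
  generated ones are independent), so passing tests show the engine handles
  realistic magnitudes and degenerate corners, not that it reproduces any
  particular market of products.
* `generate_toxicity_data()` draws species sensitivities log10-normally
  (default mean -1, sd 0.5 — a typical decade-wide SSD centred at
  0.1 umol/L) with small replicate noise (sd 0.05 log10). True percentiles
  of the generating distribution are available in closed form, which is
  what the recovery tests compare against. Real toxicity compilations add
  censoring, inter-lab variance and taxonomic clustering that the generator
  deliberately omits.
* `generate_runoff_trials()` produces percent-loss points on the runoff
  line plus Gaussian noise, truncated at zero — enough to validate the
  regression machinery, not a hydrological simulator.

## Monte-Carlo design of the percentile-recovery check

A single PC95 estimate from 32 species is intrinsically noisy: by
simulation, even the oracle estimator — fitting the true generating
lognormal family by maximum likelihood and reading off its 5th percentile —
has a *median absolute relative error* of about 21% at n = 32,
sigma_log10 = 0.5. No fitted SSD can beat the information in the sample, so
the package's recovery test asserts *median recovery* instead: over 200
replicated datasets, the median of the Burr III PC95 estimates must lie
within 15% of the generating distribution's true 5th percentile. This
checks for systematic bias (a wrong quantile formula, a skewed optimiser)
while respecting sampling noise; the shipped fitter lands within about 5%.
Problem sizes throughout the suite (200 replicates of n = 32; lattices of
n = 1000; one 10,000-point empirical-quantile check) were chosen so each
check is statistically meaningful while the whole suite stays quick to run.

## Statistics module

`spearman()` ranks with average ties and correlates with Pearson's formula;
the two-sided p-value is the exact permutation fraction for n <= 9 and the
t approximation `t = rho sqrt((n-2)/(1-rho^2))` otherwise. Both routes are
offered because small runoff-trial datasets (n ≈ 15) sit near the boundary
where the approximation starts to be trusted. Outlier removal in
`fit_loss_regression()` (e.g. dropping a charge-anomalous compound from a
soil type) is an explicit `drop =` argument, never automatic.

## Known limitations

* Mobility ignores leaching, erosion, spray drift and site specifics
  (slope, rainfall, soil); the score is generic by design.
* Thresholds inherit every limitation of their input data; AF-derived
  values are typically conservative and carry `reliability = "unknown"`.
* The Burr III likelihood surface is flat in `k` for near-log-logistic
  data; parameter values are then poorly identified even though the fitted
  quantiles (all that the score consumes) are stable.
* Reconstructed application rates in the bundled dataset reproduce the
  published measures, not the current labels; regulatory decisions should
  re-derive rates from live label data via the registry CSVs.
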