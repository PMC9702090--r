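---
title: "Methods: envirotyping, mega-environments, and multi-trait stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envirotyping, mega-environments, and multi-trait stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`envmet` implements a complete workflow for dissecting genotype-by-environment
interaction (GEI) in multi-environment trials (METs) of annual crops: it
characterises trial locations from long-term daily weather ("envirotyping"),
groups them into mega-environments (MEs), partitions phenotypic variance with
a crossed random-effects model, and selects genotypes within each ME for the
combination of mean performance and year-to-year stability across many traits
at once. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology leaves room.

```{r setup}
library(envmet)
```

## 1. Environmental covariables

The raw inputs are daily weather records per location: mean, maximum, minimum
and dew-point temperature (°C), relative humidity (%), precipitation
(mm day⁻¹), wind speed at 2 m (m s⁻¹), shortwave insolation on a horizontal
surface and downward longwave flux (MJ m⁻² day⁻¹). `derive_covariables()`
expands these to 19 covariables by adding ten derived quantities:

* **TRANGE** — diurnal temperature range, `Tmax − Tmin`.
* **VPD** — vapour pressure deficit (kPa). Saturation vapour pressure uses
  the Tetens form `e_s(T) = 0.6108·exp(17.27T/(T+237.3))`; actual vapour
  pressure is `e_s(Tdew)`; VPD is the mean of `e_s(Tmax)` and `e_s(Tmin)`
  minus `e_a`, floored at zero.
* **SVP** — slope of the saturation vapour pressure curve at `Tmean`,
  `Δ = 4098·e_s(T)/(T+237.3)²` (kPa °C⁻¹); ≈ 0.145 at 20 °C.
* **RTA, N** — extraterrestrial radiation and daylight hours from standard
  solar geometry (inverse relative Earth–Sun distance, solar declination and
  sunset hour angle from latitude and day of year).
* **n** — actual sunshine duration, inverting the Ångström relation
  `Rs = (a + b·n/N)·RTA` with defaults `a = 0.25`, `b = 0.50`, clipped to
  `[0, N]`.
* **ETP** — reference evapotranspiration (mm day⁻¹). Priestley–Taylor
  (α = 1.26) is the default because it needs no wind or humidity calibration;
  FAO-56 Penman–Monteith is available via
  `covariable_params(etp_method = "penman-monteith")`. Both use net radiation
  from shortwave input, clear-sky transmissivity and vapour pressure.
* **PETP** — precipitation minus ETP. Sign convention: **positive PETP means
  water supply exceeds atmospheric demand**. This is fixed by definition
  here; descriptions of the quantity in the agronomic literature sometimes
  gloss the sign both ways, so the package documents its own convention and
  uses it consistently.
* **GDD** — growing degree days, `max(0, (Tmax+Tmin)/2 − Tbase)`, with
  `Tbase = 8 °C` for maize (configurable).
* **FRUE** — temperature effect on radiation-use efficiency: a
  piecewise-linear response in [0, 1] between cardinal temperatures
  `Tb = 9`, `Topt1 = 26`, `Topt2 = 32`, `Tceil = 45 °C` (configurable).

All formulas are evaluated day by day; the test suite checks them against an
independent straight-line re-evaluation at 10⁻⁹ tolerance.

## 2. Envirotype matrix, enviromic kernel, mega-environments

`build_w_matrix()` aggregates daily covariables into one descriptor per
(year, covariable, calendar-month window). The default windows are the six
months May–October, covering the summer growing season, so 20 years of
archive yield `20 × 19 × 6 = 2280` descriptors per location. Aggregation is
the **mean** for state variables (temperatures, humidity, VPD, SVP, FRUE,
wind, radiative fluxes) and the **sum** for accumulation variables
(precipitation, ETP, PETP, GDD, sunshine, daylight and extraterrestrial
radiation); the literature does not prescribe the aggregator, and sums keep
accumulation variables in agronomically meaningful units (total thermal time,
seasonal water balance).

Columns are standardised across environments before anything else; without
standardisation the kernel is dominated by high-magnitude covariables (GDD
sums are thousands, FRUE is ≤ 1). Quality control then removes **whole
descriptor columns** containing any standardised cell beyond ±3 SD (the
threshold is the `qc_sd` knob). Removing whole columns rather than cells
keeps the matrix complete; zero-variance columns are removed for the same
reason.

The enviromic kernel is

$$K_E = \frac{WW'}{\mathrm{trace}(WW')/n},$$

the environmental analogue of a genomic relationship matrix; the
normalisation forces `trace(K_E) = n` environments (tested to 10⁻⁹, along
with symmetry and positive semi-definiteness).

`delineate_mega_environments()` clusters environments with average linkage
(UPGMA). Because a kernel is a similarity, a distance must be chosen: we use
the kernel-induced Euclidean distance
`d(i,j) = sqrt(K_ii + K_jj − 2K_ij)`, which preserves the geometry the
kernel defines. The number of MEs `k` is a **user decision** (default 4);
no automatic cut is applied because cluster-count selection on 10
environments is fragile. `me_silhouette()` is offered as a diagnostic only.

## 3. Environmental typology

`env_typing()` classifies each trial day of each covariable into classes
bounded by the global quantiles 0.01, 0.25, 0.50, 0.75, 0.975 and 0.99
(configurable), and tabulates relative day frequencies per
(year, ME, crop stage). The default maize stage windows in days after sowing
are 0–14 (initial), 15–35 (leaf expansion I), 36–65 (leaf expansion II),
66–90 (flowering) and 91–120 (grain filling). Breakpoints are global (pooled
over all trial days) so that "extreme" means the same thing in every ME;
frequencies within each group sum to 1 by construction, and empty groups are
omitted and logged rather than emitted as NaN.

## 4. Variance components and heritability

For each trait the model is

$$y_{ijkn} = \mu + G_i + M_j + Y_k + GM_{ij} + GY_{ik} + MY_{jk} + GMY_{ijk}
  + REP_{n(j:k)} + \epsilon_{ijkn},$$

with all terms random and only the intercept fixed. The replicate term is
the location × block combination nested within each ME × year — locations
are deliberately absorbed into replicates because the ME, not the individual
location, is the environmental unit of interest. Estimation is REML via
`lme4::lmer()`; variances are constrained non-negative and boundary
estimates are reported as exact zeros. On balanced one-way layouts the
estimates match the ANOVA closed form `(MS_G − MS_E)/r` to 10⁻⁶ relative
(tested), which anchors the implementation to an independent oracle.

Term significance uses the likelihood-ratio test between the full REML fit
and the fit without the term. The default reference distribution is
χ²(1) — conservative, because the null value lies on the boundary of the
parameter space — with the 50:50 mixture χ²₀:χ²₁ available via
`lrt_random_effects(..., dist = "mixture")`.

Broad-sense heritability on a genotype-mean basis is

$$H^2 = \frac{\sigma^2_G}{\sigma^2_P}, \qquad
\sigma^2_P = \sigma^2_G + \frac{\sigma^2_{GY}}{K} + \frac{\sigma^2_{GM}}{J}
 + \frac{\sigma^2_{GMY}}{JK} + \frac{\sigma^2_\epsilon}{\sum_k N},$$

with `J` MEs, `K` years, and the residual divided by the **total** number of
location × block × year replicate combinations (60 for a 10-location,
3-block, 2-year design). The divisor interpretation matters: only the total
count reproduces the published genetic-parameter tables this package's
acceptance checks recompute. Selection accuracy is `Ac = sqrt(H2)`.
`variance_contributions()` returns both the share of each model term in the
total phenotypic variance and the share of each component in σ²_P.

## 5. Mean performance and stability (MPS)

Within each ME, `genotype_year_means()` averages plots over the ME's
locations and blocks per year. Pooling plots (rather than averaging location
means first) is exact under balance and uses all data under imbalance; this
choice is documented because the two coincide only for balanced data.
Year-to-year stability is Wricke's ecovalence

$$W_i = \sum_k (\bar Y_{ik} - \bar Y_{i.} - \bar Y_{.k} + \bar Y_{..})^2,$$

the genotype's contribution to the genotype × year interaction sum of
squares (their sum equals the interaction SS exactly — an identity the tests
assert). Genotypes missing a year are excluded with a warning since their
ecovalence is undefined.

Mean performance and ecovalence are each linearly rescaled to [0, 100] in
the direction that makes 100 "good": traits where higher is better (grain
yield, ear length, ear rows, grain weight per ear, 100-seed weight) map the
maximum to 100; traits where lower is better (grain moisture, plant and ear
height, bare tip length) and the ecovalence (always) map the minimum to 100.
A degenerate (constant) vector rescales to 50 everywhere with a warning — a
neutral value that avoids claiming a best or worst genotype without
information. The MPS index is the weighted mean

$$MPS_i = \frac{rY_i\,\theta_Y + rW_i\,\theta_S}{\theta_Y + \theta_S},$$

with default weights θ_Y = 70, θ_S = 30 favouring mean performance, since a
stable but poor genotype is not a selection target. `weight_scenarios()`
recomputes rankings over the 21-step grid 100/0, 95/5, …, 0/100 to show how
rank depends on the weighting; ties get average ranks for determinism.

## 6. Multi-trait index (MTMPS)

The genotype × trait table of MPS values (`mps_table()`) feeds an
exploratory factor analysis (`factor_analysis()`): principal-component
extraction from the trait correlation matrix `R`, retention of factors with
eigenvalue > 1, varimax rotation with Kaiser row normalisation (the standard
default), and regression scores

$$F = Z\,(A'R^{-1})',$$

where `Z` is the column-standardised table and `A` the rotated loadings.
Rotated loadings are used for scoring because the scores are computed after
rotation in this workflow. If `R` is singular, a Moore–Penrose pseudo-inverse
is substituted and flagged. If no eigenvalue exceeds 1 (e.g. an identity
`R`), one factor is kept with a warning rather than none. The ideotype — MPS
= 100 for every trait — is passed through the **same** standardisation
(genotype-sample column means and SDs) and scoring map; projecting the
ideotype with the sample statistics keeps it in the same score space as the
genotypes. The index

$$MTMPS_i = \Big[\sum_{j=1}^f (F_{ij} - F_j^{\,ideo})^2\Big]^{1/2}$$

is the Euclidean distance to the ideotype's scores; lower is better, and a
genotype scoring 100 on every trait attains exactly 0.
`select_genotypes()` keeps the `round(intensity · q)` smallest distances
(6 of 26 at the default intensity 6/26 ≈ 23%; 25% intensity rounds to the
same six), breaking ties by genotype label. `selection_differentials()`
reports `ΔS% = (X_s − X_o)/X_o × 100` on trait means (desired sign = the
trait's direction) and on ecovalences (desired sign negative), and
`cross_me_summary()` tabulates in how many MEs each genotype is selected.

## 7. The synthetic-data generator

Because the workflow is usually applied to confidential trial data, the
package ships a generator that reproduces the *statistical structure* the
analysis assumes — not any real climate or genetics.

**Phenotypes** (`simulate_trial()`) are drawn exactly from the Section 4
model: independent zero-mean normal draws per term, with per-trait variances
defaulting to REML estimates from a published 26-hybrid maize panel, so
simulated signal-to-noise ratios per trait are realistic. The effect
distribution is exposed as a hook (`effect_rng`) for robustness experiments;
the replicate (location × block) effect is assumed normal like every other
term — a modelling convention, since random-effects METs rarely state that
distribution explicitly. Default grand means are field-typical magnitudes
(grain yield 10.5 t ha⁻¹, in the 10–12 t ha⁻¹ range of high-input summer
maize; plant/ear heights centred on hybrid catalogue ranges at 260/104 cm;
moisture 25%, ear length 17.5 cm, 15.4 ear rows, bare tip 1.2 cm, 180 g
grain per ear, 32 g per 100 seeds).

**Weather** (`simulate_weather()`) is, per variable and location, a
sinusoidal seasonal mean peaking in mid-July plus AR(1) daily noise
(autocorrelation 0.7), with constant per-archetype offsets. The four default
archetypes emulate the contrasts that matter downstream — warm/wet,
warm/high-longwave, dry/high-VPD/wide-diurnal-range, and cool — at
latitudes 31.7–37 °N, and the default 10 locations split 1/3/4/2 across
them. Physicality is enforced by construction rather than by clipping
after the fact: temperatures derive from a mean and a positive diurnal
range; the dew point is the air temperature minus a positive depression
(hence VPD ≥ 0 and RH ∈ (0, 100]); shortwave radiation is a clearness
fraction in [0.25, 0.75] of the computed extraterrestrial radiation, which
also keeps the Ångström inversion inside [0, N]. The AR(1) noise gives the
typology realistic day-to-day persistence, and the archetype offsets give
cluster-recovery tests a controllable separation (`noise_scale = 0` makes
same-archetype locations identical; offsets ≫ noise make the k = 4
delineation recover the archetypes exactly, which the tests assert via the
adjusted Rand index).

What the generator does **not** emulate: real spatial trends within fields,
trait-trait genetic correlations (each trait's effects are independent),
non-normal effect distributions, storm/heat-wave event structure, or any
actual geography. Passing tests therefore demonstrate the pipeline's
correctness and statistical calibration under its own assumptions, not
agronomic validity for any particular region.

## 8. Numerical choices and degenerate inputs

* Variance estimates at the REML boundary are exact zeros, matching
  convention; with few factor levels (e.g. two years) constrained REML has a
  positive truncation bias for that term's variance — a property of the
  estimator, quantifiable with `varcomp_recovery()`.
* Kernel distances clip tiny negative squared distances (rounding) to zero;
  PSD is asserted at eigenvalue ≥ −10⁻⁸.
* Duplicate environments merge at height 0 and always co-label; delineation
  is invariant to input order up to label names.
* Quantile breakpoints are deduplicated before classing, so constant
  covariables produce a single occupied class.
* Degenerate rescaling (no spread) yields 50s; a singular trait correlation
  matrix falls back to a pseudo-inverse; an all-equal eigenvalue spectrum
  retains one factor.
* All randomness flows from one seed, fanned out per stage, so every run —
  including CSV output — is byte-reproducible.

## 9. Problem sizes used in the tests

The shipped test-suite and acceptance checks run the full default design
(26 genotypes × 10 locations × 2 years × 3 blocks; 20-year weather archive)
where the quantity under test depends on it, and smaller layouts (e.g. 8 × 4
× 2 × 2) where it does not. Monte-Carlo properties use 100–200 replicates:
REML parameter recovery at 200 trials of the full design, factor-count
recovery at 200 tables of 100 genotypes, and selection-property simulations
at 100 replicates — sizes at which the Monte-Carlo error of the checked
summaries is well below the asserted tolerances.

## 10. Known limitations

* The delineation depends on the chosen `k`; with 10 environments any
  internal cluster-count criterion is noisy, hence the deliberate absence of
  automation.
* REML variance components for terms with ≤ 2 levels (year, ME × year) are
  weakly identified; their LRT p-values are conservative and their
  point estimates carry boundary bias (see Section 8).
* The MPS rescaling is relative to the analysed genotype panel: indices are
  not comparable across panels or MEs, only ranks within one panel-ME are.
* The factor-analytic index assumes the MPS correlation structure is
  meaningfully low-rank; with near-independent traits the eigenvalue rule
  may retain a single weak factor, and the index degrades toward an
  equal-weight compromise.
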