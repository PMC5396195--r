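---
title: "Methods: pollen-based pesticide risk metrics and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen-based pesticide risk metrics and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenrisk)
```

# The problem

Honey bee colonies rented into mass-blooming crops collect pollen from
the focal crop and from whatever else flowers nearby, and the pollen
they pack into comb (beebread) carries pesticide residues from both.
This package implements a site-level risk assessment for that exposure
pathway: hazard quotients from residue screens of beebread, a
spray-record index of on-farm pesticide use, regulatory classification
of exposures, pollen-composition metrics that describe where the pollen
came from, and landscape predictors of foraging — plus a calibrated
generator of synthetic studies for validating the whole chain.

# Hazard model and assumptions

The **Pollen Hazard Quotient** for one compound is the residue
concentration in ng/g pollen divided by the honey bee LD50 in µg
a.i./bee, with contact and oral LD50s treated as separate routes. The
quotient deliberately mixes units (its fields' convention); the
package keeps it raw and confines all unit handling to the conversion
below. Site totals sum quotients over detected compounds, which
encodes the first modelling assumption:

1. **Additivity.** Compounds act additively; synergism (for example
   between ergosterol-biosynthesis-inhibiting fungicides and
   pyrethroids or neonicotinoids) is documented in the ecotoxicology
   literature and would make these totals underestimates. It is out of
   scope here.
2. **Bee mass 100 mg** (`exposure_params(bee_mass_mg = 100)`).
3. **Acute contact = one body-weight equivalent of pollen** (100 mg)
   contacted over the span of a laboratory contact-LD50 study. The
   window is modelled as a single dose, not a per-day rate.
4. **Chronic oral = 9.4 mg pollen/day for 10 days**, the median
   mass-bloom pollination period, matching a 10-day LC50 exposure.

Under these, `pct_of_ld50()` maps a total PHQ to percent of LD50 as
`PHQ × contact_mass[g] / 10` (contact) and
`PHQ × intake[g/day] × days / 10` (oral): ppb times grams of pollen
gives ng of pesticide, ÷1000 gives µg, and the LD50 is already in the
quotient. At the defaults the contact factor is 0.01 and the oral
factor 0.0094 percent per PHQ unit.

**Levels of concern** (`loc_thresholds()`): EPA Tier 1 acute-contact
risk quotient 0.4; EFSA acute-contact ETR 0.2; EFSA chronic-oral ETR
0.03. Each is evaluated independently and flags only on *strict*
exceedance of the exposure fraction, so boundary equality does not
flag. Inverting the conversion, the flags flip at total contact PHQ
4000 (EPA), 2000 (EFSA acute) and total oral PHQ 0.03/9.4e-5 ≈ 319.15
(EFSA chronic); the conversion is written as a single
multiply-and-divide so these boundaries are exact in floating point.

**Missing LD50s** (oral values are unavailable for abamectin, atrazine
and fenbuconazole in the bundled panel) are kept as `NA`. A detected
compound without a route LD50 contributes nothing to that route's
total and is listed in the site's `skipped_*` columns — substituting 0
would hide hazard, substituting infinity would fabricate it.

The **Pesticide Use Index** sums `(1/contact LD50) × (%ai/100) ×
app_rate` over during-bloom applications. `%ai` is read on a 0–100
scale and the application rate in kg product/ha; both are otherwise
unitless in the index's definition, so the conventions are fixed here
and documented. Multiple applications of the same compound accumulate
(it is an index of *use*). Events whose compound lacks a contact LD50
are skipped with a warning.

**Spray attribution.** A compound is "sprayed" at a site only if a
during-bloom application of it exists in that site's records; the
non-spray fraction of a site's hazard is the share of total PHQ from
all other compounds, defined as 0 when the total is 0. Sites with
residues but no spray records at all attribute everything to non-spray
sources.

# Pollen and landscape conventions

The sporadic-pollen rule pools morphotypes that never reach 3%
relative abundance on any slide into an `"other"` category. The
definition leaves exact equality ambiguous; the package retains at
`>= 3%`. Richness counts retained morphotypes with positive counts per
site; the sporadic pool never counts. The focal-crop fraction is the
focal morphotype's share of all grains regardless of retention.

Buffer composition uses cell-center-in-circle membership on the 30 m
grid — deterministic, exactly reproducible by enumeration, and
accurate to the cell size for the 1–3 km radii involved. All group
percents share one denominator (in-buffer non-NODATA cells). Whether
focal-crop cells also count as agricultural is a flag (default `TRUE`,
since orchards are cropland); with the flag off the four groups
partition the buffer and sum to 100.

Scale selection fits one simple regression of the response on each
landscape predictor at each radius and picks the radius minimising the
*summed* Gaussian AIC over the predictors — the most literal reading
of choosing the scale at which the landscape variables jointly fit
best; per-predictor selections are available in the returned table.
Ties (ΔAIC < 1e-8) go to the largest radius, the more conservative
foraging envelope.

The regression engine itself is written from the normal equations so
its conventions are pinned: `F = R²/(1−R²)·(n−2)` with df (1, n−2),
p from the F distribution, and `AIC = n·log(RSS/n) + 2k` with k = 3.
The additive Gaussian constant is omitted consistently; only AIC
differences are ever used. Degrees of freedom always come from the
rows actually present, so analyses with a dropped site report (1, 27)
rather than a hard-coded (1, 28). An exact fit (RSS = 0) yields
R² = 1, infinite F, p = 0 and AIC = −∞, which dominates model
selection as it should.

# The synthetic generator

`generate_study()` draws a complete study from one master seed, with
an independent sub-stream per component (landscape, pollen, sprays,
residues, grid) so changing one component never perturbs the others.
Defaults emulate a 30-site orchard system:

- **Landscape.** Focal-crop (apple) area fractions follow a fixed
  gradient `seq(0.005, 0.35)` shuffled across sites — the 0–35% range
  the analysis is designed to span — with the remaining cover split
  among natural, other-agricultural and other classes. The optional
  raster realises each site's composition i.i.d. within its own 6.3 km
  tile, so a 3 km buffer recovers the intended fractions to within
  binomial noise (< 0.3 percentage points).
- **Pollen.** The latent focal-pollen fraction is
  `0.01 + 0.55 × apple_area + ε`, clamped to (0.001, 0.95), giving a
  mean focal share near 11% — close to the ~9% typical of apple
  pollination. Counts are multinomial over the focal type plus 8–16 of
  19 non-focal morphotypes with gamma-distributed weights, which makes
  realized richness vary between sites.
- **Residues.** Site totals are linear couplings — fungicides to the
  *measured* focal-pollen fraction (`800 + 8000·p̂`), insecticides to
  realized richness (`60 + 9·richness`) — split across compounds with
  gamma weights scaled by the bundled panel's observed mean residues,
  then censored at each compound's limit of detection. The intercepts
  and slopes reproduce the panel's per-site scale (≈1.5 µg/g fungicide
  and ≈150 ng/g insecticide mass) so fungicides dominate residue mass
  while insecticides dominate hazard, and site-level risk straddles
  all three levels of concern with chronic-oral exceedance common and
  acute exceedance rare.
- **Sprays.** 10% of sites spray nothing during bloom; the rest apply
  2–4 fungicides and, at 60% of sites, 1–2 insecticides, with
  ISO-dated events inside a May 7–22 bloom window plus occasional
  pre-bloom events.
- **Never-sprayed contamination.** Each site receives
  `Poisson(2.8)` compounds from the 9-compound pool never sprayed
  during bloom anywhere. A plain Poisson(2.8) already leaves 93.9% of
  sites with at least one (against an intended 28/30 = 93.3%), so no
  truncation is applied. If a site would otherwise carry no
  insecticide residue, one is drawn from the never-sprayed pool so the
  richness coupling stays defined; this nudges the realized novel-
  compound mean slightly above 2.8.

**Noise calibration.** Each coupling's noise SD is solved analytically
from `R² = var(signal) / (var(signal) + var(noise))` using the
realized predictor variance, with two refinements: the population R²
is first adjusted for the finite-sample overfit bias of the fitted
coefficient of determination (`E[R̂²] ≈ ρ² + (1−ρ²)/(n−2)`, inverted),
and the multinomial counting variance of a 300-grain slide is
subtracted from the pollen noise budget since it already sits on the
measured fraction. There are no tuning loops; the calibration is
checked by simulation in the test suite (200 replicates recover the
0.67 and 0.46 targets to within ±0.05 of the mean, and the
richness coupling collapses to R̂² < 0.1 when switched off).

**What the generator does not emulate:** residue covariance between
compounds within a site (independence is assumed), bee foraging
mechanics (couplings are statistical, not behavioural), spatial
autocorrelation between neighbouring orchards, heteroskedastic or
zero-inflated residue distributions, and per-colony variation (the
data model pools 4 colonies per site, as the sampling design does).
Passing recovery tests therefore demonstrates that the pipeline
measures what the generator encodes — not that real orchard data meet
these assumptions.

# Numerical and reporting choices

- Concentrations are ng/g ≡ ppb throughout; LD50s µg/bee; conversions
  live only inside `pct_of_ld50()`.
- A positive concentration below the limit of detection is coerced to
  0 with a warning (the record then counts as a non-detect); the
  coercion is idempotent. How sub-LOD signals should be treated is not
  fixed by the source metric; zeroing is this package's documented
  choice.
- Compound-level summary means are means of *positive detections*
  (0 when never detected). Four rows of the bundled panel's published
  counterpart (iprodione, penthiopyrad, atrazine, trifloxystrobin)
  follow a summed-residue convention instead; the mean-of-detections
  convention is implemented and those rows are excluded from
  printed-precision checks rather than reproduced.
- Reported hazard tables round half away from zero at one decimal
  (`round_half_up()`); internal computation is full precision.
- Dates are ISO-8601 and bloom status is an explicit column, never
  inferred from dates, because bloom windows differ between sites.

# Problem sizes

The test suite exercises: 100 random micro-studies (≤5 sites × ≤5
compounds) against sequential brute-force loops; 200 synthetic
replicates at n = 30 sites for the calibration checks (the acceptance
script repeats this with seeds derived from its `--seed`); 25–60
replicates for the null-coupling and slope-coverage properties; and
buffer enumeration oracles on grids up to 70 × 70 cells. These sizes
keep the full suite under a few minutes on one CPU while leaving the
Monte-Carlo standard error of each calibrated mean near 0.007,
comfortably inside the ±0.05 bands being checked.

# Known limitations

No synergy or potentiation modelling; no NOAEC-based chronic metric
(EPA's chronic route needs no-observed-adverse-effect concentrations
that exist for few compounds); no GLM families beyond the Gaussian
identity; no coordinate-system handling for rasters (grids must arrive
as plain ESRI ASCII in a planar metre system); and the pollen model
supports one pooled slide per site, not per-colony composition.
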