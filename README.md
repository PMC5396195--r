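# pollenrisk

Quantitative pesticide-risk assessment for honey bee colonies providing
crop pollination services, built around residues measured in recently
accumulated beebread (stored pollen). The package is written for
pollinator ecotoxicologists and landscape ecologists who need to turn
per-site residue screens, grower spray records, pollen microscopy
counts and categorical land-cover rasters into regulatory-style risk
summaries and the regressions that connect them.

## The metrics

**Pollen Hazard Quotient (PHQ).** For a compound with residue
concentration *c* (ng/g pollen, i.e. ppb) and a route-specific honey
bee LD50 (µg a.i./bee),

```
PHQ = c / LD50
```

summed additively over compounds at a site, separately for contact and
oral toxicity. Compounds lacking an LD50 for a route are skipped and
flagged, never coerced to zero or infinity.

**Percent of LD50.** Raw PHQs become interpretable exposures under
standard assumptions: a 100 mg bee contacts one body-weight equivalent
of pollen (acute contact), and ingests 9.4 mg pollen/day for a 10-day
pollination period (chronic oral). At these defaults,
`% of contact LD50 = PHQ × 0.01` and `% of oral LD50 = PHQ × 0.0094`.
Sites are flagged against the EPA Tier 1 acute-contact risk quotient
(0.4), the EFSA acute-contact exposure/toxicity ratio (0.2), and the
EFSA chronic-oral trigger (0.03), each evaluated independently with
strict exceedance.

**Pesticide Use Index (PUI).** From spray records,

```
PUI = Σ over during-bloom applications of (1/LD50) × (%ai/100) × app_rate
```

with contact LD50 in µg/bee and application rate in kg product/ha,
optionally restricted to the compound panel quantified in pollen.

**Pollen composition.** Morphotype counts (300-grain slides) yield
relative abundances; morphotypes never reaching 3% relative abundance
on any slide are pooled as sporadic ("other"); richness counts retained
morphotypes per site; the focal-crop fraction (default `Malus`) links
foraging to the landscape.

**Landscape.** Percent natural / agricultural / focal-crop cover inside
1–3 km circular buffers on a 30 m categorical grid
(cell-center-in-circle membership), with the working radius chosen by
Gaussian AIC across simple regressions.

A calibrated synthetic-study generator (`generate_study()`) emulates a
30-orchard system — apple-area gradient, pollen composition coupled to
landscape (target R² 0.67), fungicide residues coupled to focal-crop
pollen (R² 0.46), insecticide residues coupled to pollen richness
(R² 0.12), and ~2.8 never-sprayed compounds detected per site — with a
full ground-truth record for parameter-recovery testing.

## Worked example

```r
library(pollenrisk)

phq_raw(557.1, 0.118)   # indoxacarb: mean residue / contact LD50
#> [1] 4721.186

study  <- generate_study(synth_config(seed = 42))
report <- run_pipeline(study)
report
#> Pesticide risk report: 30 sites
#>   sites above LOC: EPA acute contact 9, EFSA acute contact 13, EFSA chronic oral 19
#>   hazard share from compounds not sprayed during bloom: 59% contact, 82% oral
#>   detected compounds not sprayed at their site: 40%
```

Chronic-oral exceedance is widespread while acute-contact exceedance is
rarer, and most hazard traces to compounds that were never sprayed
during bloom at the site where they were found — the qualitative
signature of risk arriving through non-focal-crop pollen. The
regression table ties the pieces together (here the focal-pollen ~
focal-area fit, a single synthetic realisation of the R² 0.67 target):

```r
dplyr::select(report$regressions, response, predictor, r_squared, f_stat, p_value)[1:3, ]
#>   response         predictor        r_squared f_stat  p_value
#> 1 pct_focal_pollen pct_apple            0.636  48.8   1.34e-7
#> 2 total_residue    pct_apple            0.266  10.1   3.54e-3
#> 3 total_fungicide  pct_focal_pollen     0.296  11.8   1.89e-3

report$scale$radius     # AIC-selected buffer radius
#> [1] 3000
```

`plot_site_risk(report$site_risk, "contact")` draws the per-site
percent-of-LD50 bars split by spray status with the levels of concern
overlaid; `autoplot()` works on any fitted regression.

Real data enter through `read_residues()`, `read_toxdb()`,
`read_sprays()`, `read_pollen()`, `read_sites()` and `read_grid()`
(ESRI ASCII + class map); `run_pipeline(dir, out_dir = ...)` writes the
flat CSV surfaces (`site_risk.csv`, `compound_summary.csv`, `pui.csv`,
`pollen_composition.csv`, `buffers.csv`, `regressions.csv`) plus a
`summary.json`.

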