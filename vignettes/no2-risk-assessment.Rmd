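---
title: "Assessing occupational risk from traffic-related indoor NO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing occupational risk from traffic-related indoor NO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The assessment model

`no2risk` scores the occupational hazard that traffic-derived nitrogen
dioxide poses to hospital staff with a semi-quantitative 3 × 3 risk
matrix. Each sampled indoor location gets two ordinal scores:

* **Likelihood (L)** — how much of the work shift staff spend at the
  location, banded as < 25% (score 1), 25–75% (score 2), > 75% (score 3).
  The denominator is the 6-hour morning shift (08:00–14:00) during which
  sampling takes place; a helper converts minutes present to a fraction.
* **Severity (S)** — the indoor NO₂ concentration, banded by the health
  effects associated with each exposure range: below 500 µg/m³ (score 1,
  minor effects in healthy adults), 500–2000 µg/m³ (score 2, increased
  acute respiratory symptoms and reduced FEV₁), above 2000 µg/m³ (score 3,
  bronchitis, bronchopneumonia, reduced FVC/FEV₁).

The **risk factor** RF = L × S can only take the values
{1, 2, 3, 4, 6, 9} and is categorized *low* (1–2, green), *moderate*
(3–4, yellow), *high* (6, bright red), *very high* (9, deep red). The
model assumes exposure is adequately characterized by a single 6-h
time-weighted concentration per location and shift, and that risk scales
with the product of time-at-location and concentration band — the usual
assumptions of matrix-based occupational risk assessment. No
dose–response modelling is attempted; the clinical descriptions attached
to the severity bands are carried as text only.

### Banding conventions

The outer bands are printed strictly ("< 25%", "> 75%"; "< 500",
"> 2000"), so both middle bands are taken **closed on both ends**: an
occupancy fraction of exactly 0.25 or 0.75 scores L = 2, and a
concentration of exactly 500 or 2000 µg/m³ scores S = 2. This is the only
reading under which the three bands partition their domains with no gaps
or overlaps, and the profile validator enforces exactly that property
(adjacent bands must share an edge with exactly one side closed).

Category labels: "moderate" and "medium" are used interchangeably in this
field's reports; the package canonicalizes on `moderate` and accepts
`medium` as an input alias. RF 3 and RF 4 both map to moderate with no
sub-ordering.

### Bands are configuration, not code

The matrix engine reads its bands, category map and colors from a YAML
profile (`inst/extdata/no2_matrix.yaml`). The engine accepts any N × M
profile whose bands tile their domains and whose categories cover every
reachable product; only the default 3 × 3 profile ships. Studies that
report only a mean concentration, without occupancy data, are scored by
`external_study_rf()`, which pairs the banded severity with both plausible
likelihood assumptions (L = 2 and L = 3); a mean above 2000 µg/m³ thus
yields the RF pair (6, 9), a mean below 500 the pair (2, 3).

## The synthetic campaign generator

No per-measurement data are deposited for the study design the package
emulates, so the generator reproduces it statistically. The design is 4
hospitals — stratified by the traffic congestion of their main street:
heavy (HT, vehicle speed 0–20 km/h), moderate (MT, 20–40 km/h), low
(LT, > 40 km/h), and an on-sea road (OS, also low congestion) — times 2
seasons (hot, cold), with per-cell sample sizes (11, 11, 9, 9, 7, 7, 11,
11), 76 measurements in all. Each cell carries a published mean, SD,
minimum and maximum of the indoor concentration.

### Distributional family and calibration

Cell concentrations are drawn from a **truncated normal** on the cell's
[min, max]: the published analysis found concentrations consistent with
normality, and the printed hard extremes make plain normals inappropriate.
Naively drawing from `N(mean, sd)` and truncating would bias the realized
mean toward the interval's centre (about 5 µg/m³ for the heavy-traffic
hot-month cell, whose mean sits well below the midpoint of [770, 930]), so
the parent parameters are **moment-calibrated**: a nested root solve finds
`(mu, sigma)` such that the truncated distribution's mean and SD equal the
targets (inner 1-D solve for `mu` at fixed `sigma` — the truncated mean is
strictly increasing in `mu` — and an outer solve over `sigma`). Matched
moments are accurate to a relative tolerance of 1e-9.

### Feasibility of the published SDs

On a bounded interval the truncated-normal family's SD has a supremum: as
`sigma` grows the family tends to an exponentially tilted uniform, so no
member exceeds `(max − min)/sqrt(12)` (the untilted uniform's SD), and at
a fixed off-centre mean the supremum is lower still. Checking the eight
design cells against this bound shows that **seven of the eight published
SDs are unattainable** on their own [min, max] (e.g. SD 5.00 on
[360, 370] with mean 363.33, where even the best two-point distribution
caps at 4.71 — that cell's printed summary is internally inconsistent for
*any* distribution). The published summary statistics, taken jointly, are
therefore mutually inconsistent at small n, which is not unusual for
rounded printed tables.

The package resolves this by separating the two contracts:

* `calibrate_truncated_normal()` keeps the strict contract — an
  unattainable SD raises a calibration error — because a silent
  approximation would be wrong for general use;
* the campaign generator calls it with `on_infeasible = "nearest"`, which
  **matches the mean exactly** and takes the SD to the family's practical
  supremum (`sigma` capped at five interval widths, where the attained SD
  is within a percent or two of the limit). The cell means and the hard
  [min, max] bounds — the quantities the assessment's conclusions rest
  on — are thus reproduced exactly in expectation, while realized SDs for
  the infeasible cells fall below the printed values by construction.

### Sampling and seeding

Draws use the inverse-CDF transform. Heavily tilted calibrations place the
interval far in one tail of the parent, where CDF values collapse to 1 in
double precision, so the quantile transform is computed in whichever tail
keeps probabilities representable, and draws are clamped to [min, max] so
floating error can never leak a value outside the interval (every draw is
hard-checked in the tests). Each cell has its own RNG substream seeded
deterministically from (seed, hospital, season) — a Lehmer step spreads
the user seed over the 31-bit range before a positional hash of the cell
key is added — so scenario row order cannot affect the draws and one
integer seed reproduces a campaign bit-exactly.

Occupancy fractions are attached by label through the **occupancy rule**:
continuous-care clinical areas (clinics, patient rooms, emergency rooms,
intensive care units, operation rooms) get 0.9 of the shift,
administrative offices, pharmacies and laboratories get 0.5. These two
values are a deliberate simplification — staff rosters were not published
— chosen to put clinical areas firmly in the "very likely" band and
support areas in the middle band.

### What the generator does and does not emulate

It emulates the design's cell structure, sample sizes, central tendency
and hard ranges, and the strong concentration–congestion gradient. It does
**not** emulate within-day traffic dynamics, room-to-room spatial
correlation, outdoor–indoor transfer physics, meteorology, or measurement
error of the colorimetric analysis; cells are sampled independently.
Passing tests therefore demonstrate that the pipeline reproduces the
published aggregate findings under the stated design, not that it would
reproduce raw field data.

## The risk-table fixtures

The per-location risk tables of the original assessment were published
only as figure images, so `build_risk_fixture()` ships deterministic
**reconstructions**: for each cell, locations with evenly spaced
concentrations across the cell's band, clinical/support labels, and
occupancy per the rule above, with the clinical count per cell chosen so
that scoring the fixture reproduces the published category shares exactly
— high risk in 72.7% (8/11) and 63.6% (7/11) of heavy-traffic locations
in hot and cold months, moderate risk in 77.8% (7/9), 57.1% (4/7) and
54.5% (6/11) of moderate-traffic, on-sea and low-traffic locations in
both seasons. They are labelled reconstructions, not data.

One published inconsistency had to be resolved: the heavy-traffic
hospital's risk factors are reported as ranging 4–6 in *both* seasons,
yet its cold-month concentration minimum is printed as 490 µg/m³, which
bands to severity 1 and cannot yield RF ≥ 4 for any likelihood but 3 (and
then RF 3). The fixture therefore uses concentrations in [500, 600] for
that cell — every location banding to severity 2 — while the campaign
generator honors the printed minimum of 490. The two surfaces serve
different purposes (category-share reproduction vs summary-statistic
reproduction), and splitting them keeps both faithful.

## The statistical battery

* **Normality**: one-sample Kolmogorov–Smirnov against a normal with the
  sample's own mean and SD. Because the parameters are estimated from the
  same sample, p-values are approximate (anti-conservative relative to a
  Lilliefors correction); they are used as a consistency screen, not an
  inferential endpoint.
* **Seasonal contrasts**: Student's pooled-variance t-tests (the variant
  matching the published "equal variances" analysis), computable directly
  from summary statistics; Welch is available behind `var_equal = FALSE`
  but is not the default.
* **Between-hospital variation**: classical one-way ANOVA, followed by
  **Fisher LSD** pairwise comparisons using the ANOVA pooled error term
  and residual degrees of freedom, uncorrected for multiplicity — that is
  the procedure's definition, and no multiple-testing correction is
  applied anywhere, mirroring the analysis being reproduced.
* **Congestion correlations**: Spearman rank correlation with average
  ranks for ties and asymptotic two-sided p-values (the congestion coding
  is heavily tied, so exact p-values are unavailable anyway). The ordinal
  coding HT = 3, MT = 2, LT = 1, OS = 1 is an assumption — the original
  coding was not published — exposed as the `congestion_coding` argument;
  the on-sea road is coded with low congestion because that is how its
  traffic is described.

Significance is decided at α = 0.05 throughout (`significant` is defined
as p ≤ α, and every result row carries its α).

## Numerical and reporting choices

* Percent shares are rounded **half away from zero** to one decimal
  (8/11 → 72.7, 7/9 → 77.8); base R's round-half-even would disagree on
  exact halves.
* Degenerate inputs: zero-variance samples are rejected by the KS test;
  singleton groups are rejected wherever a sample SD is needed; an
  all-one-rank congestion vector raises an undefined-correlation error
  rather than returning NA.
* Reports (Markdown, CSV, JSON) are rendered with a dependency-free
  fixed-format table writer and emit colors as plain text tokens, so a
  fixed seed yields byte-identical report files.
* Test problem sizes: the parameter-recovery checks use 300–1,000
  replicate campaigns (76 draws each) and the battery checks 100
  replicates — large enough that the 3-standard-error and
  replicate-majority criteria are stable, small enough to keep the suite
  quick.

## Known limitations

* The matrix is ordinal; RF differences are not effect sizes, and no
  health outcome is predicted.
* Raw-sample conversion applies no desorption/collection-efficiency
  factor (the analytic constants of the colorimetric method are not
  modelled); concentrations are simple mass-per-volume.
* Fixture occupancy assignments and the congestion coding are documented
  reconstructions/assumptions constrained by published aggregates, not
  recovered data.
* For the seven infeasible-SD cells the generator's realized SDs are
  below the printed values (see above); any analysis that leans on those
  cell SDs inherits this.
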