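---
title: "Methods: fire-regime reconstruction and Callitris demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fire-regime reconstruction and Callitris demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firemosaic)
```

## The problem

Northern Australian savannas burn almost annually, yet the fire-sensitive
conifer *Callitris intratropica* — an obligate seeder with no resprouting and
no persistent seedbank — persists there in small closed-canopy groves that
suppress grass and exclude fire. Its population structure is therefore a
sensitive bio-indicator of fire-regime change: regimes dominated by frequent,
extensive fires erode groves, kill juveniles, and leave landscapes of dead
stems and isolated survivors.

`firemosaic` implements the quantitative toolkit for this kind of study:

1. **Burn mapping** from seasonal surface-reflectance composites via the
   differenced normalized burn ratio (dNBR);
2. **Time-since-fire (TSF) grids and long-unburnt patch mosaics**;
3. **Pre/post-intervention regime statistics** with the standard transforms;
4. **Stand demography**: size classes, transect densities, stand status, and
   annualized survival;
5. **Establishment dating** from ring-width series with pith and
   sample-height corrections;
6. **Grass-fuel comparison** by quantile regression with AIC model choice;
7. A **Markov patch-dynamics simulator** of the grove mosaic.

Every input has a seeded synthetic generator with known ground truth, so the
full pipeline is testable end to end without satellite or field data.

## Burn mapping

NBR is `(NIR - SWIR) / (NIR + SWIR)` on surface reflectance; it drops sharply
when vegetation burns. Seasonal dNBR is the NBR difference across a
burn-detection interval: early dry-season fires show between the March–May
and June–August composites, late fires between June–August and
September–November. From each year's seasonal dNBR the all-year mean of that
season is subtracted cellwise. This mean adjustment provably removes any
static per-cell landscape feature (a constant field cancels exactly) and
increases contrast. Cells whose anomaly is **strictly greater than 0.75**
dNBR units are classed as burnt; nodata cells are unburnt.

Two conventions deserve note, both config-exposed:

* the band formula for NBR is fixed as above (reflectances in [0, 1]); and
* the 0.75 cutoff is applied to the **mean-adjusted anomaly** (the stated
  pipeline order), with `apply_cutoff_to = "raw"` available for the
  alternative reading.

The season calendar follows the composite windows (early: MAM→JJA, late:
JJA→SON). Calendar-month definitions of "early"/"late" that differ by a month
or so exist in the literature; the window pairing is the operational
definition here because it is what the composites can support.

A consequence of mean adjustment worth keeping in mind: a cell that burns in
`k` of `Y` record years retains an anomaly of only `A(1 - k/Y)` for a fire
signal of amplitude `A`. Detection of an amplitude-1.0 fire at cutoff 0.75
therefore requires the cell to burn in fewer than a quarter of record years.
The synthetic generator defaults to 20-year records so that typical scars
(1–4 burns per cell) sit comfortably above the cutoff, which mirrors the
multi-decadal records this method is designed for.

## Time since fire, patches, and regime summaries

TSF at a query year is the number of years since the most recent detected
burn in any season (0 in a burn year). Cells with no burn on record are
right-censored at the record length `k = query year - first record year` and
carry that bound as their value plus a censored flag. TSF is only evaluated
once at least five years of history precede the query year.

Long-unburnt patches are connected components (8-neighbour by default, 4
available) of cells with TSF **strictly greater than** 5 years inside the
analysis mask. Censored cells count as long-unburnt: once the record exceeds
five years they necessarily satisfy the age condition. Patch area is cell
count × cell area; the annual regime summary reports proportions burnt early,
late and total (the **union** of the seasonal masks), mean TSF (censored
cells entering at their bound, i.e. a lower bound on the true mean), the
long-unburnt proportion, and mean patch size.

Gridded data are plain matrices inside light S3 containers with explicit
origin/cell-size georeferencing; file interchange uses the plain-text ESRI
ASCII grid format, and polygons (footprints, analysis masks) are rasterized
by the **center-point rule**: a cell belongs to a polygon iff its center
falls inside.

## Pre/post-intervention statistics

Annual values are split into pre- and post-management periods at the site's
commencement year (Dukaladjarranj 2006, Kakadu 2007; the threshold year
itself counts as post, since commencement-year burning is management
burning). The long-unburnt proportion uses a five-year-lagged threshold
(2011/2012) because the long-unburnt class cannot respond faster than the age
cutoff; the lagged years map to the sites in the same order as the
commencement years. Each variable is fitted by OLS on the two-level period
indicator — algebraically the equal-variance two-sample t-test — after its
standard transform: mean TSF untransformed, mean patch size log-transformed,
proportions arcsine-square-root transformed. Proportions exactly 0 or 1 are
transformed as-is (asin is defined there); no continuity correction is
applied. Years are entered individually, not as period means.

## Demography

Two size-class schemes coexist in the field protocols and both are
implemented: the transect scheme (seedling < 0.1 m, sapling 0.1–2.2 m, then
trees by diameter at 1 m: < 10, 10–20, 20–30, ≥ 30 cm) and the longitudinal
scheme (juvenile < 1.5 m, then < 5, 5–10, 10–20, 20–30, ≥ 30 cm). All
diameter intervals are lower-inclusive/upper-exclusive, which resolves the
overlapping printed boundaries (a 10 cm stem is "medium").

Transect densities divide per-segment counts by the class-specific sampled
band — seedlings are searched only within 2 m of the midline, everything else
across the full 25 m half-width — and the mean and standard error are taken
**across segments**, the replicated unit.

Annualized survival is `(N2/N1)^(1/y) × 100`, reported to one decimal;
missing individuals are counted dead. In the per-class analysis, class
membership is frozen at the tagging census (no promotion), matching how
longitudinal survival is reported by size class at tagging.

Stand status per 100-m segment is qualitative in field usage; the package
ships an explicit numeric default rule (juveniles-only = `new`; 1–2 stems,
majority live, < 3 juveniles = `singleton`; ≥ 3 live stems spanning ≥ 3
classes with live > dead = `healthy`; dead ≥ live but ≥ 3 juveniles =
`recovering`; otherwise `degraded`; empty segments are `absent`). Every
threshold is caller-adjustable and the applied thresholds are recorded in
each result, because a reproducible classification needs an operational rule
even where field usage is descriptive.

Indicative ages convert diameter to age assuming 2.5 mm/yr diameter growth
above 1 m height plus the seedling time to reach 1 m from the height-age
curve; rounding to the nearest decade gives the survey age-class boundaries
(10 cm → 60 y, 30 cm → 140 y).

## Establishment dating

The juvenile height-increment regression (OLS of annual increment on initial
height, with AIC support against the intercept-only model) underlies the
height-age curve

```
age = -2.1 + 2.024 * sqrt(height_cm)
```

clamped below at 0 (heights under the curve's root, ≈ 1.08 cm, map to age
0). The curve is kept unrounded; rounding to whole years happens **once**, at
composition time. For samples that missed the pith, the missing inner rings
are estimated as distance-to-pith divided by the mean width of the five
innermost measured rings (all available rings, with a warning, when fewer
than five exist). Establishment year is then

```
establishment = innermost ring year - pith offset - round(age at sample height)
```

and is rejected if internally inconsistent (after the series end).
Establishment years are binned into closed-open calendar decades per
transect segment, each segment carrying the limit of its dendrochronological
record (the earliest innermost ring year among its samples). Cross-dating is
consumed, not performed: calendar years in the input are trusted. Ring-width
files use the Tucson decadal format; both the 999 (0.01 mm) and −9999
(0.001 mm) terminator dialects are auto-detected on read.

One known inconsistency in the source material for the height-increment
model: the printed slope (0.773) is an order of magnitude larger than the
printed mean increments imply (≈ 0.0773 at a 29.5 cm mean initial height).
The fitting function takes no position — it fits whatever the data yield —
and the synthetic generators do not depend on the increment model at all.

## Grass fuels

Dry load is `fresh × (1 - moisture) / area` (g m⁻²). Regional comparison
uses quantile regression at the 0.90 and 0.50 levels, minimizing the check
loss `rho_tau(u) = u(tau - 1[u < 0])`; upper quantiles are the quantity of
interest because fuel loads are strongly heteroscedastic between regions.
For the one-factor region design the exact minimizer is the per-region
type-1 sample quantile, and the implementation uses that closed form; tests
verify check-loss optimality against a grid-search oracle on every small
instance. Confidence intervals are seeded case-resampling bootstrap
percentile intervals (default B = 2000) — chosen over rank inversion for
implementation transparency. Model support is `ΔAIC = AIC(null) -
AIC(region)` with `AIC = 2k + 2n log(check loss / n)`, the
asymmetric-Laplace working likelihood with the scale profiled out; AIC is
not uniquely defined for quantile regression, so the adopted form is stated
and used consistently on both sides of every comparison. A perfect
(zero-loss) fit maps to `-Inf` AIC, which only arises on degenerate
constant data.

## Patch-dynamics simulator

The grove mosaic is modelled as independent patches on a six-state Markov
chain (`healthy`, `degraded`, `recovering`, `singleton`, `new`, `absent`)
whose transition probabilities depend on an annual patch burn probability
`f ∈ [0, 1]`. The shipped default parameterization scales every degradation
pathway with `f` and every recovery pathway with `1 - f`, holding the
intermediate self-transitions constant, so that transitions toward
`degraded`/`absent` are nondecreasing in `f` and transitions toward
`healthy`/`recovering`/`new` nonincreasing — which guarantees equilibrium
grove occupancy falls monotonically with fire frequency. At `f = 1` the
`absent` state is absorbing and reachable from every state: the chain
reproduces, qualitatively, a landscape-scale grove collapse. The default
numbers are **illustrative**: no field-calibrated transition probabilities
exist, so all conclusions drawn from the simulator are property-based
(monotonicity, absorption, stationarity), never quantitative predictions.

Stationary distributions are computed by power iteration on the lazy chain
`(P + I)/2` (same stationary law, aperiodic, hence convergent even for
periodic inputs) to a 1e-12 tolerance, with reducible chains flagged. Patches
are independent — no spatial contagion — because the conceptual model is
drawn at patch level; a neighbour-coupling extension would change the
container, not the chain.

## The synthetic generators: what they emulate, and what they do not

All generators are pure functions of their scenario (including its seed);
sub-streams derive from the scenario seed by a fixed splitting rule, and the
global RNG state is restored afterwards.

* **Fire landscapes** are built backwards from the target dNBR: within each
  year the MAM composite carries a baseline NBR (default 0.4, encoded into
  NIR/SWIR bands summing to 0.8) and each later window drops by the static
  field plus that interval's fire signal, so the seasonal dNBR equals
  `static + amplitude × footprint + noise` exactly. Footprints are polygons
  rasterized by the center-point rule; per-composite noise is scaled so the
  dNBR noise has exactly the scenario's standard deviation. Scenarios whose
  implied NBR leaves [−1, 1] are rejected rather than clamped, preserving
  exactness. This emulates signal, static features and noise — not
  reflectance physics, phenology, clouds, or sensor artefacts.
* **Tree populations** use a Thomas-type cluster process (Poisson parents,
  Poisson offspring counts, isotropic Gaussian dispersal) plus independent
  singletons, reproducing the grove/singleton dichotomy; dimensions are drawn
  uniformly within each class's bounds. Real groves are multi-aged and
  spatially anisotropic; none of that is claimed.
* **Survival histories** are per-individual annual Bernoulli chains (dead
  stays dead) with class-specific rates; the defaults use the annualized
  rates the longitudinal study reports, with census years 2006–2019.
* **Ring series** invert the dating pipeline exactly: innermost ring year =
  establishment + rounded height-age + pith offset, with lognormal widths and
  a distance-to-pith consistent with the five-ring pith estimator. Ring-width
  series carry no climate signal; cross-dating is out of scope.
* **Fuel samples** draw dry loads from per-region lognormals (the stated
  median with a region-specific `sdlog` for the upper tail; defaults 71 and
  112 g m⁻² with sdlog 0.5/0.8, echoing the contrast between a traditionally
  managed estate and a depopulated park) and back-compute fresh weights
  through a uniform moisture fraction (default U(0.2, 0.5)), so the
  dry-weight conversion inverts the generator exactly.

Passing tests on these generators demonstrate the **arithmetic and
inferential machinery** — recovery of known truth under the stated noise
model — not that real Landsat composites or field censuses obey the
generators' distributional assumptions.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-denominator NBR cells are
nodata; constant responses give slope 0, r² 0, p 1; zero check loss gives
−Inf AIC; empty segments are `absent`; empty masks are rejected. Oracle
tests run at sizes where brute force is exact and fast (20 × 20 grids,
two-group quantile fits with n ≤ 12, 6-state chains), and stochastic
recovery checks use a few hundred seeded replicates with binomial-band
tolerances — sizes chosen so the whole suite exercises every pipeline stage
in well under a minute of compute while keeping Monte-Carlo error far below
the asserted tolerances.

## Known limitations

* Fire severity is deliberately not mapped (the underlying index cannot
  support it in these savannas); no cloud masking or cross-sensor
  calibration.
* The regime statistics are plain linear models on annual values; no
  autocorrelation-aware or mixed-effects structure.
* Quantile fits include region only; plot/segment grouping is not modelled.
* The patch simulator is state-based, not spread-based, and uncalibrated.
* The synthetic fire scenes cannot represent a cell burning in both seasons
  of one year at full amplitude without leaving the physical NBR range; such
  scenarios are rejected.
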