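---
title: "Partitioning uncertainty in ensemble biodiversity scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning uncertainty in ensemble biodiversity scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A biodiversity scenario chains several models: a statistical species
distribution model (SDM) fitted to presence/absence data under current
climate, a global circulation model (GCM) supplying future climate fields,
a representative concentration pathway (RCP) driving the GCM, and an
assumption about how far species can disperse. Each link is a subjective
choice, and different choices give visibly different futures. `bioscen`
treats those choices as factors of a designed experiment: it projects every
retained SDM onto every (GCM, RCP, horizon) climate layer under two
dispersal assumptions, summarises each projection with sensitivity metrics,
and attributes the variability of each metric to the factors with a nested
analysis of deviance.

Real analyses of this kind consume global range polygons and downscaled
climatologies. Those inputs are deliberately out of scope here: the package
instead simulates a planar world with virtual species whose environmental
responses are known exactly, which makes every stage of the pipeline
verifiable against ground truth. The pipeline itself — training-set
assembly, validation, thresholding, projection, metrics, partitioning — is
the same code a real-data study would run once the inputs are gridded.

## The synthetic world

The world is a flat equal-area lattice (default 100 km cells; distances are
Euclidean between cell centres, with no wrap-around). Four bioclimatic
variables are generated as planar gradients plus spatially autocorrelated
Gaussian noise: annual mean temperature (°C), annual temperature range
(°C), annual precipitation sum (mm) and precipitation seasonality (CV, %).
The two precipitation-like variables are clipped at zero. The generator
makes no claim of matching real-world marginal distributions; what it
provides is a smooth, controllable climate surface with known structure.

Future climate layers follow the delta-change convention: temperature
variables receive additive shifts, precipitation variables multiplicative
ones. Each layer is

* a monotone RCP signal — `rank × rcp_severity_step × period_scaling`,
  where rank is the RCP's 1-based position in severity order, so emission
  severity is ordered by construction;
* a GCM-specific deviation field, drawn once per GCM and reused across
  RCPs and periods (so "GCM" is a coherent factor, as in a real CMIP5
  ensemble): a scalar offset with standard deviation `gcm_sd` plus a
  smooth zero-mean spatial pattern, which makes the between-GCM variance
  of spatially averaged warming equal `gcm_sd²` — a property the tests
  verify by Monte Carlo;
* optional independent per-layer noise (`noise_sd`, default 0).

The default scenario design mirrors the unbalanced structure of real
ensembles: 5 GCMs × 4 RCPs restricted to 14 combinations (all GCMs ran the
two middle-of-the-road and severe pathways, only two ran each of the
others), over two 20-year horizons with the later horizon scaled by 1.3.
Defaults of `scenario_effects()` (e.g. 1.1 °C per RCP rank for mean
temperature, `gcm_sd` 0.45 °C) were chosen so that the most severe
scenario's shift is several times a typical niche breadth — future climate
is genuinely novel for most species — while GCM spread stays a fraction of
the RCP signal, the qualitative ordering real ensembles show.

Virtual species have independent 4-D Gaussian niches: suitability is the
product over variables of `exp(−(x − optimum)² / (2 breadth²))`. Optima are
climates of randomly chosen anchor cells (jittered), breadths a random
fraction (0.25–0.6 by default) of each variable's spatial standard
deviation. The true range is the suitability quantile exceeding the
species' drawn prevalence target (5–30% of cells by default), and species
with fewer than 20 presence cells — the minimum for fitting response curves
to four predictors — are re-drawn or dropped with a warning. Independence
of niche axes is a deliberate simplification: it keeps the true response
available in closed form for recovery tests. Sub-regions are contiguous
rectangular blocks tiling the grid, a stand-in for policy reporting units.

What passing tests on this world do **not** show: robustness to spatially
biased sampling, range-map error, correlated predictors, or non-Gaussian
responses. The world is a correctness harness, not a realism claim.

## The SDM ensemble

Four algorithm families are fixed: GLM (linear + quadratic terms), GAM
(smooth terms, small basis `k ≤ 5`), gradient-boosted trees (80 rounds,
depth 3, learning rate 0.1) and random forest (150 trees). Hyperparameters
are modest and logged; none are tuned per species.

Pseudo-absences are sampled uniformly without replacement from the cells
within the taxon's buffer of the range but outside it — sampling from a
geographic neighbourhood rather than the whole world avoids inflating
accuracy with trivially alien climates. The default count is
`min(10 × presences, all buffer cells)`, bounding class imbalance; the
count is configurable because the choice is genuinely open. One absence
sample is drawn per species; the random 70/30 calibration/evaluation split
is re-drawn per repetition (shared across algorithms within a repetition),
giving four split-sample repetitions treated downstream as replicate runs,
not as a design factor (their incremental explained deviance is checked to
be under 1% on exchangeable tables).

The taxon → buffer mapping (amphibian 2000 km, mammal 3000 km, bird
4000 km) serves both absence sampling and the limited-dispersal domain, and
is configurable — domain knowledge could justify other orderings, so the
mapping is a parameter rather than a constant.

Binarisation is the TSS-maximising cutoff on the evaluation split — the
standard choice in ensemble platforms, and the natural companion to a
TSS-centric evaluation. Candidate cutoffs are the unique scores plus
midpoints between consecutive scores; ties break to the smallest cutoff;
constant scores return 0.5 with a warning. Retention thresholds of 0.4,
0.6 and 0.7 on the hold-out TSS are compared side by side; raising the
threshold can only shrink the retained set, so all three record sets derive
from one fitted ensemble. Single-class splits and hard fit failures are
dropped and logged, never imputed — downstream engines must and do tolerate
the resulting unbalanced design.

## Sensitivity metrics

With suitable "area" = suitable cell count (the grid is equal-area):

* **CCS** (change in climatic suitability, limited dispersal):
  `(future − current)/current` suitable cells, both maps restricted to the
  dispersal domain. Undefined when the current count is zero; such records
  are flagged, excluded, and counted.
* **LCS** (loss in climatic suitability, no dispersal): fraction of
  currently suitable cells that become unsuitable. The denominator is the
  model's *currently suitable cells within the current range* rather than
  the raw range, because the metric contrasts two projections of the same
  model pair; when the future map is restricted to that same set,
  CCS = −LCS exactly, an identity the tests assert.
* **Δα** per pixel: percent change in stacked species richness (limited
  dispersal); **% loss** per pixel: percent of currently present species
  lost (no dispersal); **βt** per pixel:
  `(lost + gained)/(richness + gained)` (limited dispersal), 0 iff the
  community is unchanged and 1 iff nothing persists.
* **Δβs** per sub-region: the wording "percent change in total diversity
  per sub-region divided by the mean α-diversity" admits two readings. The
  default treats it as the relative change of Whittaker's multiplicative
  turnover β = γ/ᾱ, because "change in spatial turnover" names a
  β-diversity quantity; the literal reading (percent change of γ, then
  divided by current ᾱ) is retained behind `semantics = "literal"`. No
  worked value exists to disambiguate, so both are first-class.

All zero-denominator cells propagate as missing and are excluded from
partitioning with logged counts. Pixel metrics are computed from per-model
maps (not an ensemble consensus), so that every design cell contributes a
response value to the ANOVA.

## The deviance partition

"Deviance" is operationalised as Gaussian deviance — sums of squares — and
reported both ways: as each component's share of *explained* deviance and
as its share of *total* deviance, since figures in this literature use
either convention.

The nested scheme expands `SDM/GCM:RCP` as three sequential terms: SDM;
GCM-within-SDM (the indicator space of SDM×GCM cells); RCP-within-SDM.
SDMs are fitted irrespective of the forcing, but how a given algorithm
responds to a GCM or RCP is specific to that algorithm — hence the nesting.
Each term's deviance is the drop in residual sum of squares when its
columns join the cumulative design, computed with pivoted QR
decompositions, so incomplete factorials (14 of 20 combinations, dropped
models) are handled by least squares on the observed rows with no
imputation. Note a consequence the tests make explicit: the nested GCM and
RCP terms absorb their within-SDM interaction with SDM, so on a balanced
design they can exceed the classical main effects; the within-SDM GCM:RCP
interaction itself is pooled into the residual by default (an explicit
`include_interaction` term can extract it; whether that deviance belongs to
GCM, RCP or neither is genuinely undecidable, so residual is the
conservative default, flagged in output). The full-factorial engine
(sequential main effects SDM, GCM, RCP) is provided for comparison; on
balanced complete designs its sequential sums equal the classical
main-effect decomposition under any term order.

Degenerate inputs are flagged rather than partitioned: constant responses
give zero total deviance with undefined shares; single-level factors warn
and contribute zero. Conservation (components + residual = total, relative
tolerance 1e−8) is asserted for every fit in the test suite.

The partition is applied four ways: pooled across species, per pixel
(grouped by taxon and period; the per-pixel sweep reuses one response
vector per cell against the shared factor columns), per log-range-size bin
(equal-width bins on log₁₀ cells, right-closed), and per TSS threshold
policy. Pooled fits do not include a pixel-identity blocking term by
default; because each pixel is also partitioned separately, the blocked
variant adds little and is left to the user (fit `nested_partition` on any
subset).

## Verification strategy and problem sizes

Every engine is checked against an independent route: sequential sums of
squares against a group-means oracle on all balanced shapes up to
4 × 3 × 2 levels with 5 replicates and against `stats::anova(lm(...))` on
unbalanced tables; TSS against confusion-matrix arithmetic on random
vectors; pixel metrics against per-cell recounts; dispersal masks against
all-pairs distance checks. Variance recovery plants effects with *exact*
9:4:1 variance ratio (`simulate_design_table(exact_variance = TRUE)`
rescales drawn effects to the stated standard deviations) on a balanced
4 × 5 × 4 × 4 design: expected shares then deviate slightly from 9/14,
4/14, 1/14 because the three factors carry 3, 16 and 12 degrees of freedom
respectively, and the recovered means sit within ±5 points. Null
calibration checks that with no signal each component's mean share matches
its degrees-of-freedom fraction.

The qualitative mechanism experiment (`mechanism_experiment()`) runs 20
replicate worlds of 18 × 18 cells, 3 species each, a 3-GCM × 4-RCP × 1
horizon ensemble and 2 repetitions per algorithm — sizes chosen as the
smallest at which the component shares stabilise across replicates. It
verifies the direction of the headline result: between-algorithm map
disagreement is an order of magnitude larger under the strongest-RCP future
than under current climate, making SDM the dominant component for CCS
(limited dispersal) while RCP leads for LCS (no dispersal). The shipped
demo experiment (`demo_config()`: 20 species, 15 × 20 grid, 2 GCMs × 2
RCPs × 1 period) exercises every stage and artifact end to end.

## Known limitations

* The world is planar with Euclidean distances; great-circle geometry,
  coastlines and latitude-dependent cell areas are real-data concerns the
  generator does not emulate.
* Niche axes are independent Gaussians; interactions among predictors, and
  therefore genuinely complex response surfaces, are absent — algorithm
  divergence under novel climate arises only from extrapolation behaviour.
* No spatial-block cross-validation, ensemble weighting, additional
  algorithm families, dispersal kernels or land-cover barriers; these are
  explicit non-goals.
* Persistence is tabular (CSV/JSON/YAML); gridded outputs are long tibbles
  keyed by cell rather than raster files.
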