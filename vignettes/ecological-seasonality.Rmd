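---
title: "Delineating seasonal space-use states: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating seasonal space-use states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecoseasons` delineates *seasonal space-use states* — blocks of the ordinal
year in which a population's movement and habitat use are homogeneous —
from GPS collar telemetry, then characterizes habitat selection within each
state. This vignette is the package's own account of the procedure: the
model behind each stage, the tunable parameters and their defaults, the
places where the design was genuinely open and how we resolved them, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## 1. From tracks to the daily space-use matrix

The clustering observation is the *ordinal day* (1–365, circular; Feb 29
merges into day 59 so that multi-year data share one cycle). For each day
we average, over every retained fix of every individual and year:

* **movement**: step length (m, Euclidean distance from the prior retained
  fix) and signed turning angle (degrees, the heading change completed on
  arrival at a fix — so the first two fixes of a track carry no angle);
* **terrain**: slope (degrees) and northness (cos aspect, +1 = north-facing);
* **distance surfaces**: distance to lake and to road (m);
* **land cover**: per-class occupancy fractions over the six land-cover
  classes. A daily "average" of a
  categorical layer is otherwise undefined; occupancy fractions (the daily
  mean of class indicators, summing to one) are our documented choice.

Before averaging, tracks are cleaned by the 7-day capture/mortality buffer
and resampled to 12 ± 2 h relocation intervals. Resampling is greedy
forward selection: keep the first fix, then from each kept fix the earliest
later fix whose gap falls inside the tolerance window, restarting the chain
at the first fix beyond the window when none qualifies. The rule is
deterministic, independent of future fixes, and idempotent. Note one
consequence: on an oversampled track the *earliest* admissible gap is kept,
e.g. hourly fixes resampled to 4 ± 1 h keep every third fix (3-h gaps),
not every fourth.

Columns are then symmetrized and standardized. The classical practice is a
visual normality check; software needs a deterministic rule, so we apply a
square root when a non-negative column's sample skewness exceeds 1, and
center-and-scale always. Zero-variance columns are dropped. Finally the
collinearity screen iteratively removes one member of every pair with
|Pearson r| ≥ 0.70 — the member with the larger mean absolute correlation
to all other columns (ties break toward the later column). The surviving
matrix has unit-variance columns, which is what makes the k-means
squared-Euclidean objective commensurable across covariates.

## 2. Delineating states

### Variable screening

HINoV (heuristic identification of noisy variables) clusters the days on
each variable alone (probe k = 2 by default, matching the smallest
candidate clustering) and scores each variable by *topri*: the summed
adjusted Rand agreement between its single-variable partition and every
other variable's. Variables sharing cluster structure score high; pure
noise scores near zero. We flag the group below the largest gap in the
sorted topri sequence, but only when that gap exceeds `min_gap = 0.5`:
adjusted Rand has a natural scale (independent partitions score about 0,
shared structure 0.5 and up), and when *every* variable is noise the sorted
sequence shows only small sampling gaps — cutting there would leave an
arbitrary single survivor whose one-dimensional clustering is trivially
stable.

The ANOVA screen asks, per variable, whether its distribution differs
across a candidate partition of the days. Two design points deserve
emphasis:

* **Direction.** The screen exists to discard variables that carry little
  clustering information, so the default `anova_mode =
  "remove_nonsignificant"` removes variables that do *not* differ across
  candidate states (p ≥ α after Holm adjustment). The literal opposite rule
  (`"remove_significant"`) is implemented behind the same switch because
  the wording of the screening step is ambiguous in parts of the applied
  literature; under a k-means-derived candidate partition it would discard
  exactly the variables carrying the structure, so we do not recommend it.
* **The candidate partition.** Testing variables against a partition
  derived from the same data by k-means is circular: any split of a point
  cloud differs "significantly" along its own direction. Seasons, however,
  are temporally coherent by definition, so `season_states()` builds its
  candidate from the pipeline's own temporal machinery: preliminary k-means
  labels are mode-filtered to a fixed point and converted to candidate
  calendar states by the run-length transition rule. Variables are then
  screened on whether they distinguish *contiguous blocks of days*, with
  Holm adjustment across the family of tested variables. A scattered split
  that mixes out of every block is not evidence of seasonality.

Because the screen needs a coherent candidate and the clustering benefits
from the screened variable set, `season_states()` iterates the two: after a
calendar is delineated, variables are re-screened against the *final*
states and the clustering repeats when anything falls out (at most three
rounds; in practice the fixed point arrives after one). Without this
polish, a single strongly informative variable accompanied by several weak
ones can be diluted into a hybrid, half-seasonal clustering.

### k selection, stability, and the "no seasonal states" verdict

The number of clusters is proposed by the elbow rule (maximum second
difference of the within-cluster sum of squares over k) and by the maximum
mean silhouette width, both on deterministic seeded k-means fits (10
random restarts; we use the stock `stats::kmeans` under a fixed derived
seed rather than a bespoke initializer — equally deterministic and one
fewer thing to maintain). When the two disagree, stability is assessed for
both and the smaller stable k wins.

Stability itself is bootstrap-Jaccard: per outer seed, fit a reference
k-means, then for each of B bootstrap resamples of the days refit and match
every reference cluster to the resample cluster maximizing Jaccard
similarity over the days present in the resample. Instability of **any**
cluster under **any** seed (mean Jaccard < γ = 0.75) voids the clustering —
the strictest reading of the rule. Defaults are B = 5000 and 10 seeds; the
package's own tests and acceptance runs use the documented fast profile
B = 200 with 3 seeds. The bootstrap resampling unit is the matrix row (the
ordinal day), because the day is the clustering observation.

A caution that shaped the design: bootstrap-Jaccard stability rejects only
near-isotropic data. A unimodal Gaussian cloud with mild cross-variable
correlation (equicorrelation 0.2 suffices) is split by k-means along its
long axis *reproducibly*, with per-cluster Jaccard near 0.94 — stability is
a necessary, not sufficient, condition for real clusters. Daily telemetry
matrices are always somewhat correlated (land-cover fractions are
compositional; every covariate is driven by the same fix positions), so the
γ rule alone cannot identify an aseasonal population. The package therefore
adds a **temporal-coherence floor**: after smoothing and transition dating,
every final state must last at least `2 × run_length + window` days (21 by
default). The floor is the method's own resolution — a state must be able
to contain the two 8-day runs that date its boundaries plus the smoothing
margin — not a free parameter. An aseasonal population whose spuriously
stable labels oscillate through many short blocks fails the floor and is
reported as having **no seasonal states**; a genuinely seasonal population
is untouched, months away from the bound.

### Smoothing and transition dating

Stable first-seed assignments are smoothed by the mode of a 5-day circular
window (ties keep the day's own label, then the smallest label). Each
transition between consecutive label regimes is dated by two scans over the
smoothed sequence: forward to the first day starting `run_length = 8`
consecutive days of the new label (date A), and backward to the day after
the last 8-day run of the old label (date B); the transition is the
circular midpoint of A and B, rounded half-up, and becomes the first day of
the new state. The scans deliberately run on the *unmerged* sequence —
stray days outside the final states are exactly what the run rule is
designed to skip — while regimes too short to host a run are merged into
their larger neighbor to fix the final state structure. Circular midpoints
matter because winter states span the year boundary.

PCA on the retained matrix then characterizes the states; we report the
percent variance of the first two components and the loadings, which is how
between-state differences are conventionally summarized.

## 3. Resource selection within states

Locations (resampled at 4 ± 1 h for high-frequency collars) are segmented
by individual × state × year — the same state in different years is a
separate sample unit — after discarding fixes within 14 days of any
transition; segments under 50 locations are dropped. For each segment a
utilization distribution is fit as a Gaussian kernel density on the
landscape grid with a normal-reference bandwidth, each fix weighted by the
time span it represents (half the gap to each temporal neighbor; boundary
fixes take their single full gap, so regular schedules are unweighted). The
50% and 95% isopleths are smallest superlevel cell sets, so the core range
nests inside the home range by construction.

Selection is estimated as used (segment fixes inside the isopleth) versus
available (uniform in the isopleth, 10 : 1), by logistic regression with
heavy down-weighting of available points — the standard weighted-logistic
approximation to the inhomogeneous Poisson point process. Predictors are
land cover (open water reference, chosen for its uniformly low use),
northness, slope, and the distance surfaces, with no interactions, plus an
**elliptical-Gaussian ranging nuisance** (a bivariate quadratic in
kilometer-scaled coordinates centered on the segment's weighted centroid).
The nuisance stands in for the integrated ranging model of a full
continuous-time treatment: without it, the concentration of use toward the
range center lets any covariate with a smooth gradient across the home
range masquerade as selection. Covariance is day-cluster robust
(fixes within a day are serially dependent). Separation triggers a logged
ridge-penalized refit; a land-cover class absent from a segment is marked
inestimable and skipped in pooling.

Population-level estimates are AICc-weighted arithmetic means of the
segment coefficients (relative Akaike weights within the fit set; an
equal-weight mode is provided because the weighting semantics are a
convention, and relative AICc weights across segments of very different
sizes concentrate on one segment — in that degenerate case the pooled CI is
reported as undefined rather than infinite). Significance is the pooled 95%
t-interval excluding zero.

**What this stage is not.** It is a deliberate simplification of the
weighted-autocorrelated-KDE / weighted-RSF framework: no continuous-time
movement model is fitted, and autocorrelation enters only through time-span
weights and clustered errors. Consequences we have measured on simulated
range-resident data: coefficient *signs* and the qualitative selection
ranking are recovered reliably, but confidence intervals for very smooth
covariates (the distance surfaces) under strong site fidelity remain
anti-conservative. The package's validation experiments therefore use
free-ranging simulated animals observed at quasi-independent 12-h fixes
when assessing interval calibration, and we advise the same caution with
real data that the full framework exists to address.

## 4. The synthetic-data generator

The generator exists so that every downstream stage has known ground truth.

* **Landscape** (`make_landscape`): a smoothed Gaussian random field cut at
  class-quantile breakpoints reproduces requested class proportions by
  construction (the default composition is 44% mixed forest, 17% deciduous,
  11% coniferous, 9% shrubland, 7% wetland, 5% open water, a boreal
  shoreline mosaic) with spatially coherent patches; terrain derives from a
  second smoothed field; distance layers are exact Euclidean distances to
  the open-water cells and to one meandering road polyline. Default grids
  are 80 × 80 to 200 × 200 cells at 30 m.
* **Movement** (`simulate_track`): a regime-switching biased correlated
  random walk. Per step, 30 candidate endpoints are drawn from the current
  regime's gamma step-length and von Mises turning-angle laws and one is
  chosen with probability ∝ exp(selection weights · covariates) — the
  discrete-choice approximation of a habitat-weighted redistribution
  kernel. Each individual is range-resident via a log-linear penalty on
  distance from its home-range center (default 0.003 per m, kilometer-scale
  ranges), the discrete-choice analog of Ornstein–Uhlenbeck centering; real
  telemetry animals hold ranges, and without this term the daily matrix
  tracks a wandering population centroid that no real population exhibits.
  Regime day-windows are shared population-wide (seasons are
  population-level states). The reference two-season condition uses a 3 : 1
  step-scale ratio (450 m vs 150 m gamma scale) with distinct habitat
  weights, switching at days 100 and 300; the aseasonal control uses one
  regime with averaged parameters.
* **Schedule**: fixes every 4 h by default (real collars in such studies
  range from 0.25 to 4.5 h) with ±15 min uniform jitter and 5% independent
  dropout, producing the irregular gaps the resampler must handle.
* **Weather** (`simulate_weather`): a sinusoid through the configured
  January minimum (−17.8 °C) and July maximum (23.3 °C) plus Gaussian noise
  (SD 2.5 °C, between the observed month-level spreads), with snow depth
  proportional to the negative part of the smoothed curve. Growing degree
  days accumulate above a 1 °C plant-growth threshold (the package exposes
  the threshold directly; latitude corrections are applied by choosing it),
  so green-up (ΔGDD) and snow depth are negatively associated by
  construction.

What the generator does **not** emulate: GPS positional error, habitat-
dependent fix failure, collar duty cycles, interannual phenological drift,
social structure (packs moving jointly), and memory-based range shifts.
Passing the package's recovery tests therefore demonstrates that the
pipeline's logic is correct and well-calibrated under clean conditions, not
that any field dataset will behave as cleanly.

## 5. Numerical conventions and degenerate inputs

* Circular arithmetic throughout uses a 365-day year; signed differences
  lie in (−182, 182] and midpoints round half-up.
* Raster lookup uses the half-open convention: a cell owns its left and top
  edges.
* All stochastic stages draw from seeds derived deterministically from one
  master seed; identical inputs give byte-identical outputs.
* Degenerate cases are explicit: empty tracks after boundary filtering warn
  and return empty; constant matrix columns are dropped with a recorded
  reason; a segment of identical coordinates raises a degenerate-UD error;
  an empty bootstrap refit is retried up to 10 times then scores zero for
  unmatched clusters; a variable with too few distinct values is excluded
  from HINoV with a flag.

## 6. Validation summary

The test suite builds every fixture in code. Unit oracles include
brute-force distance transforms, hand-traced resampling chains, exhaustive
window-mode and run-scan reimplementations, closed-form correlation
statistics, and the mclust and cluster packages as independent
cross-checks for adjusted Rand and silhouette. End-to-end, the default
two-season condition (12 individuals, 2 years) recovers both true switch
days within ±3 days in 10 of 10 seeded runs at the fast stability profile,
and the matching one-season control reports "no seasonal states" in 10 of
10; `scripts/acceptance.R` reruns these experiments from scratch at any
seed. Problem sizes in the tests (80 × 80 landscapes, B = 200, 3 seeds, 20
replicate selection experiments) were chosen as the smallest at which the
verdicts stabilize.

## 7. Known limitations

* Bootstrap-Jaccard stability cannot, by itself, distinguish elongated
  unimodal structure from true clusters; the temporal-coherence floor is
  our guard, and it is a package design decision, not part of the classical
  procedure.
* The ANOVA screen's candidate partition is data-derived; the Holm-adjusted
  calendar-state construction reduces but cannot eliminate the circularity.
* The selection stage's interval calibration degrades for very smooth
  covariates under strong site fidelity (see §3).
* Per-individual season calendars, model-based clustering, and formal
  cross-population contrasts are out of scope.
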