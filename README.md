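# ecoseasons

Animal-defined seasons from GPS telemetry.

Ecologists increasingly define seasons by what animals *do* rather than by
calendar dates: a "seasonal space use state" is a block of the year in which
a population's movement and habitat use are homogeneous, and transitions
between states mark the population's own phenology (prey migration, snow
melt, parturition). `ecoseasons` implements a complete, testable pipeline
for delineating such states from GPS collar data, for characterizing them
with habitat-selection models, and for simulating telemetry with known
ground-truth seasons so every stage can be validated end to end.

## The method

**Daily space-use matrix.** Tracks are filtered (7 days dropped around
capture and mortality), resampled to 12 ± 2 h relocation intervals by greedy
forward selection, annotated with step length `s_t = ||x_t − x_{t−1}||` and
signed turning angle, and intersected with landscape rasters (land cover,
slope, northness = cos(aspect), distance to lake and road). Pooling all
individuals and years, each covariate is averaged per ordinal day
(land cover as per-class occupancy fractions), square-root transformed where
skewness exceeds 1, z-scored, and screened for collinearity (|r| ≥ 0.70).

**Season delineation** (`season_states()`): noisy variables are screened by
HINoV (each variable is clustered alone; its *topri* score sums adjusted
Rand agreement with every other variable's partition) and by one-way ANOVA
against a temporally coherent candidate partition; k is chosen by the elbow
and silhouette methods; the k-means clustering of days must survive a
bootstrap stability test — per cluster, the mean Jaccard similarity between
the reference cluster and its best-matching cluster across bootstrap refits
(B replicates × several seeds) must stay ≥ γ = 0.75, for every cluster and
every seed, or the population is declared to have **no seasonal states**.
Stable daily assignments are smoothed with a 5-day circular moving-window
mode, and each transition is dated as the circular midpoint between the
first 8-consecutive-day run of the new state (forward scan) and the day
after the last 8-day run of the old state (backward scan). Finally every
state must last at least `2 × run_length + window` days (21 by default) —
shorter "states" mean the assignment is not temporally coherent and the fit
reports no seasonal states. Principal components summarize how the states
differ.

**Resource selection** (`segment_locations()`, `fit_ud()`, `fit_rsf()`,
`pool_population()`): locations are split into individual × state × year
segments (±14-day transition buffer, ≥ 50 locations), a time-span-weighted
kernel utilization distribution gives 50% (core) and 95% (home-range)
isopleths, and habitat selection is estimated by weighted logistic
regression of used versus uniformly sampled available points
(`w(x) ∝ exp(βᵀz(x))`, open water as the reference land-cover class, an
elliptical-Gaussian ranging nuisance, day-cluster robust errors).
Segment coefficients are pooled across a population with relative-AICc (or
equal) weights; a predictor is significant when its pooled 95% CI excludes
zero.

**Simulator** (`make_landscape()`, `simulate_population()`,
`simulate_weather()`): smoothed-Gaussian-field landscapes cut to requested
class proportions, regime-switching biased correlated random walks
(gamma steps, von Mises turns, discrete-choice habitat weighting,
home-range attraction), and sinusoidal weather with snow only below
freezing — all fully seeded, with the true season calendar returned
alongside the tracks.

## Worked example

```r
library(ecoseasons)

ls  <- make_landscape(MAINLAND_PROPORTIONS, grid_spec(80, 80), seed = 1)
cfg <- sim_config(12, default_regimes("two_state", switch_days = c(100, 300)),
                  n_years = 2, rng_seed = 101)
pop <- simulate_population(ls, cfg)        # truth: switches at days 100, 300
dm  <- prepare_daily_matrix(pop$tracks, ls)
fit <- season_states(dm, B = 200, n_seeds = 3, seed = 101)
fit
#> Seasonal space-use states: k = 2 stable state(s)
#> Season calendar: 2 state(s)
#>   S01            10 Apr - 28 Oct
#>   S02            29 Oct - 09 Apr
#> Transitions:
#>   S02 -> S01 on 10 Apr (day 100)
#>   S01 -> S02 on 29 Oct (day 302)
#> Components 1-2 describe 50.0% of daily space-use variation
```

The fitted calendar recovers the true switch days (100 and 300) to within a
couple of days; the same pipeline applied to a one-regime population
(`default_regimes("one_state")`) prints `no seasonal states`. The companion
`season_offsets()` turns several populations' calendars into signed circular
day offsets between their transitions, e.g. a predator transitioning 20 days
after its prey.

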