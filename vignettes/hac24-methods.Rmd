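---
title: "Methods: compositional latent profiles of the 24-hour activity cycle"
author: "hac24"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional latent profiles of the 24-hour activity cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sleep, sedentary behaviour (SB), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA) partition the day. Because any
extra minute of one behaviour must come out of another, the four durations
form a *composition*: only their relative sizes are informative, and ordinary
multivariate statistics applied to raw minutes suffer from the constant-sum
constraint (spurious negative correlations, multicollinearity). hac24
implements a complete analysis chain for wrist-actigraphy studies of this
24-hour activity cycle (24-HAC) in older adults with mild cognitive
impairment (MCI): epoch scoring, compositional coordinates, latent activity
profiles, and between-profile comparisons of cognition — plus a synthetic
data generator so every stage can be exercised without any participant data.

# Actigraphy scoring

Minute-epoch counts are classified with wrist cutpoints: SB at or below
178.50 counts/min, MVPA at or above 562.50 counts/min, LPA in between. Inside
the nightly rest interval, epochs strictly below 20 counts/min score as
sleep; epochs at or above it are wake after sleep onset (WASO) and are
excluded from sleep.

A "day" runs from one night's bedtime to the next (`[bed_n, bed_{n+1})`), so
its length varies around 24 h; the first partial recording day is dropped. We
count a day's duration as the number of minute epochs in that half-open
window, which makes two consecutive identical bedtimes give exactly
1440 min.

Three scoring questions have no canonical answer, and we resolved them as
follows:

* **Where do WASO minutes go?** They cannot stay in sleep, but dropping them
  would break the requirement that the four parts sum to the day's length —
  an invariant everything downstream relies on. We classify WASO epochs by
  the intensity cutpoints (in practice almost always SB), by analogy with
  naps, which are conventionally indexed as SB. Real pipelines sometimes
  discard WASO entirely; that is why observed mean day totals in field data
  (about 1343 min) fall short of 1440. Our conservation rule is the
  internally consistent choice; the closure step removes the difference in
  either case.
* **Epoch gaps.** Gaps of at most 2 min are filled by carrying the last
  classification forward; a longer gap invalidates the day. The literature is
  silent here and this is the conservative option.
* **Rest intervals.** Paired event-marker presses are authoritative. Without
  them, a heuristic takes maximal runs (at least 3 h) of epochs that are both
  dark (lux below 10) and quiet (15-min running median of counts below the
  sleep/wake threshold); sub-3 h rest blocks are treated as naps and left in
  the sedentary budget. On synthetic recordings the heuristic recovers the
  generating rest window to within a few minutes; proprietary device
  algorithms are not reproduced.

Participants need at least 5 consecutive valid days (the longest
calendar-adjacent run is used); included participants contribute the
arithmetic mean of each behaviour across those days.

# Compositional coordinates

Average behaviour minutes are closed to a constant (`kappa` = 1440 min
internally; percentages are minutes divided by 14.4) and mapped to isometric
log-ratio (ILR) coordinates through a sequential binary partition:

$$\mathrm{ilr}_1 = \sqrt{3/4}\,\ln\frac{\mathrm{MVPA}}{(\mathrm{SB}\cdot \mathrm{LPA}\cdot \mathrm{Sleep})^{1/3}},\quad
\mathrm{ilr}_2 = \sqrt{2/3}\,\ln\frac{\mathrm{SB}}{(\mathrm{LPA}\cdot \mathrm{Sleep})^{1/2}},\quad
\mathrm{ilr}_3 = \sqrt{1/2}\,\ln\frac{\mathrm{LPA}}{\mathrm{Sleep}}.$$

The basis is orthonormal, scale invariant (closing to minutes or percent
gives identical coordinates) and invertible; the compositional mean is the
part-wise geometric mean re-closed, equivalently the inverse ILR of the mean
ILR vector. Zero parts are a hard error: no zero-replacement strategy is
implemented, and the generator never emits zeros. The code matrix is
configurable, but only this partition is tested.

Outlier screening uses Tukey fences (Q1 − 1.5 IQR, Q3 + 1.5 IQR) with
winsorization to the 5th/95th percentiles, fences and percentiles computed
once from the original vector in a single pass. Quantiles use linear
interpolation between order statistics (type 7), the R default; no convention
was prescribed, so we state this one and use it consistently. The pipeline
screens behaviours (min/day) before the ILR step and the ILR coordinates and
cognition afterwards, mirroring variable-wise screening of the three sets.

# Latent profile analysis

Profiles are a Gaussian finite mixture on the three ILR coordinates, fitted
by EM. The default variance structure is *equal-diagonal* — per-coordinate
variances shared across classes, zero covariances — the simplest model in
common LPA software and the natural default when the published analysis does
not state its covariance specification; a free-diagonal structure is
available. Parameter counts are `3K + 3 + (K-1)` and `3K + 3K + (K-1)`.

Numerical choices: the first start is k-means (5 restarts of Lloyd's
algorithm), remaining starts draw class centres from the data with jitter;
convergence is declared when the relative log-likelihood change falls below
`1e-8` (500 iteration cap); variances are floored at `1e-6` of each
coordinate's total variance, and a restart that empties a class is
discarded. The log-likelihood trace is retained so monotonicity is checkable
on every fit.

Model selection follows the published protocol: AIC, BIC, normalised entropy
`1 - sum(-p log p) / (n log K)` (the convention of common LPA software;
defined as 1 when K = 1), a bootstrapped likelihood-ratio test (BLRT) of K
against K−1, and a class-size rule. The BLRT is a parametric bootstrap with
the add-one p-value estimator `(1 + #{LR_b >= LR_obs}) / (B + 1)`, B = 100 by
default with a reduced restart budget inside the bootstrap. A class count is
eligible when its BLRT is significant (`p < 0.05`) and every class passes the
size rule; among eligible counts the lowest BIC wins, ties to the smaller K.

**The class-size rule.** The published criterion is "at least 25 participants
or more than 1% of the sample". We implement it literally as the disjunction
(default `"either"`), with strict single-arm variants available. The strict
"at least 25" arm is deliberately *not* the default: the reference cohort's
smallest profile has 26 members, one above the cutoff, and simulation at the
published parameters shows the smallest fitted class fluctuates by around ±6
across seeds — a hard ≥25 gate would reject the published solution itself in
a large fraction of replications, so it cannot be the rule that admitted it.
Under the disjunctive reading selection is driven by BLRT and BIC, which is
stable.

Label switching is handled at evaluation time: comparisons against reference
labels or means use the adjusted Rand index and best-permutation matching
(`match_class_means`, exhaustive over K! permutations), both permutation
invariant. "Matched class-mean error" means the average over classes of the
Euclidean distance between matched fitted and reference ILR means.

# Between-profile inference

Descriptive comparisons use one-way ANOVA for continuous variables and
Pearson chi-square (no continuity correction) for categorical ones.
`anova_from_summary()` reconstructs the F-test from printed per-group
n/mean/SD so published descriptive tables can be checked directly. Cognition
is compared with ANCOVA adjusted for age, biological sex, BMI, MoCA score and
trial cohort (a sensitivity switch replaces MoCA with education years). The
factor is tested marginally (Type III with sum-to-zero contrasts; with no
interaction terms this equals the factor-after-covariates test), and
estimated marginal means average categorical covariates over their observed
proportions (\pkg{emmeans} with proportional weights). Pairwise contrasts are
unadjusted by default, matching an exploratory protocol; adjustment methods
are available behind a flag. Pairwise contrasts from the full model share its
pooled error term, so they match subset refits in the estimate exactly but
not in the standard error.

# The synthetic generator

`generate_cohort()` draws participants from a four-profile logistic-normal
mixture whose defaults *are* the published study conditions: per-profile
percent-of-day compositional means and SDs, class sizes 103/70/54/26 (mixing
weights at n = 253), bedtime-to-bedtime day totals Normal(1343.53, 44.11)
truncated to [1100, 1550] min, cognition Normal(−0.31, 0.62) with no true
between-profile effect (shifts can be injected for power checks), and the
cohort's demographic marginals. Within-profile noise lives in ILR space with
diagonal covariance, guaranteeing strictly positive, closed compositions.

Because the published SDs are on the percent scale while the model operates
in ILR space, the three ILR noise parameters per profile are calibrated by
least squares on log SD ratios against the four percent-scale targets, using
fixed common-random-number draws so calibration is deterministic. Three
parameters cannot match four targets exactly; achieved SDs land within about
15% of the targets, and the exact within-profile covariance of the original
data is unrecoverable in principle.

Seeding is hierarchical: one master seed, with per-participant substreams
derived deterministically, so any subset of a cohort reproduces bit for bit.

`generate_epoch_series()` builds minute-epoch fixtures for the actigraphy
module: nights of sub-threshold counts with scattered WASO minutes in the
SB band and low lux, bounded by event markers, followed by shuffled awake
epochs placed inside their cutpoint bands with daytime lux. Day summaries
recover the generating targets exactly by construction. Because the day
window equals the sum of the behaviour targets (mean about 1343 min),
bedtimes drift earlier across a simulated week — a deliberate artifact of
honouring both the published day-duration distribution and duration
conservation; rest detection does not assume fixed clock times, so the drift
is harmless. No attempt is made to simulate raw accelerations, device noise,
or light physiology.

**What passing tests do and do not show.** The generator reproduces the
published *marginal* structure (profile means, spreads, class sizes, null
cognition effect). It does not reproduce real data's demographic-profile
associations (e.g. sex or BMI differences between profiles), temporal
structure within days beyond the rest/wake layout, device noise, or missing
data. Recovery results on synthetic cohorts therefore speak to the
correctness of the implementation under the published conditions, not to the
field behaviour of the instruments. Notably, at the published within-profile
SDs the mixture components overlap substantially: class *means* are recovered
well (matched mean error around 0.09 ILR units in the test suite), while
modal assignment agreement with the generating labels is intrinsically capped
(median adjusted Rand index around 0.6, which even the Bayes-optimal
classifier could not push to 0.9 at this overlap). The class-size and
class-count recovery results in the acceptance suite are the meaningful
operating characteristics.

# Problem sizes and tolerances used in the tests

The test suite fits cohorts of n = 253 (the reference size) for selection
and recovery checks, 100 simulation seeds for the smallest-class statistic,
20 seeds for parameter recovery, 200 replicates at B = 99 for the BLRT
type-I study (at n = 60 per replicate, with a slightly relaxed EM tolerance
of `1e-5` inside the simulation), and B = 50 for the full selection
protocol; these sizes were chosen to make the Monte-Carlo error small
relative to the tolerances being asserted. Algebraic contracts (closure,
ILR round-trips) are asserted at `1e-9` or machine precision; statistical
checks use binomial error bands at their replication counts.

# Known limitations

* Proprietary device scoring (rest-interval internals, firmware filtering)
  is not reproduced; only the published rules are implemented.
* No zero-replacement for compositions; a participant with a true zero in
  any behaviour (e.g. no MVPA at all) must be handled upstream.
* Sleep is the major nightly period only; sleep quality metrics
  (efficiency, fragmentation) are out of scope.
* The ANCOVA assumes homogeneous slopes (no factor-by-covariate
  interactions) and complete cases.
* The mixture never models within-class covariances between ILR
  coordinates; profiles with strongly correlated coordinates would be
  approximated by more classes instead.
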