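---
title: "Honey as pooled eDNA: models and methods behind honeybiogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honey as pooled eDNA: models and methods behind honeybiogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeybiogeo)
library(dplyr)
```

## The scientific setting

Honey carries DNA from every colony that contributed nectar to it, which
makes a jar of honey a pooled environmental-DNA sample of the apiaries
around its production site. A qualitative PCR assay on the COI–COII
intergenic spacer can tell apart the three major *Apis mellifera*
maternal lineages — A (African), C (South-Eastern European) and M
(Northern/Western European) — so each honey sample yields a *lineage
pattern*: the non-empty subset of {A, C, M} whose diagnostic fragments
amplified. Seven patterns are possible. Tabulated over space (latitude,
longitude, administrative region) and time (production year), these
patterns describe how the maternal composition of managed honey bee
populations is shifting across a country like Italy, where the native
C-lineage *A. m. ligustica* coexists with the A-shifted Sicilian
subspecies and with M- and C2-carrying populations at the western and
eastern Alpine margins.

`honeybiogeo` implements the full analysis chain for such data, plus a
seeded generator that emulates the sampling structure, so every stage is
testable without access to any survey deposit.

## The pooled-detection model

A colony is mono-mitotype: one queen, one maternally inherited lineage.
If a honey sample pools $k$ colonies whose lineages are i.i.d. draws
from the local colony-level frequencies $(p_A, p_C, p_M)$, and each
colony's DNA is detected with probability $d$, then the probability that
the pattern contains lineage $L$ is

$$P(\text{pattern} \ni L) = 1 - (1 - p_L d)^k,$$

implemented in `detect_prob()`, with `expected_detect_prob()` averaging
over a pool-size distribution. Pool sizes are taken as discrete uniform
on 10–30 colonies by default — the plausible range of colonies
contributing to one commercial honey sample; uniformity is an assumption
(no empirical pool-size distribution is available) and is exposed in the
configuration. The *inflation factor* `inflation_factor()` is the ratio
of the pooled detection frequency to the individual-bee carrier
frequency; it exceeds 1 because a pool flags a lineage if *any*
contributing colony carries it. Identifying bee-level with colony-level
frequencies is exact under mono-mitotype colonies and uniform sampling
of bees — an assumption we make explicit because published comparisons
of honey-derived and bee-derived frequencies rely on it silently.

```{r pool}
detect_prob(p = 0.013, k = 20)
inflation_factor(expected_detect_prob(0.013, uniform_pool_law()), 0.013)
```

The model is qualitative by design: the underlying assay reports
presence, not abundance, so no amplicon-competition term is included.
Whether PCR competition suppresses minority lineages in real pools
(which would make $d < 1$ and $k$-dependent) is unknown; `detect_d` is
available for sensitivity analyses but defaults to 1.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` generate a survey with the
structure the analysis assumes:

* **Beekeepers** are placed at fixed uniform locations in 20 synthetic
  regions grouped into the five macro-regions (North, Central, South,
  Sicily, Sardinia), with region weights putting roughly 45% of
  beekeepers in the North. Locations are fixed across years, matching
  geocoding by municipality (no transhumance).
* **Participation**: each beekeeper is active in a random subset of the
  six production years (default law: 45% one year, 5% all six; mean 2.3
  years), and submits 1–9 samples per active year (default mean ≈ 1.4),
  so the default 1,300 beekeepers yield roughly 4,000 samples and about
  3,000 unique beekeeper-years — the scale of a national honey survey.
* **Colony-level frequencies** follow a multinomial-logit surface with C
  as reference: for lineage $L$,
  $\eta_L = \alpha_L + \beta^{lat}_L(\phi - 42) + \beta^{lon}_L(\lambda - 12) + \gamma_L m(\text{macro})(t - t_0)$,
  and $(p_A, p_C, p_M) = \operatorname{softmax}(\eta_A, \eta_C, \eta_M)$.
  Defaults (`default_cline_coefficients()`) are calibrated on the logit
  scale so that, after the pooled-union transformation with 10–30
  colonies, sample-level contains-A runs from ≈11% in the North to ≈26%
  in the South and contains-M from ≈14% to ≈36%, while only-C declines —
  the observed continental structure. Latitude enters in raw
  north-positive decimal degrees, so "rising southward" means a
  *negative* slope.
* **Two structures the smooth cline cannot carry** are configured
  separately: an additive island offset (`island_offsets`, default +7 on
  $\eta_A$ in Sicily, making Sicily a strong A island) and per-macro-region
  drift multipliers $m(\cdot)$ (`drift_mult`, default: Central and South
  drift toward higher A/M frequencies at $\gamma = 0.15$/year on the
  logit scale, North and the islands stable). A single global year slope
  could not produce "Central–South diversifying, North stable", which is
  the temporal signal the trend machinery is built to detect.
* **Patterns** are unions over the pool: $k \sim \mathrm{DU}(k_{\min},
  k_{\max})$ colonies drawn i.i.d. from the local frequencies, each
  contributing with probability $d$; empty unions (possible only when
  $d < 1$) are redrawn, since a sample with no amplified lineage would
  never enter the observed data.

Colonies are i.i.d. within a pool — the minimal model. Real apiaries are
clustered (a Sicilian beekeeper may keep pure *A. m. siciliana* or pure
*ligustica* stock); an optional beekeeper-level random intercept
(`beekeeper_sd`) mimics that clustering but defaults to off. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated sampling model, not robustness to within-apiary
correlation, spatial autocorrelation, or reporting biases of real survey
data.

## Frequency tabulation

`tabulate_patterns()` reports, per group, counts and frequencies of the
seven exact patterns and of six derived binary codings (`contains-L`,
`only-L`). Percentages are rounded half-up to one decimal, with sub-1%
values reported at two decimals (so 7/4,150 prints as 0.17); printed
frequency tables in this field are consistent with either half-up or
half-even at one decimal, and half-up is adopted as the documented rule.
Counts are never rounded. `dedup_unique()` implements the unique-sample
view — one randomly retained sample per beekeeper and year, seeded and
idempotent. Which view feeds an analysis is a user choice; per-year
cline analyses default to all samples (the denominator used for
headline frequencies), with deduplication available upstream.

## Logistic cline regression

`fit_logistic()` fits $\operatorname{logit} P(y = 1) = \beta_0 +
\beta_1 x$ by iteratively reweighted least squares, written out rather
than delegated, since slope inference on these codings is the core of
the geographic analysis. Numerical choices:

* initialisation at $\mu = (y + 1/2)/2$, convergence when the relative
  deviance change drops below $10^{-8}$ (25 iterations max), followed by
  up to three Newton polish steps to the stationary point;
* step-halving guarantees a non-increasing deviance trace;
* model significance is the 1-df likelihood-ratio chi-square against the
  intercept-only fit (reported alongside the Wald test on the slope);
* complete/quasi-separation is detected (working weights collapsing or
  $|\eta| > 30$) and flagged as non-converged rather than reported — no
  penalisation is applied;
* all-0/all-1 outcomes and constant predictors are errors.

`run_cline_battery()` runs the standard grid: latitude over the
Peninsula, optionally adding Sicily and then Sardinia; longitude over
the North only (the one continuous west–east transect bounded by the
natural ranges of *A. m. mellifera* and *A. m. carnica*); production
year within macro-area groups, including only macro-area-by-year cells
with more than 100 samples to guard against sparse-cell artefacts. Each
combination is fitted pooled and per year; empty or degenerate cells are
recorded as skipped rather than failing the battery.

```{r battery}
d <- simulate_dataset(sim_config(n_beekeepers = 400, seed = 7))
run_cline_battery(d, codings = "contains-A", predictors = "latitude",
                  per_year = FALSE)
```

## Per-beekeeper trends: Modified Mann–Kendall

Each beekeeper active in at least four years contributes a yearly
lineage-diversity series: the number of distinct lineages (1–3) in the
union of all that year's patterns. Kendall's $S = \sum_{i<j}
\operatorname{sign}(x_j - x_i)$ and tie-adjusted $\tau_b$ are computed
exactly; $\operatorname{var}(S)$ uses the standard tie-corrected
formula. The Modified Mann–Kendall correction follows Hamed–Rao — the
canonical "MMK" variant, adopted because no variant is otherwise
specified: lag autocorrelations of the rank-transformed series, retained
when significant at 5% (two-sided normal approximation, lags up to
$n-3$), inflate the variance by
$1 + \tfrac{2}{n(n-1)(n-2)} \sum_i (n-i)(n-i-1)(n-i-2)\,\rho_r(i)$,
floored at 0.01 so the corrected variance stays positive. The test
statistic uses the standard continuity correction,
$z = (S - \operatorname{sign}(S))/\sqrt{\operatorname{var}^*(S)}$.
Calendar-year order handles gap years: Kendall statistics depend only on
order, not spacing.

Two policies deserve note because the heavily tied, short series make
them consequential:

* **Variance of $\tau$ for meta-analysis** uses the untied denominator
  $D = n(n-1)/2$, i.e. $\operatorname{var}(\tau) =
  \operatorname{var}^*(S)/D^2$. With {1,2,3}-valued series of length
  4–6, $\tau_b$ denominators fluctuate wildly with the tie structure;
  the untied denominator is stable. The choice is configurable
  (`tau_denominator = "tau_b"`).
* **Constant series** (a beekeeper reporting identical diversity every
  year) are degenerate: $\tau = 0$ is forwarded with the untied-formula
  variance and a flag, so the meta-analysis can either keep them
  (default — they carry genuine "no change" information and no exclusion
  rule is imposed) or drop them (`exclude_degenerate = TRUE`). This
  convention is this package's policy; it is one of the genuinely open
  choices in this design.

## Pooling: REML random-effects meta-analysis

Per-beekeeper $\tau$ estimates are pooled in a random-effects model with
a geographic moderator, coded as dummies without intercept so each
coefficient is its area's pooled mean $\tau$. Two schemes are built in:
the five areas, and the macro-area scheme with Central and South
combined (North, Central–South, Sicily, Sardinia) — both appear in
practice and the package makes no attempt to privilege one. The
between-study variance $\tau^2$ (deliberately named `tau2` to avoid the
symbol collision with Kendall's $\tau$) is estimated by REML: the score
$-\tfrac12[\operatorname{tr}(P) - y^\top P^2 y]$ is solved on
$[0, \infty)$ by bracketing and Brent's method (bisection-safeguarded)
to $10^{-12}$, returning the boundary 0 when the score at zero is
non-positive. Weights are $1/(v_i + \hat\tau^2)$; confidence intervals
are normal-based at 95% (the framework's default), with a Knapp–Hartung
adjustment behind a flag. Residual heterogeneity $Q_E$ is computed with
fixed-effect weights. Whether pooled weighting should use the
MMK-corrected or raw variance of $\tau$ is not settled; the corrected
variance is used, and either can be passed via the `variance` column
argument. A level contributing a single estimate is pooled with its own
$v_i + \hat\tau^2$ as variance and flagged.

```{r meta}
trends <- mk_trend(d)
fit <- fit_meta(trends, scheme = "macro_areas")
tidy(fit)
```

`autoplot(fit)` draws the forest plot with dot sizes proportional to the
number of contributing beekeepers.

## Within-year consistency

`classify_consistency()` classifies beekeepers with two or more
same-year samples by whether every sample shares one exact pattern:
"consistent" means identical patterns, not merely overlapping lineages —
a beekeeper submitting {C} and {A,C} is "different patterns". Uniform
non-C categories are labelled per shared pattern by default and can be
collapsed, since the published category structure for those bars is not
fully legible.

## Verification strategy and problem sizes

Every hand-written statistic is checked against an independent route:
Kendall $S/\tau/\operatorname{var}(S)$ against exhaustive pair
enumeration over all {1,2,3}-valued series up to length 6 and against
`cor(method = "kendall")`; the IRLS slope against the closed-form log
odds ratio on binary predictors and against `glm` on random datasets;
REML $\hat\tau^2$ against a grid-plus-golden-section maximiser of an
independently coded restricted likelihood and against `metafor::rma`;
pooled detection against direct binomial simulation. Calibration uses
10,000 length-8 null series for the MMK test (discreteness makes it
conservative; the empirical size is well under the nominal 5%) and 500
null logistic fits at n = 10,000. Parameter recovery uses 100 replicate
surveys of ≈2,000 samples for slope-sign recovery through the full
pooled-union generator — where the marginal sample-level slope has no
closed form, so the sign is the testable quantity — and 100 replicates
of data generated directly from the logistic law, where the true slope
is defined, for CI coverage; REML recovery uses 200 replicates at
k = 200. Pooled-τ structure is assessed over five replicate surveys
because a single survey's pooled estimates carry sampling noise of
about 0.04. These sizes were chosen to give Monte-Carlo error well
inside the assertion margins while keeping a full verification run in a
few minutes.

## Known limitations

* Lineages are categorical labels; no sequence-level simulation, and no
  C1/C2 mitotype resolution (the assay modelled here cannot separate
  them).
* Single-predictor models only — no splines, no spatial autocorrelation,
  no multivariable geography, matching the analysis design this package
  reproduces.
* The generator's i.i.d.-colonies default understates within-apiary
  correlation; island frequencies are therefore more extreme than a
  clustered reality would produce (synthetic Sicily's contains-A
  approaches 1 rather than ≈0.66).
* Nuclear introgression is invisible to mtDNA entirely.
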