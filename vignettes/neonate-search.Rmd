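---
title: "Detecting active search for ungulate neonates from dual GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting active search for ungulate neonates from dual GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetrack)
```

## The inference problem

Many large herbivores give birth in a short, predictable seasonal window —
the *birth pulse* — during which neonates are highly vulnerable. Whether a
carnivore merely stumbles on newborns (incidental encounter) or actively
hunts for them (active search) has very different consequences for prey
demography, but the two are hard to separate because a predator may end up
near prey simply by preferring the same habitat. `pulsetrack` implements an
inference chain that separates them using contemporaneous GPS telemetry of
predators and prey:

1. **Parturition detection.** Births of collared females are inferred from
   movement alone: a parturition event is declared on the first run of
   evaluation times whose trailing 24-h minimum-convex-polygon (MCP) area
   stays at or below a species threshold (30 ha for elk, 15 ha for mule
   deer) for at least 120 h. Mothers with neonates localize; the collapse of
   the daily range is the signal.
2. **Step-selection function (SSF) with an encounter covariate.** Each
   observed predator step is compared with K = 20 random steps drawn from
   the predator's fitted Gamma step-length and von Mises turning-angle
   kernels. The covariate of interest is a binary indicator that the step
   endpoint lies within 200 m of a collared female inside her 30-day
   post-partum window at the time of near-simultaneous fixes. Conditional
   logistic regression on the matched strata estimates selection for
   encounters *after* controlling for canopy, vegetation class, ruggedness,
   log distances to road and water, log step length and cos(turning angle).
   A positive encounter coefficient that habitat cannot explain is evidence
   of active search.
3. **Parturition-habitat RSF.** A binomial GLM contrasts prey locations in
   the 7 days after each birth with a 1:10 uniform availability sample,
   over the full ten-covariate habitat model (no model selection). The
   exponential score w(x) = exp(beta'x), computed per 30-m cell without the
   intercept, maps where neonates are likely to be.
4. **Phenology tracking.** Weekly mean RSF scores at each predator's fixes
   (15 April–31 July) are modeled with a random-intercept linear mixed model
   in Julian week, fitted by maximum likelihood; a likelihood-ratio test
   compares quadratic against linear week effects. A supported concave
   quadratic whose peak sits on the birth pulse indicates the predator
   re-targets parturition habitat exactly when neonates are most available.

Every stage can be exercised end to end on synthetic telemetry with known
ground truth, which is how the package validates itself.

## The synthetic-data generator

The generator emulates the telemetry design the analyses expect: elk-like
prey on 30-min fixes (mule-deer-like on 60–90-min), carnivores on 2–3-h
fixes with a small per-animal clock jitter so predator fix times rarely
coincide exactly with prey fix times (forcing the temporal matching rule to
do real work), and a late-May birth pulse (mean day-of-year 147, sd 7 d).

* **Landscapes** are Gaussian-random-field covariate layers (canopy,
  ruggedness, shrub, forb, slope, elevation; aspect from field gradients; a
  four-class vegetation map cut from a smoothed field at the configured
  proportions) plus true Euclidean distance-to-feature layers for roads and
  streams, on a 30-m grid with the origin at the lower-left corner.
* **Prey** move as a correlated random walk (Gamma step lengths, von Mises
  turns). At a birth time drawn from the pulse the animal localizes: every
  fix for the localization duration (default 144 h ≥ the 120-h detection
  requirement) falls within the localization radius (default 50 m) of the
  birth site. The analyses make no assumption about behavior after the
  mother–young pair rejoins the herd, so post-localization movement is a
  free simulator choice: the usable radius grows linearly until pre-partum
  ranging resumes.
* **Predators** choose each step among M = 50 candidate endpoints drawn
  from their movement kernels, with probability proportional to
  exp(beta_land' z + beta_enc · enc), where z are landscape covariates
  standardized over the whole landscape and enc is the encounter indicator
  evaluated exactly as the analysis defines it. M is deliberately larger
  than the analysis K = 20: the candidate count controls generative sampler
  bias, whereas K belongs to estimation. An optional attraction term with a
  time-varying coefficient on the standardized log RSF surface produces the
  "searching predator" used to validate the phenology test.

Walks are kept on the raster by reflecting coordinates into a 300-m
interior margin; steps that would cross the boundary are slightly truncated
by the fold, which is why kernel-fidelity checks use landscapes large
relative to the step scale. All randomness derives from one integer seed
per call through a deterministic stream split, so any module can be re-run
independently and reproduces bit-identical output.

What the generator does *not* emulate matters for interpreting green tests:
there is no GPS measurement error or habitat-driven fix failure, no neonate
mortality (females count as parturient for the full 30 days, as the
analyses assume), no herding or interaction between animals, and real
landscapes are rougher than Gaussian fields. Passing validation shows the
estimators recover the truth under the stated movement model, not that
field data meet these assumptions.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold_ha` | 30 (elk), 15 (deer) | rolling-MCP area at or below which movement counts as localized |
| `min_duration_h` | 120 h | continuous qualifying run required for an event |
| `window_h` | 24 h | trailing MCP window |
| `K` | 20 | random steps per observed step |
| `radius_m` | 200 m | encounter radius, inclusive |
| `window_d` | 30 d | post-partum window during which a female is "parturient" |
| `tolerance` | 15 min | temporal match window; half the prey fix interval |
| `days` (RSF) | 7 | post-partum days defining used points |
| `ratio` | 10 | available : used |
| season | 15 Apr–31 Jul | phenology window |

The deer threshold's published wording ("<15 hectares or less") is
internally contradictory; both the area threshold and the 120-h duration
are implemented as **inclusive** comparisons. The rolling window is
evaluated at every fix time rather than in daily bins — the validation
statistic is a timing error in hours, which demands sub-daily resolution —
and the event is anchored at the start of the qualifying run with no
back-shift. The "simultaneous positions" of the encounter covariate are
operationalized as the nearest prey fix within half the prey's nominal fix
interval (ties to the earlier fix); prey are sampled 4–6 times faster than
predators, so a near-contemporaneous fix essentially always exists.

## Numerical choices

* **Conditional logistic likelihood** (authored in this package): Newton
  iteration from beta = 0 with step-halving on any likelihood decrease,
  convergence at gradient max-norm < 1e-8, 100-iteration cap, per-stratum
  log-sum-exp shifts for stability. Standard errors come from the inverse
  observed information. Separation (e.g. the encounter indicator perfectly
  predicting observed steps) is reported as non-convergence with a
  diagnostic — either a singular information matrix or a coefficient
  diverging past |beta| = 15 on the standardized scale — never as a silent
  estimate. Tests cross-check the solver against an independent dense grid
  search and against `survival::clogit`.
* **Standardization** is computed once per fitted model over that model's
  full design (observed + random steps; used + available points), so
  coefficients are comparable within a fit. Zero-variance columns are left
  unscaled and flagged. cos(turning angle) is already a bounded index and
  stays unscaled; ln(step length) is standardized with the rest.
  Distances enter as ln(d + 1 m) so on-feature cells stay finite.
* **Aspect** is circular, and raw degrees in a linear model are
  statistically incoherent; the RSF therefore uses sin + cos components by
  default, with `aspect_mode = "degrees"` available to reproduce the
  literal single-covariate formula.
* **Mixed models** are fitted by ML (not REML) because the LRT compares
  fixed effects; week is centered at its range midpoint and scaled to unit
  sd before squaring to avoid collinearity between week and week². A
  singular random-intercept fit (variance 0) falls back to OLS — the same
  ML objective with the variance profiled out — and is flagged.
* **Degenerate inputs**: MCPs of fewer than three distinct non-collinear
  points have area 0; windows with under 3 fixes count as localized only
  because the animal is present (area 0); turning angles after a
  zero-length step are undefined and the stratum is skipped; off-raster
  random endpoints are dropped (a stratum is dropped only if its *observed*
  endpoint is off-raster).

## Design choices on open questions

* Steps are pooled across individuals into one conditional-logistic fit per
  species (or species × sex, mirroring the separate male/female bear
  models), with strata = steps; this matches reporting a single coefficient
  per species. Sex-specific fits are the same operation on filtered input.
* Strata in which no endpoint could ever encounter prey are retained; they
  still inform the habitat coefficients.
* The availability region is the convex hull (MCP) of all prey fixes, with
  an arbitrary supplied polygon accepted; availability is pooled across
  years and sampled with replacement.
* Weekly means are unweighted by fix count (minimum one fix per record,
  configurable); records are treated as independent given the animal
  intercept — no temporal autocorrelation term, matching the stated model.
* Only **complete** Julian weeks — those whose full 7-day span lies inside
  the season window (weeks 16–30 for 15 Apr–31 Jul) — enter the phenology
  model by default. The window boundaries slice the terminal weeks down to
  1–2 days of fixes, inflating those weekly means' sampling variance
  roughly sevenfold precisely at the extremes of the week axis, where the
  extra noise loads on the quadratic term: in null simulations this alone
  raised the quadratic LRT's rejection rate from the nominal 5% to ~16%.
  Dropping incomplete weeks restores the nominal size; the truncating
  behavior remains available via `complete_weeks = FALSE`.
* Weekly RSF scores enter the phenology model raw; their scale is absorbed
  by the response standardization implicit in the LMM. Julian week w covers
  days 7w−6..7w, so a pulse peaking on day d corresponds to week coordinate
  (d + 3)/7 when a fitted peak is compared with the generative truth.

## Validation summary (what the tests compute)

The test suite and `scripts/acceptance.R` recompute, from fresh synthetic
data: the Newton-vs-grid agreement of the conditional-logistic solver;
recovery of a generative encounter coefficient of 0.9 from 15 predators
tracked 90 days (20 replicates) and the Wald test's size from 200 null
replicates at a reduced scale (5 predators, 30 days — a deliberate
scaled-down Monte Carlo); detection of 30 synthetic births with the
timing-error statistic that the field validation of the rolling-MCP method
reports in hours, plus a false-positive rate on 30 non-parturient controls;
componentwise recovery of known RSF coefficients at 1000 used points and
rank-invariance of the predicted surface to the availability ratio; and the
power (10 searching predators, 15 weeks, 100 replicates) and size (100
indifferent-predator replicates) of the quadratic-week LRT together with
the recovered peak week. Two deliberate choices shape the phenology
scenario: the parturition-habitat surface is built from known moderate
coefficients (the generative truth) rather than refitted each time — an RSF
refitted to a handful of 50-m synthetic birth clusters sits near separation
and yields scores spanning dozens of orders of magnitude, which no fitted
surface on a real landscape does — and the predators carry Gaussian
home-range attachment (sd 800 m), because resident carnivores range within
stable home ranges rather than drifting across the landscape, and weekly
habitat-use records are only exchangeable given the animal intercept when
movement mixes through the home range on a sub-weekly timescale. The
vignette intentionally quotes no numbers that those scripts do not compute.

## Known limitations

* The RSF fitted to a handful of tightly localized birth clusters can sit
  near separation; the fit is flagged and the predicted surface is then
  only rank-meaningful, which is all the phenology response requires.
* The conditional-logistic solver assumes strata small enough to enumerate
  (always true here: K + 1 rows); it is not a general sparse conditional
  likelihood engine.
* Coordinates are exact planar meters; there is no geodesy and no CRS
  handling. Raster I/O is the plain-text ESRI ASCII grid with a JSON
  sidecar.
* Movement kernels are fitted once and held fixed (no integrated SSF that
  re-estimates kernels inside the likelihood), matching the analysis the
  package implements.
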