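# pulsetrack

Tools for asking whether carnivores **actively search** for ungulate
neonates during the seasonal birth pulse, or merely stumble on them, using
contemporaneous GPS telemetry of predators and prey. The package is aimed
at movement ecologists with dual predator–prey collar data (e.g. cougars,
coyotes, black bears or bobcats tracked alongside elk or mule deer), and at
methodologists who want the whole inference chain exercisable on synthetic
telemetry with known ground truth.

## The inference chain

1. **Parturition detection** (`detect_parturition`). Births are inferred
   from movement alone: a parturition event is declared at the start of the
   first run of fix times whose trailing 24-h minimum-convex-polygon area
   stays ≤ 30 ha (elk; ≤ 15 ha for deer) for ≥ 120 h continuously. Mothers
   of neonates localize; the collapse of the daily range is the signal.
2. **Step-selection function with an encounter covariate**
   (`build_strata`, `fit_conditional_logistic`). Each observed predator
   step is matched with K = 20 random steps drawn from fitted Gamma
   (step-length) and von Mises (turning-angle) kernels, and the model

   *w*(x) ∝ exp(β₁·enc + β₂·canopy + β₃·veg + β₄·ruggedness +
   β₅·ln d(road) + β₆·ln d(water) + β₇·ln SL + β₈·cos TA)

   is estimated by conditional logistic regression over the matched strata
   (Newton iteration on the exact conditional likelihood, authored here and
   cross-checked against `survival::clogit` and a dense grid search in the
   tests). `enc` indicates a step endpoint within 200 m of a collared
   female inside her 30-day post-partum window at near-simultaneous fix
   times. β₁ > 0 after the habitat terms is evidence of active search.
3. **Parturition-habitat RSF** (`fit_rsf`, `predict_surface`). Logistic
   regression of prey locations in the 7 days after birth against a 1:10
   uniform availability sample over ten habitat covariates (global model,
   no selection), projected as the exponential score w(x) = exp(β'x) per
   30-m cell.
4. **Phenology tracking** (`weekly_use`, `fit_phenology`,
   `lrt_phenology`, `peak_week`). Weekly mean RSF scores at each
   predator's fixes (15 Apr–31 Jul) are modeled with a random-intercept
   linear mixed model in Julian week (ML), and a likelihood-ratio test
   compares quadratic vs linear week effects. A supported concave quadratic
   peaking on the birth pulse indicates the predator re-targets parturition
   habitat exactly when neonates are most available.

A synthetic-telemetry generator (`generate_landscape`, `simulate_prey`,
`simulate_predator`) produces landscapes, prey with a late-May birth pulse
and post-partum localization, and predators whose steps are drawn from an
exponential selection rule with known coefficients — so every stage can be
validated against ground truth. See the vignette
(`vignettes/neonate-search.Rmd`) for the models, assumptions and design
decisions.

## Worked example

Simulate a season of dual telemetry, detect the births, and test whether
the predators' steps over-represent proximity to parturient females:

```r
library(pulsetrack)

landscape <- generate_landscape(landscape_config(extent = c(6000, 6000), seed = 42))
prey <- simulate_prey(prey_config(start = "2017-04-15", n_days = 100),
                      landscape, n_animals = 10, seed = 42)

events <- detect_parturition_all(prey$fixes, threshold_ha = 30, min_duration_h = 120)
score_detections(events, prey$events, max_offset_h = 72)$mean_abs_dt_h
#> [1] 16.6375

pred_cfg <- predator_config(species = "cougar", start = "2017-05-10", n_days = 60,
                            beta_land = c(canopy = 0.3, ruggedness = -0.2,
                                          ln_dist_road = 0.2),
                            beta_enc = 0.9)
predators <- simulate_predator(pred_cfg, landscape, prey = prey,
                               n_animals = 8, seed = 7)
strata <- build_strata(predators, landscape,
                       parturient_set = list(fixes = prey$fixes, events = events),
                       K = 20, seed = 7)
fit_conditional_logistic(strata)
#> <selection_fit> 3832 strata, logLik = -11248.066, converged (6 iterations)
#>               term  estimate      se      z        p
#>                enc  0.966500 0.07875 12.300 1.27e-34
#>             canopy  0.281300 0.02342 12.000 3.22e-33
#>         ruggedness -0.160400 0.01957 -8.190 2.54e-16
#>       ln_dist_road  0.137100 0.02556  5.360 8.13e-08
#>      ln_dist_water -0.006887 0.03456 -0.199 8.42e-01
#>     ln_step_length  0.106000 0.01749  6.060 1.36e-09
#>           cos_turn  0.060860 0.02403  2.530 1.13e-02
#>  veg_closed_forest  0.097930 0.05382  1.820 6.88e-02
#>      veg_grassland  0.121200 0.06259  1.940 5.28e-02
#>          veg_other  0.165300 0.07450  2.220 2.65e-02
```

All ten synthetic births are detected with a mean timing error of 16.6 h.
The fitted encounter coefficient (0.97 ± 0.08, on the binary indicator) is
close to its generative truth of 0.9 and strongly positive after the
habitat terms — the "active search" signature — while the habitat
coefficients recover the configured preferences (canopy +0.3, ruggedness
−0.2, road avoidance +0.2) up to the standardization scale.

A thin command-line wrapper with `detect` / `ssf` / `rsf` / `phenology`
subcommands is installed at `inst/cli/pulsetrack.R`.

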