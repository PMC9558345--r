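# Packaged validation scenarios: fixed study conditions under which the
# inference chain is exercised against ground truth. Defaults mirror the
# telemetry design the package targets (elk on 30-min fixes with a late-May
# birth pulse, carnivores on 3-h fixes, 20 random steps per observed step,
# 200-m encounters, 30-d post-partum windows) so that simulation studies and
# the acceptance checks run the same conditions.

#' Default validation landscape
#'
#' 6 x 6 km, 30-m cells, smooth covariate fields, three roads and two
#' streams.
#'
#' @param seed integer seed.
#' @param extent_m landscape edge length (m).
#' @return a `covariate_stack`.
#' @export
scenario_landscape <- function(seed = 1L, extent_m = 6000) {
  generate_landscape(landscape_config(extent = c(extent_m, extent_m),
                                      seed = split_seed(seed, 101L)))
}

#' One step-selection parameter-recovery replicate
#'
#' Simulates parturient elk and predators whose steps are drawn with a known
#' encounter coefficient, rebuilds the matched strata with the analysis
#' K = 20, and refits the conditional logistic model. Landscape habitat
#' preferences (canopy +0.3, ruggedness -0.2, road avoidance +0.2 on
#' ln distance) are part of the generative truth so the encounter effect must
#' be recovered after controlling for habitat.
#'
#' @param seed integer replicate seed.
#' @param beta_enc true encounter coefficient.
#' @param n_predators,n_prey animal counts.
#' @param n_days predator tracking duration (days).
#' @param K random steps per observed step in the analysis.
#' @param landscape optional `covariate_stack` to reuse across replicates.
#' @return list: `fit` (`selection_fit`), `beta_enc_hat`, `p_enc` (Wald p),
#'   `beta_enc_true`, `n_strata`.
#' @export
ssf_recovery_replicate <- function(seed, beta_enc = 0.9, n_predators = 15,
                                   n_prey = 15, n_days = 90, K = 20,
                                   landscape = NULL) {
  if (is.null(landscape)) landscape <- scenario_landscape(seed)
  prey <- simulate_prey(prey_config(start = "2017-04-15", n_days = 115),
                        landscape, n_animals = n_prey,
                        seed = split_seed(seed, 1L))
  cfg <- predator_config(start = "2017-05-10", n_days = n_days,
                         beta_land = c(canopy = 0.3, ruggedness = -0.2,
                                       ln_dist_road = 0.2),
                         beta_enc = beta_enc)
  pred <- simulate_predator(cfg, landscape, prey = prey,
                            n_animals = n_predators,
                            seed = split_seed(seed, 2L))
  strata <- build_strata(pred, landscape, parturient_set = prey, K = K,
                         seed = split_seed(seed, 3L))
  fit <- fit_conditional_logistic(strata)
  i <- match("enc", fit$coefficients$term)
  list(fit = fit, beta_enc_hat = fit$coefficients$estimate[i],
       p_enc = fit$coefficients$p[i], beta_enc_true = beta_enc,
       n_strata = fit$n_strata)
}

#' Parturition-detector validation scenario
#'
#' Simulates elk-like trajectories with known births (50-m localization,
#' 144 h) plus non-parturient controls, runs the 30-ha / 120-h rolling-MCP
#' detector, and scores detections against the truth.
#'
#' @param seed integer seed.
#' @param n_parturient,n_controls animal counts.
#' @param landscape optional reused landscape.
#' @return list: `score` (from [score_detections()]), `fp_rate` (controls
#'   falsely detected), `n_parturient`, `n_controls`.
#' @export
parturition_scenario <- function(seed, n_parturient = 30, n_controls = 30,
                                 landscape = NULL) {
  if (is.null(landscape)) landscape <- scenario_landscape(seed)
  par_prey <- simulate_prey(prey_config(start = "2017-04-15", n_days = 100),
                            landscape, n_animals = n_parturient,
                            seed = split_seed(seed, 11L))
  detected <- detect_parturition_all(par_prey$fixes, threshold_ha = 30,
                                     min_duration_h = 120)
  score <- score_detections(detected, par_prey$events, max_offset_h = 72)
  ctl <- simulate_prey(prey_config(start = "2017-04-15", n_days = 100,
                                   p_parturient = 0),
                       landscape, n_animals = n_controls,
                       seed = split_seed(seed, 12L))
  ctl_det <- detect_parturition_all(ctl$fixes, threshold_ha = 30,
                                    min_duration_h = 120)
  list(score = score, fp_rate = nrow(ctl_det) / n_controls,
       n_parturient = n_parturient, n_controls = n_controls)
}

#' RSF parameter-recovery scenario
#'
#' Used points are sampled from the landscape's cells with probability
#' proportional to exp(beta' z) for a known beta on landscape-standardized
#' covariates; availability is drawn uniformly over the full extent at the
#' 1:10 ratio; the fitted coefficients are compared with the truth.
#'
#' @param seed integer seed.
#' @param n_used number of used points.
#' @param beta_true named true coefficients (design covariate names).
#' @param ratio available:used ratio.
#' @param landscape optional reused landscape.
#' @return list: `fit` (`rsf_fit`), `comparison` (term, truth, estimate, se),
#'   `landscape`, `used`.
#' @export
rsf_recovery_scenario <- function(seed, n_used = 1000,
                                  beta_true = c(canopy = 0.5, shrub = 0.4,
                                                ruggedness = -0.3,
                                                ln_dist_road = 0.25,
                                                elevation = -0.2),
                                  ratio = 10, landscape = NULL) {
  if (is.null(landscape)) landscape <- scenario_landscape(seed)
  set.seed(split_seed(seed, 21L))
  zl <- build_z_layers(landscape, beta_true)
  lp <- 0
  for (nm in names(beta_true)) lp <- lp + beta_true[[nm]] * zl[[nm]]
  pr <- exp(lp - max(lp))
  idx <- sample.int(length(pr), n_used, replace = TRUE, prob = pr)
  cc <- cell_centers(landscape)
  row <- (idx - 1L) %% landscape$nrow + 1L
  col <- (idx - 1L) %/% landscape$nrow + 1L
  cs <- landscape$cell_size
  used <- data.frame(x = cc$x[col] + stats::runif(n_used, -cs / 2, cs / 2),
                     y = cc$y[row] + stats::runif(n_used, -cs / 2, cs / 2))
  ext <- stack_extent(landscape)
  polygon <- cbind(x = ext[c(1, 2, 2, 1)], y = ext[c(3, 3, 4, 4)])
  avail <- draw_available(polygon, n_used, ratio = ratio,
                          seed = split_seed(seed, 22L))
  fit <- fit_rsf(used, avail, landscape)
  est <- fit$coefficients
  comparison <- data.frame(term = names(beta_true),
                           truth = as.numeric(beta_true),
                           estimate = est$estimate[match(names(beta_true),
                                                         est$term)],
                           se = est$se[match(names(beta_true), est$term)])
  list(fit = fit, comparison = comparison, landscape = landscape,
       used = used)
}

#' Set up the phenology-tracking scenario
#'
#' Builds a landscape and the parturition-habitat selection surface the
#' predators respond to. The surface is constructed from known, moderate
#' coefficients on landscape-standardized covariates (the generative truth),
#' giving the realistic 2-3 orders of magnitude of score variation a fitted
#' parturition RSF shows on real landscapes; a surface refitted from a
#' handful of tightly localized synthetic birth clusters sits near
#' separation and produces astronomically heavy-tailed scores instead.
#'
#' @param seed integer seed.
#' @param beta_par known surface coefficients.
#' @return list: `landscape`, `surface` (a `selection_surface`), `beta_par`,
#'   `pulse_peak_doy` (mean birth day-of-year), `pulse_peak_week`.
#' @export
phenology_scenario_setup <- function(seed = 1L,
                                     beta_par = c(canopy = 0.5, shrub = 0.4,
                                                  ruggedness = -0.3,
                                                  ln_dist_road = 0.25,
                                                  elevation = -0.2)) {
  landscape <- scenario_landscape(seed)
  zl <- build_z_layers(landscape, beta_par)
  lp <- 0
  for (nm in names(beta_par)) lp <- lp + beta_par[[nm]] * zl[[nm]]
  surface <- structure(list(
    stack = covariate_stack(list(rsf_score = exp(lp)),
                            cell_size = landscape$cell_size,
                            xmin = landscape$xmin, ymin = landscape$ymin),
    fit_terms = names(beta_par), aspect_mode = "sincos"),
    class = "selection_surface")
  pc <- prey_config()
  # julian week w spans days 7w-6 .. 7w, so its midpoint is day 7w - 3 and a
  # pulse peaking on day d sits at week coordinate (d + 3) / 7
  list(landscape = landscape, surface = surface, beta_par = beta_par,
       pulse_peak_doy = pc$birth_doy_mean,
       pulse_peak_week = (pc$birth_doy_mean + 3) / 7)
}

#' One phenology power / size replicate
#'
#' Simulates predators over 15 April - 31 July. In the "searching" scenario
#' their attraction to the parturition-habitat surface follows a Gaussian
#' seasonal pulse centered on the mean birth date (sd 14 d, peak coefficient
#' 1.5 on the standardized log surface); in the "indifferent" scenario the
#' attraction is zero. Weekly mean RSF scores are modeled with the
#' random-intercept LMM and the quadratic-week LRT is returned.
#'
#' @param setup output of [phenology_scenario_setup()].
#' @param seed integer replicate seed.
#' @param searching logical scenario switch.
#' @param n_predators number of predators.
#' @param peak_coef peak attraction coefficient (searching scenario).
#' @return list: `p` (LRT p-value), `peak_week` (NA when the quadratic is not
#'   concave), `lrt`, `n_records`.
#' @export
phenology_replicate <- function(setup, seed, searching = TRUE,
                                n_predators = 10, peak_coef = 1.5) {
  peak_doy <- setup$pulse_peak_doy
  weight <- if (searching) {
    function(t) peak_coef * exp(-(doy_frac(t) - peak_doy)^2 / (2 * 14^2))
  } else {
    function(t) rep(0, length(t))
  }
  cfg <- predator_config(species = "black_bear", sex = "M",
                         start = "2017-04-15", n_days = 107,
                         beta_land = c(canopy = 0.3, ruggedness = -0.2),
                         home_range_sd = 800,
                         attraction = list(surface = setup$surface,
                                           weight = weight))
  pred <- simulate_predator(cfg, setup$landscape, n_animals = n_predators,
                            seed = split_seed(seed, 41L))
  rec <- weekly_use(pred, setup$surface)
  f_lin <- fit_phenology(rec, "linear")
  f_quad <- fit_phenology(rec, "quadratic")
  lrt <- lrt_phenology(f_quad, f_lin)
  pw <- tryCatch(peak_week(f_quad), error = function(e) NA_real_)
  list(p = lrt$p, peak_week = pw, lrt = lrt, n_records = nrow(rec))
}
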