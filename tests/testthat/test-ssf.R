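test_that("step decomposition gets lengths, bearings and signed turns right", {
  fx <- make_fixes(rbind(c(0, 0), c(1000, 0), c(2000, 0)))
  st <- decompose_steps(fx)
  expect_equal(st$length, c(1000, 1000))
  expect_equal(st$turn, c(NA, 0))
  # left turn is positive (counterclockwise convention)
  fx2 <- make_fixes(rbind(c(0, 0), c(1000, 0), c(1000, 1000)))
  expect_equal(decompose_steps(fx2)$turn[2], pi / 2)
  # closed square loop: four identical-sign turns summing to 2*pi
  loop <- make_fixes(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0),
                           c(1, 0)))
  turns <- decompose_steps(loop)$turn[-1]
  expect_equal(turns, rep(pi / 2, 4))
  expect_equal(sum(turns), 2 * pi)
  # zero-length step leaves the following turn undefined
  fx3 <- make_fixes(rbind(c(0, 0), c(0, 0), c(5, 5)))
  expect_true(is.na(decompose_steps(fx3)$turn[2]))
})

test_that("movement kernels are recovered by maximum likelihood", {
  set.seed(2024)
  n <- 1e4
  steps <- data.frame(length = rgamma(n, shape = 2, scale = 300),
                      turn = rvonmises(n, 0, 1.5))
  k <- fit_step_kernels(steps)
  expect_true(k$gamma_shape > 1.9 && k$gamma_shape < 2.1)
  expect_true(k$gamma_scale > 285 && k$gamma_scale < 315)
  expect_equal(k$vm_mu, 0, tolerance = 0.05)
  expect_equal(k$vm_kappa, 1.5, tolerance = 0.1)
  # symmetric turns about 0 -> mu near 0; uniform turns -> kappa near 0
  unif <- data.frame(length = rgamma(n, 2, scale = 100),
                     turn = runif(n, -pi, pi))
  expect_lt(fit_step_kernels(unif)$vm_kappa, 0.05)
  ident <- data.frame(length = rep(100, 50), turn = rep(0.1, 50))
  expect_error(fit_step_kernels(ident), "identical")
})

test_that("von Mises density integrates to 1 and sampler matches the density", {
  for (kp in c(0.5, 2, 20)) {
    expect_equal(integrate(dvonmises, -pi, pi, mu = 0.5, kappa = kp)$value,
                 1, tolerance = 1e-6)
  }
  set.seed(11)
  th <- rvonmises(2e4, mu = 0.8, kappa = 2)
  f <- fit_vonmises(th)
  expect_equal(f$mu, 0.8, tolerance = 0.05)
  expect_equal(f$kappa, 2, tolerance = 0.1)
})

test_that("random steps follow the kernels and the previous bearing", {
  fx <- make_fixes(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
  steps <- decompose_steps(fx)
  k <- structure(list(gamma_shape = 2, gamma_scale = 300, vm_mu = 0,
                      vm_kappa = 500), class = "step_kernels")
  rs <- generate_random_steps(steps, k, K = 50, seed = 3)
  # kappa -> infinity surrogate: candidates nearly collinear with the
  # previous bearing (for step 2, previous bearing is east)
  s2 <- rs[rs$step_row == 2, ]
  expect_true(all(abs(atan2(s2$y - 0, s2$x - 1000)) < 0.2))
  expect_identical(rs, generate_random_steps(steps, k, K = 50, seed = 3))
  # generated distances match the generating Gamma (KS)
  k2 <- structure(list(gamma_shape = 2, gamma_scale = 300, vm_mu = 0,
                       vm_kappa = 1), class = "step_kernels")
  set.seed(33)
  long <- make_fixes(cbind(cumsum(runif(600, 100, 300)), rnorm(600, 0, 50)))
  rs2 <- generate_random_steps(decompose_steps(long), k2, K = 20, seed = 4)
  expect_gte(nrow(rs2), 1e4)
  ks <- suppressWarnings(ks.test(rs2$length, pgamma, shape = 2,
                                 scale = 300))
  expect_gt(ks$p.value, 0.01)
})

test_that("the encounter indicator applies the 200-m / 30-day rules inclusively", {
  t0 <- as.POSIXct("2017-05-20 00:00:00", tz = "UTC")
  prey_fx <- make_fixes(cbind(rep(1000, 40 * 24 * 2 + 1),
                              rep(1000, 40 * 24 * 2 + 1)),
                        start = "2017-05-20", by_min = 30)
  pset <- list(fixes = prey_fx,
               events = data.frame(animal_id = "elk_01", event_time = t0))
  q <- function(x, days) encounter_indicator(
    x, 1000, t0 + days * 86400, pset)
  expect_equal(q(1150, 5), 1L)         # 150 m away, 5 d post-partum
  expect_equal(q(1150, 31), 0L)        # 31 d post-partum: window closed
  expect_equal(q(1200, 5), 1L)         # exactly 200.0 m: inclusive radius
  expect_equal(q(1200.5, 5), 0L)       # just beyond 200 m
  expect_equal(q(1150, -1), 0L)        # before the event
  # beyond the matching tolerance there is no contemporaneous fix: a query
  # 16 min past one fix and 14 min before the next has no match at 10 min
  late <- t0 + 5 * 86400 + 16 * 60
  expect_equal(encounter_indicator(1150, 1000, late, pset,
                                   tolerance = as.difftime(10,
                                                           units = "mins"),
                                   window_d = 30), 0L)
})

test_that("strata carry K+1 rows, proper covariates, and flags", {
  ls <- test_landscape(extent = 6000)
  cfg <- predator_config(start = "2017-05-10", n_days = 20,
                         gamma_scale = 150)
  fx <- simulate_predator(cfg, ls, n_animals = 1, seed = 13)
  st <- build_strata(fx, ls, K = 20, seed = 14)
  rows <- table(st$data$stratum)
  expect_equal(max(rows), 21)                       # K = 20 -> 21 rows
  expect_true(all(rows <= 21))
  expect_gte(mean(rows == 21), 0.8)                 # off-raster drops are rare
  expect_lte(st$n_strata, nrow(fx) - 2)
  expect_true(all(c("enc", "canopy", "ln_dist_road", "ln_step_length",
                    "cos_turn", "veg_closed_forest") %in% names(st$data)))
  # standardized pooled design: mean 0, sd 1
  expect_equal(mean(st$data$canopy), 0, tolerance = 1e-9)
  expect_equal(sd(st$data$canopy), 1, tolerance = 1e-9)
  expect_true(all(abs(st$data$cos_turn) <= 1))      # bounded, unscaled
  # constant landscape: zero-variance layers are flagged, not scaled
  cl <- constant_landscape()
  fx2 <- simulate_predator(predator_config(start = "2017-05-10", n_days = 20,
                                           gamma_scale = 60),
                           cl, n_animals = 1, seed = 15)
  st2 <- build_strata(fx2, cl, K = 5, seed = 16)
  expect_true(all(c("canopy", "ruggedness") %in% st2$skipped))
})

test_that("conditional logistic likelihood at zero matches the uniform-choice form", {
  ls <- test_landscape()
  fx <- simulate_predator(predator_config(start = "2017-05-10", n_days = 15,
                                          gamma_scale = 100),
                          ls, n_animals = 1, seed = 17)
  st <- build_strata(fx, ls, K = 20, seed = 18)
  full21 <- names(table(st$data$stratum))[table(st$data$stratum) == 21]
  dat <- st$data[st$data$stratum %in% full21, ]
  dat[, setdiff(names(dat), c("stratum", "y"))] <- 0
  f <- fit_conditional_logistic(dat)
  expect_equal(unname(f$coefficients$estimate), rep(0, nrow(f$coefficients)))
  expect_equal(f$logLik, -length(full21) * log(21), tolerance = 1e-9)
})

test_that("Newton solution matches dense grid search on toy strata", {
  # 3 strata, one binary covariate, K = 1
  toy <- data.frame(stratum = rep(1:3, each = 2), y = rep(c(1, 0), 3),
                    z = c(1, 0, 1, 0, 0, 1))
  f <- fit_conditional_logistic(toy)
  g <- grid_clogit(toy, "z")
  expect_equal(f$coefficients$estimate, g, tolerance = 1e-4)
  # 5 strata, two covariates
  set.seed(19)
  toy2 <- data.frame(stratum = rep(1:5, each = 4),
                     y = rep(c(1, 0, 0, 0), 5),
                     a = rnorm(20), b = rnorm(20))
  f2 <- fit_conditional_logistic(toy2)
  g2 <- grid_clogit(toy2, c("a", "b"), lims = c(-5, 5))
  expect_equal(f2$coefficients$estimate, g2, tolerance = 1e-3)
})

test_that("the conditional likelihood ignores stratum-constant shifts", {
  set.seed(20)
  dat <- data.frame(stratum = rep(1:40, each = 5),
                    y = rep(c(1, 0, 0, 0, 0), 40),
                    a = rnorm(200), b = rnorm(200))
  f1 <- fit_conditional_logistic(dat)
  shifted <- dat
  shifted$a[shifted$stratum == 7] <- shifted$a[shifted$stratum == 7] + 100
  f2 <- fit_conditional_logistic(shifted)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("the in-package solver agrees with survival::clogit", {
  skip_if_not_installed("survival")
  library(survival)
  ls <- test_landscape(extent = 3000)
  prey <- simulate_prey(prey_config(start = "2017-05-01", n_days = 50), ls,
                        n_animals = 3, seed = 22)
  fx <- simulate_predator(predator_config(start = "2017-05-10", n_days = 25,
                                          beta_enc = 1.5,
                                          gamma_scale = 250),
                          ls, prey = prey, n_animals = 2, seed = 23)
  st <- build_strata(fx, ls, parturient_set = prey, K = 10, seed = 24)
  f <- fit_conditional_logistic(st)
  terms <- f$coefficients$term
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + "),
                                 "+ strata(stratum)"))
  cl <- survival::clogit(fml, data = st$data)
  expect_equal(f$coefficients$estimate, unname(coef(cl)[terms]),
               tolerance = 1e-5)
  expect_equal(f$coefficients$se,
               unname(sqrt(diag(vcov(cl)))[terms]), tolerance = 1e-4)
  expect_equal(f$logLik, unname(cl$loglik[2]), tolerance = 1e-6)
})

test_that("separation is flagged, not silently returned", {
  sep <- data.frame(stratum = rep(1:20, each = 3), y = rep(c(1, 0, 0), 20),
                    z = rep(c(1, 0, 0), 20))
  f <- fit_conditional_logistic(sep)
  expect_false(f$converged)
  expect_match(f$diagnostic, "separation")
})

test_that("estimated encounter selection rises with the generative coefficient", {
  ls <- scenario_landscape(3, extent_m = 4000)
  means <- vapply(c(0, 0.5, 1), function(b) {
    reps <- vapply(1:3, function(r)
      ssf_recovery_replicate(100 * r + round(10 * b), beta_enc = b,
                             n_predators = 3, n_prey = 6, n_days = 30,
                             landscape = ls)$beta_enc_hat, 0)
    mean(reps)
  }, 0)
  expect_true(all(diff(means) > 0))
})
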