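make_surface <- function(values, n = 20, cell = 30) {
  covariate_stack(list(rsf_score = matrix(values, n, n)), cell_size = cell)
}

test_that("julian weeks count from January 1 in 7-day blocks", {
  t <- as.POSIXct(c("2017-01-01", "2017-01-07", "2017-01-08", "2017-05-27",
                    "2017-12-31"), tz = "UTC")
  expect_equal(julian_week(t), c(1L, 1L, 2L, 21L, 53L))
})

test_that("weekly means average the surface at the fixes", {
  su <- make_surface(2.5)
  fx <- make_fixes(cbind(rep(305, 24 * 14 + 1), rep(305, 24 * 14 + 1)),
                   start = "2017-05-01", by_min = 60,
                   animal_id = "bear_01", species = "black_bear", sex = "M")
  wu <- weekly_use(fx, su)
  expect_true(all(wu$mean_score == 2.5))     # stationary at a w = s cell
  expect_lte(nrow(wu), 3)
  # two fixes in one week on cells 1 and 3 -> mean 2
  m <- matrix(1, 20, 20); m[1, 1] <- 3      # top-left cell
  su2 <- covariate_stack(list(rsf_score = m), cell_size = 30)
  fx2 <- make_fixes(rbind(c(15, 585), c(300, 300)), start = "2017-05-02",
                    by_min = 60, animal_id = "bear_01",
                    species = "black_bear", sex = "M")
  wu2 <- weekly_use(fx2, su2)
  expect_equal(wu2$mean_score, 2)
  expect_equal(wu2$n_fixes, 2L)
  # weekly records are bounded by animals x weeks and invariant to order
  expect_lte(nrow(wu), length(unique(fx$animal_id)) * 16)
  wu_shuffled <- weekly_use(fx[sample(nrow(fx)), ], su)
  expect_equal(wu_shuffled, wu, ignore_attr = TRUE)
})

test_that("fixes outside the seasonal window or off-raster are excluded", {
  su <- make_surface(1)
  fx <- make_fixes(rbind(c(100, 100), c(5000, 5000)), start = "2017-03-01",
                   by_min = 60, animal_id = "c1", species = "cougar",
                   sex = "M")
  expect_warning(wu <- weekly_use(fx, su), "seasonal window")
  expect_equal(nrow(wu), 0)
})

test_that("phenology fits recover simple structure", {
  # constant response: intercept c, slopes ~ 0, variances ~ 0
  rec <- data.frame(animal_id = rep(c("a", "b"), each = 10), year = 2017,
                    julian_week = rep(16:25, 2), mean_score = 4, n_fixes = 5)
  f <- fit_phenology(rec, "quadratic")
  expect_equal(f$fixed$estimate[f$fixed$term == "(Intercept)"], 4,
               tolerance = 1e-6)
  expect_equal(f$fixed$estimate[f$fixed$term %in% c("wk", "wk2")], c(0, 0),
               tolerance = 1e-6)
  expect_lt(f$var_resid, 1e-10)
  # quadratic nests linear: its ML logLik can only be higher
  set.seed(51)
  rec2 <- rec
  rec2$mean_score <- 4 + 0.3 * rec2$julian_week + rnorm(20, 0, 0.5) +
    rep(c(-0.4, 0.4), each = 10)
  fl <- fit_phenology(rec2, "linear")
  fq <- fit_phenology(rec2, "quadratic")
  expect_gte(fq$loglik, fl$loglik - 1e-8)
  expect_error(fit_phenology(rec2[rec2$animal_id == "a", ], "linear"),
               "2 animals")
})

test_that("likelihood-ratio test behaves at its boundaries", {
  set.seed(52)
  rec <- data.frame(animal_id = rep(c("a", "b", "c"), each = 12),
                    year = 2017, julian_week = rep(16:27, 3),
                    mean_score = rnorm(36, 5, 1), n_fixes = 4)
  fq <- fit_phenology(rec, "quadratic")
  fl <- fit_phenology(rec, "linear")
  same <- lrt_phenology(fq, fq)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  out <- lrt_phenology(fq, fl)
  expect_equal(out$df, 1)
  expect_gte(out$statistic, 0)
  expect_error(lrt_phenology(fl, fq), "higher likelihood")
})

test_that("peak week inverts the centering and scaling", {
  fake <- structure(list(
    fixed = data.frame(term = c("(Intercept)", "wk", "wk2"),
                       estimate = c(5, 0, -1), se = 0.1),
    form = "quadratic", centering = list(mid = 23.5, scale = 4.6)),
    class = "phenology_fit")
  expect_equal(peak_week(fake), 23.5)     # b = 0 -> vertex at the midpoint
  fake$fixed$estimate <- c(5, 2, -1)      # vertex at +1 scaled week
  expect_equal(peak_week(fake), 23.5 + 4.6)
  fake$fixed$estimate <- c(5, 2, 1)       # convex: no interior maximum
  expect_error(peak_week(fake), "non-negative")
})

test_that("true quadratic phenology is recovered with a random intercept", {
  set.seed(53)
  wk <- 16:31
  mid <- mean(range(wk)); scl <- sd(wk)
  reps <- lapply(1:10, function(r) {
    rec <- expand.grid(animal_id = paste0("b", 1:8), julian_week = wk)
    rec$year <- 2017
    z <- (rec$julian_week - mid) / scl
    rec$mean_score <- 3 + 0.5 * z - 0.8 * z^2 +
      rnorm(8, 0, 0.5)[as.integer(factor(rec$animal_id))] +
      rnorm(nrow(rec), 0, 0.4)
    rec$n_fixes <- 6
    fit_phenology(rec, "quadratic")
  })
  est <- t(vapply(reps, function(f)
    f$fixed$estimate[match(c("(Intercept)", "wk", "wk2"), f$fixed$term)],
    numeric(3)))
  se <- t(vapply(reps, function(f)
    f$fixed$se[match(c("(Intercept)", "wk", "wk2"), f$fixed$term)],
    numeric(3)))
  truth <- c(3, 0.5, -0.8)
  for (j in 1:3)
    expect_lt(abs(mean(est[, j]) - truth[j]), 2 * mean(se[, j]))
  # and the implied peak week back-transforms correctly
  pw <- vapply(reps, peak_week, 0)
  expect_equal(mean(pw), mid + scl * (0.5 / (2 * 0.8)), tolerance = 0.05)
})
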