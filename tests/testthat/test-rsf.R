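test_that("post-partum used points respect the 7-day window and fix cadence", {
  ls <- test_landscape()
  sim <- simulate_prey(prey_config(start = "2017-05-01", n_days = 45), ls,
                       n_animals = 3, seed = 41)
  up <- postpartum_used_points(sim$fixes, sim$events, days = 7)
  # elk on 30-min fixes: at most 337 used points per event (7 d x 48 + 1)
  cnt <- table(up$animal_id)
  expect_true(all(cnt <= 337))
  for (i in seq_len(nrow(sim$events))) {
    ev <- sim$events[i, ]
    pts <- up[up$animal_id == ev$animal_id, ]
    expect_true(all(pts$t >= ev$birth_time &
                      pts$t <= ev$birth_time + 7 * 86400))
    # localization >= 6 of the 7 days: points hug the birth site
    d <- sqrt((pts$x - ev$birth_x)^2 + (pts$y - ev$birth_y)^2)
    expect_gte(mean(d <= 50), 6 / 7 * 0.95)
  }
  # an event at the trajectory end returns only the fixes that exist
  late_ev <- data.frame(animal_id = sim$events$animal_id[1],
                        event_time = max(sim$fixes$t) - 86400)
  up2 <- postpartum_used_points(sim$fixes, late_ev, days = 7)
  expect_lte(nrow(up2), 49)
})

test_that("availability draws are uniform over the polygon", {
  poly <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  av <- draw_available(poly, n_used = 1000, ratio = 10, seed = 42)
  expect_equal(nrow(av), 10000)
  expect_true(all(av$x >= 0 & av$x <= 1 & av$y >= 0 & av$y <= 1))
  # chi-square uniformity on a 4 x 4 grid
  cell <- cut(av$x, seq(0, 1, 0.25)) : cut(av$y, seq(0, 1, 0.25))
  expect_gt(chisq.test(table(cell))$p.value, 0.01)
  expect_identical(av, draw_available(poly, 1000, 10, seed = 42))
  expect_error(draw_available(cbind(c(0, 1), c(0, 1)), 10), "vertices")
  expect_error(draw_available(cbind(c(0, 1, 2), c(0, 1, 2)), 10), "area")
})

test_that("the RSF slope on a binary covariate equals the contingency log odds ratio", {
  # used: 30 of 40 in class 1; available: 200 of 400 -> slope log 3
  set.seed(40)
  n <- 40; m <- 400
  cl <- covariate_stack(list(canopy = cbind(matrix(0, 20, 10),
                                            matrix(1, 20, 10))),
                        cell_size = 30)
  xs_for <- function(cls, k) runif(k, if (cls) 301 else 1,
                                   if (cls) 599 else 299)
  used <- data.frame(x = c(xs_for(TRUE, 30), xs_for(FALSE, 10)),
                     y = runif(n, 1, 599))
  avail <- data.frame(x = c(xs_for(TRUE, 200), xs_for(FALSE, 200)),
                      y = runif(m, 1, 599))
  fit <- fit_rsf(used, avail, cl)
  i <- match("canopy", fit$coefficients$term)
  slope_raw <- fit$coefficients$estimate[i] *
    1 / fit$standardization$canopy$sd
  expect_equal(slope_raw, log(3), tolerance = 1e-6)
})

test_that("used points concentrated in high canopy give a positive canopy effect", {
  ls <- test_landscape(extent = 3000)
  sc <- rsf_recovery_scenario(7, n_used = 400,
                              beta_true = c(canopy = 1), landscape = ls)
  i <- match("canopy", sc$fit$coefficients$term)
  expect_gt(sc$fit$coefficients$estimate[i], 0)
  expect_gt(sc$fit$coefficients$estimate[i] / sc$fit$coefficients$se[i], 3)
})

test_that("no-signal fits stay quiet", {
  ls <- test_landscape(extent = 3000)
  set.seed(43)
  ext <- stack_extent(ls)
  pts <- function(k) data.frame(x = runif(k, ext[1], ext[2] - 1),
                                y = runif(k, ext[3], ext[4] - 1))
  fit <- fit_rsf(pts(200), pts(1800), ls)
  slopes <- fit$coefficients[-1, ]
  expect_true(all(abs(slopes$estimate / slopes$se) < 3))
})

test_that("predicted surfaces obey the exponential-model algebra", {
  ls <- test_landscape(extent = 3000)
  sc <- rsf_recovery_scenario(8, n_used = 500, landscape = ls)
  su <- predict_surface(sc$fit, ls)
  w <- su$stack$layers$rsf_score
  expect_true(all(w > 0))
  # log-linearity: doubling one covariate's coefficient squares its
  # multiplicative contribution at any cell
  fit2 <- sc$fit
  fit2$glm$coefficients["canopy"] <- 2 * fit2$glm$coefficients["canopy"]
  w2 <- predict_surface(fit2, ls)$stack$layers$rsf_score
  std <- sc$fit$standardization$canopy
  z <- (ls$layers$canopy - std$mean) / std$sd
  b <- unname(sc$fit$glm$coefficients["canopy"])
  expect_equal(w2 / w, exp(b * z), tolerance = 1e-8, ignore_attr = TRUE)
  # an all-zero coefficient vector predicts a flat surface of 1
  fit0 <- sc$fit
  fit0$glm$coefficients[] <- 0
  expect_true(all(predict_surface(fit0, ls)$stack$layers$rsf_score == 1))
})

test_that("the surface ranking is invariant to the availability ratio", {
  ls <- test_landscape(extent = 3000)
  sc <- rsf_recovery_scenario(9, n_used = 1000, landscape = ls)
  ext <- stack_extent(ls)
  poly <- cbind(x = ext[c(1, 2, 2, 1)], y = ext[c(3, 3, 4, 4)])
  # same used points; the ratio-5 availability is a subset of the ratio-10
  # draw, so the contrast isolates the ratio itself
  av10 <- draw_available(poly, nrow(sc$used), ratio = 10, seed = 44)
  av5 <- av10[seq_len(5 * nrow(sc$used)), ]
  fit10 <- fit_rsf(sc$used, av10, ls)
  fit5 <- fit_rsf(sc$used, av5, ls)
  s10 <- predict_surface(fit10, ls)$stack$layers$rsf_score
  s5 <- predict_surface(fit5, ls)$stack$layers$rsf_score
  expect_gte(cor(as.vector(s10), as.vector(s5), method = "spearman"), 0.99)
})
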