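test_that("mcp_area matches closed-form hull areas", {
  sq <- function(side) data.frame(x = c(0, side, side, 0),
                                  y = c(0, 0, side, side))
  expect_equal(mcp_area(sq(1000)), 100)           # 1e6 m2 = 100 ha
  expect_equal(mcp_area(sq(547.7)), 30.0, tolerance = 1e-3)
  expect_equal(mcp_area(data.frame(x = c(0, 10), y = c(0, 10))), 0)
  expect_equal(mcp_area(data.frame(x = c(0, 5, 10), y = c(0, 5, 10))), 0)
  expect_error(mcp_area(data.frame(x = numeric(), y = numeric())),
               "at least one")
  # interior points do not change the hull
  withpt <- rbind(sq(1000), data.frame(x = 500, y = 500))
  expect_equal(mcp_area(withpt), 100)
})

test_that("mcp_area is rigid-motion invariant and scales quadratically", {
  set.seed(4)
  pts <- data.frame(x = rnorm(40, 0, 300), y = rnorm(40, 0, 300))
  a0 <- mcp_area(pts)
  expect_equal(mcp_area(data.frame(x = pts$x + 5000, y = pts$y - 2000)), a0)
  th <- 0.7
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y,
                    y = sin(th) * pts$x + cos(th) * pts$y)
  expect_equal(mcp_area(rot), a0, tolerance = 1e-9)
  expect_equal(mcp_area(pts * 3), 9 * a0, tolerance = 1e-9)
})

test_that("rolling MCP series reflects stationary and patrolling movement", {
  stat <- make_fixes(cbind(rep(100, 200), rep(100, 200)), by_min = 60)
  ser <- rolling_mcp(stat)
  expect_true(all(ser$area_ha == 0))
  pat <- square_patrol(1000, hours = 72, by_min = 60)
  ser2 <- rolling_mcp(pat)
  full <- ser2$n_fixes >= 25  # windows seeing the full square
  expect_true(all(abs(ser2$area_ha[full] - 100) < 1e-9))
  expect_true(all(ser2$few_fixes == (ser2$n_fixes < 3)))
  short <- make_fixes(cbind(1:5, 1:5), by_min = 60)
  expect_error(rolling_mcp(short), "shorter")
})

test_that("detection thresholds and durations are inclusive", {
  # constant 31-ha windows at threshold 30 -> no event
  side31 <- sqrt(31 * 1e4)
  none <- detect_parturition(square_patrol(side31, hours = 24 * 9),
                             threshold_ha = 30)
  expect_null(none)
  # windows exactly AT the threshold qualify (inclusive "30 ha or less");
  # the threshold is set to the square's own area to pin the boundary
  traj30 <- square_patrol(547.72, hours = 24 * 9)
  area <- mcp_area(traj30[1:4, c("x", "y")])
  ev <- detect_parturition(traj30, threshold_ha = area)
  expect_equal(ev$event_time, traj30$t[1])
  # ... while any threshold strictly below the area detects nothing
  expect_null(detect_parturition(traj30, threshold_ha = area - 1e-9))
  # a run lasting exactly 120 h qualifies (inclusive duration)
  exact <- square_patrol(547.72, hours = 120)
  expect_false(is.null(detect_parturition(exact, threshold_ha = area)))
})

test_that("detection is monotone in the threshold", {
  ls <- test_landscape()
  sim <- simulate_prey(prey_config(start = "2017-05-01", n_days = 40),
                       ls, n_animals = 6, seed = 21)
  det15 <- detect_parturition_all(sim$fixes, threshold_ha = 15)
  det30 <- detect_parturition_all(sim$fixes, threshold_ha = 30)
  expect_true(all(det15$animal_id %in% det30$animal_id))
  # and the 30-ha events can only be earlier or simultaneous
  common <- intersect(det15$animal_id, det30$animal_id)
  t15 <- det15$event_time[match(common, det15$animal_id)]
  t30 <- det30$event_time[match(common, det30$animal_id)]
  expect_true(all(t30 <= t15))
})

test_that("synthetic births are detected close to their true times", {
  ls <- test_landscape(extent = 3000)
  # 60 days so even late-pulse births finish their 120-h localization run
  sim <- simulate_prey(prey_config(start = "2017-05-01", n_days = 60),
                       ls, n_animals = 5, seed = 31)
  det <- detect_parturition_all(sim$fixes, threshold_ha = 30)
  sc <- score_detections(det, sim$events, max_offset_h = 72)
  expect_equal(sc$sensitivity, 1)
  expect_lte(sc$mean_abs_dt_h, 24)
  # rolling series drops below 30 ha within one window of the true birth
  a1 <- sim$events$animal_id[1]
  tr <- sim$fixes[sim$fixes$animal_id == a1, ]
  ser <- rolling_mcp(tr)
  t_true <- sim$events$birth_time[1]
  first_low <- min(ser$t[ser$area_ha <= 30 & ser$t >= t_true])
  expect_lte(as.numeric(difftime(first_low, t_true, units = "hours")), 24)
})

test_that("score_detections arithmetic and degenerate cases", {
  t0 <- as.POSIXct("2017-05-27 00:00:00", tz = "UTC")
  truth <- data.frame(animal_id = c("a", "b", "c"), event_time = t0)
  # identical detections: sensitivity 1, mean offset 0
  perfect <- score_detections(truth, truth, max_offset_h = 24)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$mean_abs_dt_h, 0)
  # no detections: sensitivity 0
  none <- score_detections(truth[0, ], truth, max_offset_h = 24)
  expect_equal(none$sensitivity, 0)
  # offsets 6, 12, 24 h -> mean 14 h
  det <- data.frame(animal_id = c("a", "b", "c"),
                    event_time = t0 + c(6, 12, 24) * 3600)
  sc <- score_detections(det, truth, max_offset_h = 24)
  expect_equal(sc$mean_abs_dt_h, 14)
  expect_equal(sc$false_positives, 0)
  # a detection for an animal without a true birth is a false positive
  fp <- score_detections(rbind(det, data.frame(animal_id = "d",
                                               event_time = t0)),
                         truth, max_offset_h = 24)
  expect_equal(fp$false_positives, 1)
})
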