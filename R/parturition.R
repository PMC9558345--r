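# Parturition detection from localized movement: a birth is inferred the
# first time the area of a rolling 24-h minimum convex polygon stays at or
# below a species-specific threshold (30 ha for elk, 15 ha for mule deer) for
# at least 120 consecutive hours.

# fast hull area on bare coordinate vectors (chull tolerates duplicates and
# returns a degenerate hull, which the shoelace sum maps to 0)
hull_area_ha <- function(xs, ys) {
  h <- grDevices::chull(xs, ys)
  n <- length(h)
  if (n < 3) return(0)
  hx <- xs[h]; hy <- ys[h]
  j <- c(n, seq_len(n - 1))
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2 / 1e4
}

#' Area of the minimum convex polygon of a point set
#'
#' Convex hull area in hectares. Fewer than 3 distinct, non-collinear points
#' have zero area.
#'
#' @param points matrix or data.frame with columns `x` and `y` (meters).
#' @return area in hectares.
#' @export
mcp_area <- function(points) {
  pts <- as.data.frame(points)
  if (nrow(pts) == 0) stop("mcp_area needs at least one point")
  xy <- unique(cbind(pts$x, pts$y))
  if (nrow(xy) < 3) return(0)
  hull_area_ha(xy[, 1], xy[, 2])
}

#' Rolling 24-h MCP area series for one trajectory
#'
#' The window is trailing (past-looking) and anchored at each evaluation
#' time; evaluation happens at every fix time, giving sub-daily resolution.
#' Windows holding fewer than 3 fixes get area 0 and are flagged.
#'
#' @param traj fixes data.frame for one animal (strictly increasing `t`).
#' @param window_h window length in hours.
#' @return data.frame with `t` (evaluation time = window end), `window_start`,
#'   `n_fixes`, `area_ha`, `few_fixes` (TRUE when < 3 fixes in the window).
#' @export
rolling_mcp <- function(traj, window_h = 24) {
  stopifnot(nrow(traj) >= 2)
  if (length(unique(traj$animal_id)) != 1)
    stop("rolling_mcp expects a single animal")
  tt <- as.numeric(traj$t)
  span_h <- (tt[length(tt)] - tt[1]) / 3600
  if (span_h < window_h)
    stop("trajectory spans ", round(span_h, 1), " h; shorter than the ",
         window_h, "-h window")
  win_s <- window_h * 3600
  start_idx <- findInterval(tt - win_s, tt) + 1L  # first fix with t > t_i - win
  n <- length(tt)
  xs <- traj$x; ys <- traj$y
  area <- numeric(n); nfix <- integer(n)
  for (i in seq_len(n)) {
    s <- start_idx[i]
    nfix[i] <- i - s + 1L
    area[i] <- if (nfix[i] >= 3) hull_area_ha(xs[s:i], ys[s:i]) else 0
  }
  data.frame(t = traj$t, window_start = traj$t - win_s, n_fixes = nfix,
             area_ha = area, few_fixes = nfix < 3)
}

#' Detect a parturition event from sustained localized movement
#'
#' Scans the rolling-MCP series for the first maximal run of evaluation times
#' whose areas stay at or below `threshold_ha` continuously for at least
#' `min_duration_h`. The event is anchored at the start of that run (no
#' back-shift); the site is the centroid of the fixes in the first
#' `min_duration_h` hours of the run. Both the area threshold and the
#' duration are inclusive. Returns `NULL` when no qualifying run exists (the
#' animal is assumed not to have given birth).
#'
#' @param traj fixes data.frame for one animal.
#' @param threshold_ha MCP area threshold (30 for elk, 15 for mule deer).
#' @param min_duration_h minimum run duration in hours.
#' @param window_h rolling window length in hours.
#' @return one-row data.frame (`animal_id`, `event_time`, `x`, `y`, `method`,
#'   `threshold_ha`) or `NULL`.
#' @export
detect_parturition <- function(traj, threshold_ha = 30,
                               min_duration_h = 120, window_h = 24) {
  ser <- rolling_mcp(traj, window_h = window_h)
  ok <- ser$area_ha <= threshold_ha
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tt <- as.numeric(ser$t)
  for (k in which(r$values)) {
    dur_h <- (tt[ends[k]] - tt[starts[k]]) / 3600
    if (dur_h >= min_duration_h) {
      t0 <- ser$t[starts[k]]
      in_run <- traj$t >= t0 &
        traj$t <= t0 + min_duration_h * 3600
      data_run <- traj[in_run, , drop = FALSE]
      return(data.frame(animal_id = traj$animal_id[1], event_time = t0,
                        x = mean(data_run$x), y = mean(data_run$y),
                        method = "rolling_mcp", threshold_ha = threshold_ha,
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Detect parturition events for every animal in a fix table
#'
#' @param fixes fixes data.frame (possibly many animals).
#' @inheritParams detect_parturition
#' @return events data.frame (zero rows if nothing detected).
#' @export
detect_parturition_all <- function(fixes, threshold_ha = 30,
                                   min_duration_h = 120, window_h = 24) {
  out <- lapply(split(fixes, fixes$animal_id), function(tr)
    detect_parturition(tr, threshold_ha = threshold_ha,
                       min_duration_h = min_duration_h,
                       window_h = window_h))
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(animal_id = character(), event_time = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric(), method = character(),
                      threshold_ha = numeric())
  rownames(out) <- NULL
  out
}

#' Score detected parturition events against known births
#'
#' A detection matches the truth for its animal when the absolute timing
#' offset is at most `max_offset_h`; detections with no matching truth are
#' false positives.
#'
#' @param detected events data.frame (`animal_id`, `event_time`).
#' @param truth events data.frame with true `animal_id`, `event_time`
#'   (`birth_time` also accepted).
#' @param max_offset_h matching window in hours.
#' @return list: `sensitivity`, `n_true`, `n_detected`, `false_positives`,
#'   `mean_abs_dt_h` (over matched pairs), and the per-animal `table`.
#' @export
score_detections <- function(detected, truth, max_offset_h = 72) {
  tt <- truth$event_time %||% truth$birth_time
  truth_tab <- data.frame(animal_id = truth$animal_id, true_time = tt)
  det <- data.frame(animal_id = detected$animal_id,
                    det_time = detected$event_time)
  m <- merge(truth_tab, det, by = "animal_id", all = TRUE)
  dt_h <- abs(as.numeric(m$det_time) - as.numeric(m$true_time)) / 3600
  matched <- !is.na(dt_h) & dt_h <= max_offset_h
  fp <- !is.na(m$det_time) & (is.na(m$true_time) | (!is.na(dt_h) & dt_h > max_offset_h))
  list(sensitivity = if (nrow(truth_tab)) sum(matched) / nrow(truth_tab) else NA_real_,
       n_true = nrow(truth_tab), n_detected = sum(!is.na(m$det_time)),
       false_positives = sum(fp),
       mean_abs_dt_h = if (any(matched)) mean(dt_h[matched]) else NA_real_,
       table = data.frame(animal_id = m$animal_id, true_time = m$true_time,
                          det_time = m$det_time, abs_dt_h = dt_h,
                          matched = matched))
}
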