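# Parturition-habitat resource selection function: logistic regression of
# used (post-partum prey fixes, 7 days after the event) versus available
# (uniform draws over the area used by the prey population, 10 per used
# point) locations on standardized landscape covariates, followed by raster
# prediction of the exponential selection score w(x) = exp(beta' x), without
# the intercept, per 30-m cell.

#' Post-partum used points
#'
#' All fixes of each parturient female in the `days` days immediately
#' following her parturition event.
#'
#' @param prey_fixes prey fix table.
#' @param events events data.frame (`animal_id`, `event_time` or
#'   `birth_time`).
#' @param days length of the post-partum window (days).
#' @return data.frame of used points: `animal_id`, `t`, `x`, `y`.
#' @export
postpartum_used_points <- function(prey_fixes, events, days = 7) {
  if (is.null(events$event_time)) events$event_time <- events$birth_time
  out <- lapply(seq_len(nrow(events)), function(i) {
    tr <- prey_fixes[prey_fixes$animal_id == events$animal_id[i], ]
    ev <- events$event_time[i]
    tr <- tr[tr$t >= ev & tr$t <= ev + days * 86400, ]
    if (nrow(tr) == 0) return(NULL)
    tr[, c("animal_id", "t", "x", "y")]
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(animal_id = character(),
                      t = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric())
  rownames(out) <- NULL
  out
}

#' Convex-hull availability polygon of a fix table
#'
#' The "entire area used" by the prey population, taken as the minimum convex
#' polygon of all its fixes (a supplied polygon can be used instead in
#' [draw_available()]).
#'
#' @param fixes fix table.
#' @return two-column matrix of polygon vertices (not closed).
#' @export
availability_polygon <- function(fixes) {
  h <- grDevices::chull(fixes$x, fixes$y)
  cbind(x = fixes$x[h], y = fixes$y[h])
}

#' Draw available points uniformly inside a polygon
#'
#' Rejection sampling (with replacement at the cell level) in the polygon's
#' bounding box.
#'
#' @param polygon two-column vertex matrix.
#' @param n_used number of used points.
#' @param ratio available:used ratio (10 random locations per used location
#'   by default).
#' @param seed integer seed.
#' @return data.frame with `x`, `y` of `n_used * ratio` points.
#' @export
draw_available <- function(polygon, n_used, ratio = 10, seed = 1L) {
  poly <- as.matrix(polygon)
  if (nrow(poly) < 3) stop("availability polygon needs >= 3 vertices")
  if (abs(mcp_area(data.frame(x = poly[, 1], y = poly[, 2]))) <= 0)
    stop("availability polygon has zero area")
  set.seed(split_seed(seed, 0L))
  n <- n_used * ratio
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2 * (n - length(out_x)), 100)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    ok <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))
    out_x <- c(out_x, px[ok]); out_y <- c(out_y, py[ok])
  }
  data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Fit the parturition-habitat resource selection function
#'
#' Binomial GLM (logit link) of used (1) versus available (0) points on the
#' full standardized covariate set - canopy, ln(distance to road),
#' ln(distance to water), ruggedness, shrub, forb, slope, aspect, elevation,
#' vegetation class - with no model selection (global model). Aspect is
#' circular; by default it enters as sin + cos components, with
#' `aspect_mode = "degrees"` reproducing a raw-degrees coding.
#'
#' @param used data.frame of used points (`x`, `y`).
#' @param available data.frame of available points (`x`, `y`).
#' @param landscape a `covariate_stack`.
#' @param aspect_mode `"sincos"` (default) or `"degrees"`.
#' @return an `rsf_fit`: `glm` (the fitted model), `coefficients` table,
#'   `standardization`, `aspect_mode`, `ratio`, `converged`, `n_used`,
#'   `n_available`, `n_oob` (points dropped off-raster).
#' @export
fit_rsf <- function(used, available, landscape,
                    aspect_mode = c("sincos", "degrees")) {
  aspect_mode <- match.arg(aspect_mode)
  stopifnot(nrow(used) > 0, nrow(available) > 0)
  pts <- rbind(data.frame(x = used$x, y = used$y, y_used = 1),
               data.frame(x = available$x, y = available$y, y_used = 0))
  cv <- design_covariates(pts[, c("x", "y")], landscape,
                          aspect_mode = if (aspect_mode == "sincos")
                            "sincos" else "degrees")
  oob <- attr(cv, "oob")
  dat <- cbind(y_used = pts$y_used, cv)[!oob, , drop = FALSE]
  std <- standardize_design(dat[, setdiff(names(dat),
                                          c("y_used", "veg_class")),
                                drop = FALSE])
  dat[, names(std$data)] <- std$data
  fit <- stats::glm(y_used ~ ., family = stats::binomial(),
                    data = dat)
  sm <- summary(fit)
  separated <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  structure(list(
    glm = fit,
    coefficients = data.frame(term = rownames(sm$coefficients),
                              estimate = sm$coefficients[, 1],
                              se = sm$coefficients[, 2],
                              z = sm$coefficients[, 3],
                              p = sm$coefficients[, 4], row.names = NULL),
    standardization = std$constants, skipped = std$skipped,
    aspect_mode = aspect_mode,
    ratio = sum(dat$y_used == 0) / sum(dat$y_used == 1),
    converged = fit$converged && !separated,
    n_used = sum(dat$y_used == 1), n_available = sum(dat$y_used == 0),
    n_oob = sum(oob)),
    class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %d used vs %d available (1:%.1f), %s\n",
              x$n_used, x$n_available, x$ratio,
              if (x$converged) "converged" else "NOT converged"))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict the selection surface w(x) over the landscape
#'
#' Per-cell exponential RSF score w(x) = exp(beta' x_std) over the
#' standardized covariates, excluding the intercept (standard exponential
#' form; the intercept only absorbs the availability ratio). Uses the fit's
#' own standardization constants.
#'
#' @param fit an `rsf_fit`.
#' @param landscape the `covariate_stack` to project onto.
#' @return a `selection_surface`: list with `stack` (single-layer
#'   `covariate_stack` named `rsf_score`) and provenance fields.
#' @export
predict_surface <- function(fit, landscape) {
  stopifnot(inherits(fit, "rsf_fit"))
  if (is.null(fit$standardization))
    stop("fit carries no standardization constants")
  cc <- cell_centers(landscape)
  pts <- data.frame(x = rep(cc$x, each = landscape$nrow),
                    y = rep(cc$y, times = landscape$ncol))
  cv <- design_covariates(pts, landscape,
                          aspect_mode = if (fit$aspect_mode == "sincos")
                            "sincos" else "degrees")
  num <- setdiff(names(cv), "veg_class")
  cv[, num] <- standardize_design(cv[, num, drop = FALSE],
                                  constants = fit$standardization)$data
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$glm)),
                            data = cv)
  beta <- stats::coef(fit$glm)
  lp <- drop(mm[, names(beta)[-1], drop = FALSE] %*% beta[-1])
  w <- matrix(exp(lp), nrow = landscape$nrow, ncol = landscape$ncol)
  structure(list(
    stack = covariate_stack(list(rsf_score = w),
                            cell_size = landscape$cell_size,
                            xmin = landscape$xmin, ymin = landscape$ymin),
    fit_terms = names(beta)[-1], aspect_mode = fit$aspect_mode),
    class = "selection_surface")
}

#' Sample a selection surface at points
#' @param surface a `selection_surface`.
#' @param points data.frame with `x`, `y`.
#' @return numeric vector of scores (NA off-raster).
#' @export
surface_at <- function(surface, points) {
  sample_covariates(points, surface$stack)$rsf_score
}
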