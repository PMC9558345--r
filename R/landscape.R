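# Synthetic landscape generator: Gaussian-random-field covariate layers, a
# categorical vegetation map, and true Euclidean distance-to-feature layers
# for roads and perennial water. The layer set is the union of the covariates
# entering the step-selection and parturition-habitat selection models:
# canopy, vegetation class, ruggedness, distance to road, distance to water,
# shrub, forb, slope, aspect, elevation.

VEG_CLASSES <- c("open_forest", "closed_forest", "grassland", "other")

#' Configuration for a synthetic landscape
#'
#' @param extent numeric length-2, landscape size in meters (x, y).
#' @param cell_size cell edge in meters (30-m pixels by default).
#' @param layers named list of continuous-layer settings; each element is a
#'   list with `mean`, `sd`, `lengthscale` (meters; 0 gives spatially white
#'   noise) and optional `min`/`max` clamps. Defaults cover the full
#'   covariate set.
#' @param veg_props named proportions of the four vegetation classes
#'   (must sum to 1).
#' @param veg_lengthscale smoothing scale of the vegetation field (m).
#' @param n_roads,n_water number of random linear road / stream features.
#' @param road_features,water_features optional explicit features: a list of
#'   n x 2 coordinate matrices (a 1 x 2 matrix is a point feature); overrides
#'   the random features.
#' @param seed integer seed; the same config yields bit-identical landscapes.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent = c(6000, 6000), cell_size = 30,
                             layers = NULL,
                             veg_props = c(open_forest = 0.3,
                                           closed_forest = 0.4,
                                           grassland = 0.2, other = 0.1),
                             veg_lengthscale = 400,
                             n_roads = 3, n_water = 2,
                             road_features = NULL, water_features = NULL,
                             seed = 1L) {
  if (any(extent <= 0)) stop("extent must be positive")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (abs(sum(veg_props) - 1) > 1e-8)
    stop("vegetation class proportions must sum to 1")
  if (!identical(sort(names(veg_props)), sort(VEG_CLASSES)))
    stop("veg_props must name the classes: ",
         paste(VEG_CLASSES, collapse = ", "))
  defaults <- list(
    canopy     = list(mean = 45,   sd = 20,   lengthscale = 300, min = 0, max = 100),
    ruggedness = list(mean = 0.25, sd = 0.15, lengthscale = 200, min = 0, max = 1),
    shrub      = list(mean = 20,   sd = 10,   lengthscale = 250, min = 0, max = 100),
    forb       = list(mean = 15,   sd = 8,    lengthscale = 250, min = 0, max = 100),
    slope      = list(mean = 12,   sd = 8,    lengthscale = 400, min = 0, max = 60),
    elevation  = list(mean = 1400, sd = 120,  lengthscale = 900))
  if (!is.null(layers)) {
    for (nm in names(layers)) defaults[[nm]] <-
        utils::modifyList(defaults[[nm]] %||% list(), layers[[nm]])
  }
  structure(list(extent = extent, cell_size = cell_size, layers = defaults,
                 veg_props = veg_props[VEG_CLASSES],
                 veg_lengthscale = veg_lengthscale,
                 n_roads = n_roads, n_water = n_water,
                 road_features = road_features,
                 water_features = water_features, seed = seed),
            class = "landscape_config")
}

# Gaussian random field on the grid torus: white noise convolved with a
# Gaussian kernel by FFT, rescaled to zero mean / unit sd.
gaussian_field <- function(nr, nc, lengthscale_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (lengthscale_cells <= 0) return(z)
  ri <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  ci <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  k <- exp(-(outer(ri^2, rep(1, nc)) + outer(rep(1, nr), ci^2)) /
             (2 * lengthscale_cells^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

# min Euclidean distance from points to a set of polyline/point features
feature_distance <- function(px, py, features) {
  d <- rep(Inf, length(px))
  for (f in features) {
    f <- as.matrix(f)
    if (nrow(f) == 1) {
      d <- pmin(d, sqrt((px - f[1, 1])^2 + (py - f[1, 2])^2))
      next
    }
    for (i in seq_len(nrow(f) - 1)) {
      x1 <- f[i, 1]; y1 <- f[i, 2]; x2 <- f[i + 1, 1]; y2 <- f[i + 1, 2]
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx^2 + dy^2
      tt <- if (L2 == 0) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
      d <- pmin(d, sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2))
    }
  }
  d
}

# random chord across the extent (used for synthetic roads/streams)
random_chord <- function(extent) {
  sides <- sample(1:4, 2)
  while (sides[1] == sides[2]) sides <- sample(1:4, 2)
  pt <- function(s) switch(s,
    c(stats::runif(1, 0, extent[1]), 0),
    c(stats::runif(1, 0, extent[1]), extent[2]),
    c(0, stats::runif(1, 0, extent[2])),
    c(extent[1], stats::runif(1, 0, extent[2])))
  rbind(pt(sides[1]), pt(sides[2]))
}

#' Generate a synthetic covariate raster stack
#'
#' @param config a [landscape_config()].
#' @return a `covariate_stack` with layers canopy, veg_class (categorical:
#'   open_forest, closed_forest, grassland, other), ruggedness, dist_road,
#'   dist_water, shrub, forb, slope, aspect (degrees), elevation.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  cs <- config$cell_size
  nc <- as.integer(ceiling(config$extent[1] / cs))
  nr <- as.integer(ceiling(config$extent[2] / cs))
  layers <- list()
  for (nm in names(config$layers)) {
    sp <- config$layers[[nm]]
    f <- gaussian_field(nr, nc, sp$lengthscale / cs) * sp$sd + sp$mean
    if (!is.null(sp$min)) f <- pmax(f, sp$min)
    if (!is.null(sp$max)) f <- pmin(f, sp$max)
    layers[[nm]] <- f
  }
  # aspect: direction of the gradient of two smooth fields -> uniform circular
  a1 <- gaussian_field(nr, nc, 400 / cs)
  a2 <- gaussian_field(nr, nc, 400 / cs)
  layers$aspect <- (atan2(a2, a1) / pi * 180) %% 360
  # vegetation classes from quantile slices of a smooth field
  vf <- gaussian_field(nr, nc, config$veg_lengthscale / cs)
  br <- stats::quantile(vf, cumsum(config$veg_props)[-length(config$veg_props)])
  veg <- matrix(findInterval(vf, br) + 1L, nr, nc)
  layers$veg_class <- veg
  # linear features and true Euclidean distance layers
  roads <- config$road_features %||%
    lapply(seq_len(config$n_roads), function(i) random_chord(config$extent))
  water <- config$water_features %||%
    lapply(seq_len(config$n_water), function(i) random_chord(config$extent))
  cc <- list(x = (seq_len(nc) - 0.5) * cs, y = (nr - seq_len(nr) + 0.5) * cs)
  px <- rep(cc$x, each = nr); py <- rep(cc$y, times = nc)
  layers$dist_road <- matrix(feature_distance(px, py, roads), nr, nc)
  layers$dist_water <- matrix(feature_distance(px, py, water), nr, nc)
  st <- covariate_stack(layers, cell_size = cs, xmin = 0, ymin = 0,
                        categorical = "veg_class",
                        levels = list(veg_class = VEG_CLASSES))
  attr(st, "features") <- list(roads = roads, water = water)
  st
}

# Landscape-wide standardization constants for the continuous layers (used by
# the generative predator sampler so true coefficients act on z-scores).
# Distance layers are keyed by their log-transformed design names.
landscape_standardization <- function(stack) {
  out <- list()
  for (nm in setdiff(names(stack$layers), stack$categorical)) {
    v <- stack$layers[[nm]]
    key <- nm
    if (nm %in% c("dist_road", "dist_water")) {
      v <- log1p(v)
      key <- sub("dist", "ln_dist", nm)
    }
    out[[key]] <- list(mean = mean(v), sd = stats::sd(v))
  }
  out
}
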