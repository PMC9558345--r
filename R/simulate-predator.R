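# Synthetic predator trajectories with known selection coefficients.
#
# Each step is chosen among M candidate endpoints drawn from the configured
# Gamma / von Mises movement kernels, with selection probability proportional
# to exp(beta_land' z + beta_enc * enc [+ w(t) * attraction]), where z are
# landscape covariates standardized over the whole landscape, enc is the
# 200-m parturient-prey encounter indicator evaluated exactly as the SSF
# module defines it, and the optional attraction term lets predator use of a
# parturition-habitat surface vary over the season (the generative "searching
# predator"). M is the generative candidate count and is deliberately larger
# than the analysis K = 20 to reduce sampler bias.

#' Configuration of synthetic predator behavior
#'
#' Defaults emulate a GPS-collared carnivore on a 3-h fix schedule.
#'
#' @param species,sex labels written into the fix table.
#' @param fix_interval_min GPS fix interval (minutes).
#' @param gamma_shape,gamma_scale step-length Gamma kernel (m).
#' @param vm_mu,vm_kappa turning-angle von Mises kernel.
#' @param beta_land named numeric vector of true selection coefficients on
#'   landscape-standardized covariates (`canopy`, `ruggedness`,
#'   `ln_dist_road`, `ln_dist_water`, `shrub`, `forb`, `slope`, `elevation`,
#'   or vegetation dummies `veg_closed_forest`, `veg_grassland`,
#'   `veg_other`). NULL = indifferent to the landscape.
#' @param beta_enc true coefficient on the parturient-prey encounter
#'   indicator.
#' @param radius_m,window_d,tolerance_min encounter definition passed to
#'   [encounter_indicator()].
#' @param n_candidates M, the generative candidate-set size.
#' @param attraction optional list(`surface` = selection surface (a
#'   `selection_surface`, a `covariate_stack` with one layer, or a bare
#'   matrix), `weight` = function(POSIXct) -> numeric) adding a time-varying
#'   coefficient on the standardized log surface.
#' @param home_range_sd optional home-range attachment (m): candidate
#'   weights carry a Gaussian utilization penalty around each animal's
#'   starting location, so predators range within a stable home range and
#'   mix through it on a sub-weekly timescale (as resident carnivores do)
#'   instead of drifting across the landscape. NULL disables attachment.
#' @param jitter_max_min per-animal start-time jitter (minutes), so predator
#'   fix times rarely coincide exactly with prey fix times.
#' @param start simulation start (UTC); `n_days` duration.
#' @param n_days simulated days.
#' @param record_choice record the index of the chosen candidate at each step
#'   (diagnostics for sampler uniformity checks).
#' @return a `predator_config` list.
#' @export
predator_config <- function(species = "cougar", sex = "M",
                            fix_interval_min = 180,
                            gamma_shape = 1.5, gamma_scale = 400,
                            vm_mu = 0, vm_kappa = 0.3,
                            beta_land = NULL, beta_enc = 0,
                            radius_m = 200, window_d = 30,
                            tolerance_min = 15,
                            n_candidates = 50, attraction = NULL,
                            home_range_sd = NULL, jitter_max_min = 10,
                            start = "2017-04-15", n_days = 107,
                            record_choice = FALSE) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, vm_kappa >= 0,
            n_candidates >= 2, fix_interval_min > 0, n_days > 0)
  if (!is.null(beta_land) && any(!is.finite(beta_land)))
    stop("beta_land must be finite")
  if (!is.finite(beta_enc)) stop("beta_enc must be finite")
  structure(list(species = species, sex = sex,
                 fix_interval_min = fix_interval_min,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 vm_mu = vm_mu, vm_kappa = vm_kappa,
                 beta_land = beta_land, beta_enc = beta_enc,
                 radius_m = radius_m, window_d = window_d,
                 tolerance_min = tolerance_min,
                 n_candidates = n_candidates, attraction = attraction,
                 home_range_sd = home_range_sd,
                 jitter_max_min = jitter_max_min,
                 start = as.POSIXct(start, tz = "UTC"), n_days = n_days,
                 record_choice = record_choice),
            class = "predator_config")
}

# standardized covariate matrices for the generative linear predictor
build_z_layers <- function(landscape, beta_land) {
  if (is.null(beta_land) || length(beta_land) == 0) return(list())
  std <- landscape_standardization(landscape)
  z <- list()
  for (nm in names(beta_land)) {
    if (startsWith(nm, "veg_")) {
      cl <- sub("^veg_", "", nm)
      lev <- landscape$levels$veg_class
      z[[nm]] <- (landscape$layers$veg_class == match(cl, lev)) * 1
    } else {
      raw <- switch(nm,
                    ln_dist_road = log1p(landscape$layers$dist_road),
                    ln_dist_water = log1p(landscape$layers$dist_water),
                    landscape$layers[[nm]])
      if (is.null(raw)) stop("unknown beta_land covariate: ", nm)
      z[[nm]] <- (raw - std[[nm]]$mean) / std[[nm]]$sd
    }
  }
  z
}

# extract a bare score matrix from whatever carries the attraction surface
attraction_matrix <- function(surface) {
  if (is.matrix(surface)) return(surface)
  if (inherits(surface, "selection_surface")) return(surface$stack$layers[[1]])
  if (inherits(surface, "covariate_stack")) return(surface$layers[[1]])
  stop("unsupported attraction surface type")
}

#' Simulate predator trajectories with known selection coefficients
#'
#' @param config a [predator_config()].
#' @param landscape a `covariate_stack`.
#' @param prey optional list(`fixes`, `events`) of parturient prey (required
#'   when `beta_enc` is nonzero).
#' @param n_animals number of predators.
#' @param seed integer seed (deterministic trajectories).
#' @return canonical fix table; when `config$record_choice` is TRUE it
#'   carries an attribute `chosen_index` (steps x animals matrix of the
#'   selected candidate's index among the M draws).
#' @export
simulate_predator <- function(config, landscape, prey = NULL, n_animals,
                              seed = 1L) {
  stopifnot(inherits(config, "predator_config"), n_animals >= 1)
  ps <- as_parturient_set(prey)
  if (config$beta_enc != 0 &&
      (is.null(ps) || is.null(ps$events) || nrow(ps$events) == 0))
    stop("beta_enc is nonzero but no parturient prey were supplied")
  ext <- stack_extent(landscape)
  margin <- 300
  M <- config$n_candidates
  dt_s <- config$fix_interval_min * 60
  n_steps <- as.integer(floor(config$n_days * 86400 / dt_s))
  set.seed(split_seed(seed, 0L))
  jit <- round(stats::runif(n_animals, 0, config$jitter_max_min * 60))
  t0 <- as.numeric(config$start) + jit
  # per-animal, per-step parturient prey positions, precomputed
  n_prey <- if (!is.null(ps$events)) nrow(ps$events) else 0L
  PX <- PY <- array(NA_real_, c(n_steps + 1L, max(n_prey, 1L), n_animals))
  tol <- as.difftime(config$tolerance_min, units = "mins")
  if (n_prey > 0 && config$beta_enc != 0) {
    prey_split <- split(ps$fixes, ps$fixes$animal_id)
    for (a in seq_len(n_animals)) {
      ta <- as.POSIXct(t0[a] + (0:n_steps) * dt_s, origin = "1970-01-01",
                       tz = "UTC")
      for (p in seq_len(n_prey)) {
        tr <- prey_split[[ps$events$animal_id[p]]]
        if (is.null(tr)) next
        ev <- as.numeric(ps$events$event_time[p])
        ok <- as.numeric(ta) >= ev &
          as.numeric(ta) <= ev + config$window_d * 86400
        if (!any(ok)) next
        mc <- match_contemporaneous(ta[ok], tr, tol)
        PX[ok, p, a] <- mc$x
        PY[ok, p, a] <- mc$y
      }
    }
  }
  zl <- build_z_layers(landscape, config$beta_land)
  att <- NULL
  if (!is.null(config$attraction)) {
    A <- log(attraction_matrix(config$attraction$surface))
    A <- (A - mean(A[is.finite(A)])) / stats::sd(A[is.finite(A)])
    A[!is.finite(A)] <- 0
    att <- list(z = A, weight = config$attraction$weight)
  }
  x <- stats::runif(n_animals, ext[1] + 0.25 * (ext[2] - ext[1]),
                    ext[1] + 0.75 * (ext[2] - ext[1]))
  y <- stats::runif(n_animals, ext[3] + 0.25 * (ext[4] - ext[3]),
                    ext[3] + 0.75 * (ext[4] - ext[3]))
  bearing <- stats::runif(n_animals, -pi, pi)
  hx <- x; hy <- y   # home-range centers = starting locations
  X <- matrix(NA_real_, n_steps + 1L, n_animals)
  Y <- matrix(NA_real_, n_steps + 1L, n_animals)
  X[1, ] <- x; Y[1, ] <- y
  chosen <- if (config$record_choice)
    matrix(NA_integer_, n_steps, n_animals) else NULL
  anim <- rep(seq_len(n_animals), each = M)
  r2 <- config$radius_m^2
  for (i in seq_len(n_steps)) {
    len <- stats::rgamma(n_animals * M, shape = config$gamma_shape,
                         scale = config$gamma_scale)
    turn <- rvonmises(n_animals * M, config$vm_mu, config$vm_kappa)
    heading <- bearing[anim] + turn
    cx <- fold_coord(x[anim] + len * cos(heading), ext[1] + margin,
                     ext[2] - margin)
    cy <- fold_coord(y[anim] + len * sin(heading), ext[3] + margin,
                     ext[4] - margin)
    rc <- cell_rowcol(landscape, cx, cy)
    idx <- (rc[, 2] - 1L) * landscape$nrow + rc[, 1]
    lp <- numeric(n_animals * M)
    for (nm in names(zl)) lp <- lp + config$beta_land[[nm]] * zl[[nm]][idx]
    if (config$beta_enc != 0 && n_prey > 0) {
      enc <- rep(0L, n_animals * M)
      for (p in seq_len(n_prey)) {
        pxv <- PX[i + 1L, p, anim]; pyv <- PY[i + 1L, p, anim]
        hit <- !is.na(pxv) & ((cx - pxv)^2 + (cy - pyv)^2 <= r2)
        enc[hit] <- 1L
      }
      lp <- lp + config$beta_enc * enc
    }
    if (!is.null(config$home_range_sd)) {
      lp <- lp - 0.5 * ((cx - hx[anim])^2 + (cy - hy[anim])^2) /
        config$home_range_sd^2
    }
    if (!is.null(att)) {
      ta <- t0 + i * dt_s   # per-animal numeric times at the step end
      wts <- att$weight(as.POSIXct(ta, origin = "1970-01-01", tz = "UTC"))
      lp <- lp + wts[anim] * att$z[idx]
    }
    # Gumbel-max draw of one candidate per animal
    g <- -log(-log(stats::runif(n_animals * M)))
    pick <- max.col(matrix(lp + g, nrow = n_animals, byrow = TRUE))
    sel <- (seq_len(n_animals) - 1L) * M + pick
    new_x <- cx[sel]; new_y <- cy[sel]
    moved <- (new_x != x) | (new_y != y)
    bearing[moved] <- atan2(new_y - y, new_x - x)[moved]
    x <- new_x; y <- new_y
    X[i + 1L, ] <- x; Y[i + 1L, ] <- y
    if (!is.null(chosen)) chosen[i, ] <- pick
  }
  fixes <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    data.frame(animal_id = sprintf("%s_%s_%02d", config$species, config$sex, a),
               species = config$species, sex = config$sex,
               t = as.POSIXct(t0[a] + (0:n_steps) * dt_s,
                              origin = "1970-01-01", tz = "UTC"),
               x = X[, a], y = Y[, a], stringsAsFactors = FALSE)
  }))
  fixes <- validate_fixes(fixes)
  if (!is.null(chosen)) attr(fixes, "chosen_index") <- chosen
  fixes
}
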