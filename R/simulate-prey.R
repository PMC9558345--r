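# Synthetic prey (elk / mule deer) trajectories with a birth pulse.
#
# Pre-partum movement is a correlated random walk (Gamma step lengths, von
# Mises turning angles). At a birth time drawn from the seasonal pulse the
# animal localizes: for `localization_duration_h` hours every fix falls
# within `localization_radius_m` of the birth site (the signal the rolling
# MCP detector targets). Afterwards the usable range re-expands linearly
# until normal ranging resumes.

#' Configuration of synthetic prey behavior
#'
#' Defaults emulate GPS-collared elk: fixes every 30 min, a late-May birth
#' pulse (mean day-of-year 147 = 27 May, sd 7 d), and at least 120 h of
#' post-partum localization. For mule deer use `species = "mule_deer"`,
#' `fix_interval_min = 75` (60-90 min schedule).
#'
#' @param species `"elk"` or `"mule_deer"`.
#' @param fix_interval_min GPS fix interval (minutes).
#' @param gamma_shape,gamma_scale pre-partum step-length Gamma (meters per
#'   step).
#' @param vm_mu,vm_kappa pre-partum turning-angle von Mises.
#' @param birth_doy_mean,birth_doy_sd birth pulse: mean and sd of the birth
#'   day-of-year.
#' @param p_parturient probability an animal gives birth at all.
#' @param localization_radius_m radius of the post-partum localization disc.
#' @param localization_duration_h localization duration; >= 120 h for a
#'   detectable event.
#' @param range_expansion_m_per_day growth rate of the usable radius after
#'   localization ends, until pre-partum ranging resumes.
#' @param birth_site_beta optional named coefficients on standardized
#'   landscape layers used to prefer birth sites among nearby candidates
#'   (NULL = give birth at the current location).
#' @param start simulation start (ISO date or POSIXct, UTC).
#' @param n_days simulated duration in days.
#' @return a `prey_config` list.
#' @export
prey_config <- function(species = "elk", fix_interval_min = 30,
                        gamma_shape = 1.2, gamma_scale = 150,
                        vm_mu = 0, vm_kappa = 0.5,
                        birth_doy_mean = 147, birth_doy_sd = 7,
                        p_parturient = 1,
                        localization_radius_m = 50,
                        localization_duration_h = 144,
                        range_expansion_m_per_day = 50,
                        birth_site_beta = NULL,
                        start = "2017-04-15", n_days = 107) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, vm_kappa >= 0,
            localization_radius_m > 0, localization_duration_h > 0,
            fix_interval_min > 0, n_days > 0, birth_doy_sd >= 0)
  structure(list(species = species, fix_interval_min = fix_interval_min,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 vm_mu = vm_mu, vm_kappa = vm_kappa,
                 birth_doy_mean = birth_doy_mean, birth_doy_sd = birth_doy_sd,
                 p_parturient = p_parturient,
                 localization_radius_m = localization_radius_m,
                 localization_duration_h = localization_duration_h,
                 range_expansion_m_per_day = range_expansion_m_per_day,
                 birth_site_beta = birth_site_beta,
                 start = as.POSIXct(start, tz = "UTC"), n_days = n_days),
            class = "prey_config")
}

# uniform draw inside a disc
runif_disc <- function(n, cx, cy, r) {
  a <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(x = cx + rr * cos(a), y = cy + rr * sin(a))
}

#' Simulate prey trajectories with known parturition events
#'
#' @param config a [prey_config()].
#' @param landscape a `covariate_stack` (defines the arena; positions are
#'   folded back inside a 300-m interior margin).
#' @param n_animals number of animals (>= 1).
#' @param seed integer seed; one child stream per animal.
#' @return list with `fixes` (canonical fix table) and `events`
#'   (`animal_id`, `birth_time`, `birth_x`, `birth_y`; one row per parturient
#'   animal).
#' @export
simulate_prey <- function(config, landscape, n_animals, seed = 1L) {
  stopifnot(inherits(config, "prey_config"), n_animals >= 1)
  ext <- stack_extent(landscape)
  margin <- 300
  if (2 * config$localization_radius_m > min(ext[2] - ext[1], ext[4] - ext[3]))
    stop("localization radius larger than the landscape extent")
  dt_s <- config$fix_interval_min * 60
  times <- config$start + seq(0, config$n_days * 86400, by = dt_s)
  n_t <- length(times)
  year0 <- as.POSIXct(paste0(format(config$start, "%Y", tz = "UTC"), "-01-01"),
                      tz = "UTC")
  all_fixes <- vector("list", n_animals)
  events <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    set.seed(split_seed(seed, a))
    id <- sprintf("%s_%02d", config$species, a)
    # pre-partum correlated random walk over the full window
    x0 <- stats::runif(1, ext[1] + 0.25 * (ext[2] - ext[1]),
                       ext[1] + 0.75 * (ext[2] - ext[1]))
    y0 <- stats::runif(1, ext[3] + 0.25 * (ext[4] - ext[3]),
                       ext[3] + 0.75 * (ext[4] - ext[3]))
    steps <- stats::rgamma(n_t - 1, shape = config$gamma_shape,
                           scale = config$gamma_scale)
    turns <- rvonmises(n_t - 1, config$vm_mu, config$vm_kappa)
    bearing <- stats::runif(1, -pi, pi) + cumsum(turns)
    x <- fold_coord(x0 + c(0, cumsum(steps * cos(bearing))),
                    ext[1] + margin, ext[2] - margin)
    y <- fold_coord(y0 + c(0, cumsum(steps * sin(bearing))),
                    ext[3] + margin, ext[4] - margin)
    # birth pulse
    gives_birth <- stats::runif(1) < config$p_parturient
    if (gives_birth) {
      doy <- stats::rnorm(1, config$birth_doy_mean, config$birth_doy_sd)
      birth_time <- year0 + (doy - 1) * 86400
      bi <- which.min(abs(as.numeric(times) - as.numeric(birth_time)))
      birth_time <- times[bi]
      site <- pick_birth_site(x[bi], y[bi], landscape, config$birth_site_beta)
      loc_end <- as.numeric(birth_time) + config$localization_duration_h * 3600
      phase_loc <- as.numeric(times) >= as.numeric(birth_time) &
        as.numeric(times) <= loc_end
      nl <- sum(phase_loc)
      if (nl > 0) {
        p <- runif_disc(nl, site[1], site[2], config$localization_radius_m)
        x[phase_loc] <- p[, 1]; y[phase_loc] <- p[, 2]
      }
      # post-localization: range expands linearly around the site until the
      # usable radius catches up with pre-partum ranging (free simulator
      # choice; the source analyses make no assumption about this phase)
      post <- which(as.numeric(times) > loc_end)
      if (length(post)) {
        days_since <- (as.numeric(times[post]) - loc_end) / 86400
        r_t <- config$localization_radius_m +
          config$range_expansion_m_per_day * days_since
        full <- stats::quantile(steps, 0.99) * 24  # cap: resume normal ranging
        expand <- r_t < full
        if (any(expand)) {
          idx <- post[expand]
          a2 <- stats::runif(length(idx), 0, 2 * pi)
          rr <- r_t[expand] * sqrt(stats::runif(length(idx)))
          x[idx] <- fold_coord(site[1] + rr * cos(a2), ext[1] + margin,
                               ext[2] - margin)
          y[idx] <- fold_coord(site[2] + rr * sin(a2), ext[3] + margin,
                               ext[4] - margin)
        }
      }
      events[[a]] <- data.frame(animal_id = id, birth_time = birth_time,
                                birth_x = site[1], birth_y = site[2],
                                stringsAsFactors = FALSE)
    }
    all_fixes[[a]] <- data.frame(animal_id = id, species = config$species,
                                 sex = "F", t = times, x = x, y = y,
                                 stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(animal_id = character(),
                     birth_time = as.POSIXct(character(), tz = "UTC"),
                     birth_x = numeric(), birth_y = numeric())
  rownames(ev) <- NULL
  list(fixes = validate_fixes(do.call(rbind, all_fixes)), events = ev)
}

# choose a birth site near the current position, optionally preferring
# habitat via exp(beta' z) weights over candidate cells within 300 m
pick_birth_site <- function(x, y, landscape, beta) {
  if (is.null(beta)) return(c(x, y))
  cand <- runif_disc(60, x, y, 300)
  cv <- design_covariates(data.frame(x = cand[, 1], y = cand[, 2]), landscape)
  keep <- !attr(cv, "oob")
  cand <- cand[keep, , drop = FALSE]; cv <- cv[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(c(x, y))
  cv <- standardize_design(cv, constants = landscape_standardization(landscape))$data
  lp <- rep(0, nrow(cand))
  for (nm in intersect(names(beta), names(cv))) {
    lp <- lp + beta[[nm]] * cv[[nm]]
  }
  i <- sample.int(nrow(cand), 1, prob = exp(lp - max(lp)))
  c(cand[i, 1], cand[i, 2])
}
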