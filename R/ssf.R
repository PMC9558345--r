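# Step-selection functions with a contemporaneous predator-prey encounter
# covariate. Each observed predator step is matched with K random steps drawn
# from the predator's fitted step-length (Gamma) and turning-angle (von Mises)
# kernels; endpoint covariates are contrasted by conditional logistic
# regression, maximizing
#     sum_strata [ beta' x_obs - log sum_j exp(beta' x_j) ]
# by Newton iteration with step-halving. The coefficient of interest is the
# binary indicator that a step endpoint lies within 200 m of a GPS-collared
# parturient female in the 30 days after her parturition event.

SSF_CONTINUOUS <- c("canopy", "ruggedness", "ln_dist_road", "ln_dist_water",
                    "ln_step_length")

#' Decompose trajectories into steps
#'
#' A step is the straight-line displacement between consecutive fixes. The
#' turning angle is the signed change in bearing relative to the previous
#' step (counterclockwise positive), wrapped to (-pi, pi]; it is NA for the
#' first step of each animal and after a zero-length step (undefined
#' bearing).
#'
#' @param fixes fixes data.frame (one or more animals).
#' @return data.frame with one row per step: `animal_id`, `t1`, `t2`,
#'   `x1`, `y1`, `x2`, `y2`, `length`, `bearing`, `turn`, `dt_s`.
#' @export
decompose_steps <- function(fixes) {
  per_animal <- function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    dx <- diff(tr$x); dy <- diff(tr$y)
    len <- sqrt(dx^2 + dy^2)
    bearing <- atan2(dy, dx)
    bearing[len == 0] <- NA_real_
    turn <- c(NA_real_, wrap_angle(diff(bearing)))
    data.frame(animal_id = tr$animal_id[1],
               t1 = tr$t[-n], t2 = tr$t[-1],
               x1 = tr$x[-n], y1 = tr$y[-n],
               x2 = tr$x[-1], y2 = tr$y[-1],
               length = len, bearing = bearing, turn = turn,
               dt_s = as.numeric(diff(as.numeric(tr$t))),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(fixes, fixes$animal_id), per_animal))
  rownames(out) <- NULL
  out
}

#' Fit movement kernels to observed steps
#'
#' Maximum-likelihood Gamma on step lengths and von Mises on turning angles;
#' these generate the random (available) steps.
#'
#' @param steps data.frame from [decompose_steps()].
#' @return a `step_kernels` list: `gamma_shape`, `gamma_scale`, `vm_mu`,
#'   `vm_kappa`, and the sample sizes used.
#' @export
fit_step_kernels <- function(steps) {
  len <- steps$length[is.finite(steps$length) & steps$length > 0]
  if (length(len) < 30) stop("need at least 30 positive step lengths")
  if (stats::sd(len) < .Machine$double.eps * mean(len))
    stop("all step lengths identical; Gamma MLE is degenerate - jitter the ",
         "coordinates or check the data")
  g <- suppressWarnings(
    tryCatch(MASS::fitdistr(len, "gamma"),
             error = function(e)
               MASS::fitdistr(len, "gamma", lower = c(1e-8, 1e-12))))
  vm <- fit_vonmises(steps$turn)
  structure(list(gamma_shape = unname(g$estimate["shape"]),
                 gamma_scale = 1 / unname(g$estimate["rate"]),
                 vm_mu = vm$mu, vm_kappa = vm$kappa,
                 n_lengths = length(len), n_turns = vm$n),
            class = "step_kernels")
}

#' Generate random candidate steps for each observed step
#'
#' For each observed step whose previous bearing is defined, K random
#' endpoints are projected from the step's start fix: distance drawn from the
#' Gamma kernel, heading = previous bearing + a von Mises turning-angle draw.
#'
#' @param steps data.frame from [decompose_steps()].
#' @param kernels a `step_kernels` object.
#' @param K random steps per observed step.
#' @param seed integer seed.
#' @return data.frame: `step_row` (row index into `steps`), `x`, `y`,
#'   `length`, `turn`.
#' @export
generate_random_steps <- function(steps, kernels, K = 20, seed = 1L) {
  set.seed(split_seed(seed, 0L))
  usable <- which(is.finite(steps$turn) & steps$length > 0)
  n <- length(usable) * K
  len <- stats::rgamma(n, shape = kernels$gamma_shape,
                       scale = kernels$gamma_scale)
  turn <- rvonmises(n, kernels$vm_mu, kernels$vm_kappa)
  prev_bearing <- rep(steps$bearing[usable] - steps$turn[usable], each = K)
  heading <- prev_bearing + turn
  x1 <- rep(steps$x1[usable], each = K)
  y1 <- rep(steps$y1[usable], each = K)
  data.frame(step_row = rep(usable, each = K),
             x = x1 + len * cos(heading), y = y1 + len * sin(heading),
             length = len, turn = turn)
}

# normalize a parturient set: list(fixes=..., events=...) with events having
# event_time or birth_time
as_parturient_set <- function(parturient_set) {
  if (is.null(parturient_set)) return(NULL)
  ev <- parturient_set$events
  if (!is.null(ev) && is.null(ev$event_time)) ev$event_time <- ev$birth_time
  list(fixes = parturient_set$fixes, events = ev)
}

#' Encounter indicator: proximity to a parturient female
#'
#' Returns 1 when, at query time t, at least one GPS-collared prey female is
#' within her 30-day post-partum window AND her contemporaneous fix (nearest
#' fix within the matching tolerance, ties to the earlier fix) lies within
#' `radius_m` (inclusive) of the endpoint.
#'
#' @param x,y endpoint coordinates (vectors).
#' @param t POSIXct vector of endpoint times (same length).
#' @param parturient_set list with `fixes` (prey fix table) and `events`
#'   (`animal_id`, `event_time` or `birth_time`).
#' @param radius_m encounter radius in meters (inclusive).
#' @param window_d post-partum window in days.
#' @param tolerance temporal matching window (difftime or seconds); default
#'   15 min = half the 30-min elk fix interval.
#' @return integer vector of 0/1.
#' @export
encounter_indicator <- function(x, y, t, parturient_set, radius_m = 200,
                                window_d = 30,
                                tolerance = as.difftime(15, units = "mins")) {
  ps <- as_parturient_set(parturient_set)
  enc <- integer(length(x))
  if (is.null(ps) || is.null(ps$events) || nrow(ps$events) == 0) return(enc)
  tn <- as.numeric(t)
  prey_split <- split(ps$fixes, ps$fixes$animal_id)
  for (i in seq_len(nrow(ps$events))) {
    id <- ps$events$animal_id[i]
    tr <- prey_split[[id]]
    if (is.null(tr)) next
    ev <- as.numeric(ps$events$event_time[i])
    in_window <- tn >= ev & tn <= ev + window_d * 86400
    if (!any(in_window)) next
    mc <- match_contemporaneous(t[in_window], tr, tolerance)
    d2 <- (x[in_window] - mc$x)^2 + (y[in_window] - mc$y)^2
    hit <- !is.na(mc$idx) & d2 <= radius_m^2
    enc[in_window][hit] <- 1L
  }
  enc
}

#' Build matched step strata with endpoint covariates
#'
#' One stratum per usable observed step (defined turning angle, positive
#' length, on-raster endpoint) holding the observed endpoint plus K random
#' endpoints. Covariates: the encounter indicator, canopy, vegetation-class
#' dummies (reference: open forest), ruggedness, ln(distance to road),
#' ln(distance to water), ln(step length), cos(turning angle). Continuous
#' covariates are standardized over the pooled design (observed + random
#' rows); cos(turning angle) is a bounded index and is left unscaled;
#' zero-variance columns are skipped and flagged.
#'
#' @param predator_fixes fixes data.frame for the predator(s) being fit
#'   (pool all animals of one species, or filter by sex for sex-specific
#'   fits).
#' @param landscape a `covariate_stack`.
#' @param parturient_set prey fixes + events (see [encounter_indicator()]);
#'   NULL gives an all-zero encounter column.
#' @param kernels optional `step_kernels`; fitted from `predator_fixes` when
#'   NULL.
#' @param K random steps per observed step.
#' @param seed integer seed for the random-step draws.
#' @param radius_m,window_d,tolerance encounter definition.
#' @return an `ssf_strata` object: `data` (stratum, y, covariates),
#'   `standardization`, `skipped` (zero-variance columns), `kernels`, `K`,
#'   and dropped-row counts.
#' @export
build_strata <- function(predator_fixes, landscape, parturient_set = NULL,
                         kernels = NULL, K = 20, seed = 1L, radius_m = 200,
                         window_d = 30,
                         tolerance = as.difftime(15, units = "mins")) {
  steps <- decompose_steps(predator_fixes)
  if (is.null(kernels)) kernels <- fit_step_kernels(steps)
  rnd <- generate_random_steps(steps, kernels, K = K, seed = seed)
  usable <- sort(unique(rnd$step_row))
  obs <- data.frame(step_row = usable,
                    x = steps$x2[usable], y = steps$y2[usable],
                    length = steps$length[usable], turn = steps$turn[usable])
  all_pts <- rbind(cbind(obs, y_obs = 1L), cbind(rnd, y_obs = 0L))
  all_pts$t <- steps$t2[all_pts$step_row]
  cv <- design_covariates(all_pts[, c("x", "y")], landscape)
  oob <- attr(cv, "oob")
  # strata whose observed endpoint is off-raster are dropped entirely
  bad_strata <- unique(all_pts$step_row[oob & all_pts$y_obs == 1L])
  keep <- !oob & !(all_pts$step_row %in% bad_strata)
  n_dropped_random <- sum(oob & all_pts$y_obs == 0L)
  all_pts <- all_pts[keep, , drop = FALSE]
  cv <- cv[keep, , drop = FALSE]
  enc <- encounter_indicator(all_pts$x, all_pts$y, all_pts$t,
                             parturient_set, radius_m = radius_m,
                             window_d = window_d, tolerance = tolerance)
  dat <- data.frame(stratum = match(all_pts$step_row,
                                    sort(unique(all_pts$step_row))),
                    y = all_pts$y_obs, enc = enc,
                    canopy = cv$canopy, ruggedness = cv$ruggedness,
                    ln_dist_road = cv$ln_dist_road,
                    ln_dist_water = cv$ln_dist_water,
                    ln_step_length = log(all_pts$length),
                    cos_turn = cos(all_pts$turn))
  if ("veg_class" %in% names(cv)) dat <- cbind(dat, veg_dummies(cv$veg_class))
  std <- standardize_design(dat[, setdiff(names(dat),
                                          c("stratum", "y", "enc", "cos_turn")),
                                drop = FALSE],
                            exclude = grep("^veg_", names(dat), value = TRUE))
  dat[, names(std$data)] <- std$data
  structure(list(data = dat, standardization = std$constants,
                 skipped = std$skipped, kernels = kernels, K = K,
                 n_strata = length(unique(dat$stratum)),
                 n_dropped_random = n_dropped_random,
                 n_dropped_strata = length(bad_strata),
                 settings = list(radius_m = radius_m, window_d = window_d,
                                 tolerance_s = as.numeric(tolerance,
                                                          units = "secs"))),
            class = "ssf_strata")
}

#' @export
print.ssf_strata <- function(x, ...) {
  cat(sprintf("<ssf_strata> %d strata, K = %d (%d random endpoints dropped off-raster)\n",
              x$n_strata, x$K, x$n_dropped_random))
  invisible(x)
}

#' Fit a conditional logistic regression over matched strata
#'
#' Maximizes the conditional-logistic (matched case-control) likelihood by
#' Newton iteration: start at 0, step-halving when the likelihood decreases,
#' convergence at gradient max-norm < `tol`. Standard errors come from the
#' inverse observed information at the optimum.
#'
#' @param strata an `ssf_strata` object, or a data.frame with columns
#'   `stratum`, `y` (one 1 per stratum) and covariates.
#' @param covariates optional character vector selecting covariate columns
#'   (default: every column except `stratum` and `y`).
#' @param tol gradient max-norm tolerance.
#' @param max_iter iteration cap.
#' @return a `selection_fit`: `coefficients` (term, estimate, se, z, p),
#'   `logLik`, `n_strata`, `converged`, `vcov`, `iterations`.
#' @export
fit_conditional_logistic <- function(strata, covariates = NULL, tol = 1e-8,
                                     max_iter = 100L) {
  dat <- if (inherits(strata, "ssf_strata")) strata$data else strata
  if (is.null(covariates))
    covariates <- setdiff(names(dat), c("stratum", "y"))
  if (inherits(strata, "ssf_strata"))
    covariates <- setdiff(covariates, strata$skipped)
  sid <- as.integer(factor(dat$stratum))
  X <- as.matrix(dat[, covariates, drop = FALSE])
  y <- dat$y
  if (any(tapply(y, sid, sum) != 1))
    stop("each stratum must contain exactly one observed (y = 1) row")
  n_s <- max(sid)
  if (n_s < 2) stop("need at least 2 strata")
  p <- ncol(X)
  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    smax <- as.numeric(tapply(eta, sid, max))
    lse <- log(drop(rowsum(exp(eta - smax[sid]), sid))) + smax
    sum(eta[y == 1]) - sum(lse)
  }
  ll <- loglik(beta)
  converged <- FALSE
  it <- 0L
  diagnostic <- NULL
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mx <- as.numeric(tapply(eta, sid, max))[sid]
    w <- exp(eta - mx)
    denom <- drop(rowsum(w, sid))[sid]
    pr <- w / denom
    grad <- drop(crossprod(X, y - pr))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    M <- rowsum(X * pr, sid)              # per-stratum E[x]
    H <- -(crossprod(X * sqrt(pr)) - crossprod(M))
    step <- tryCatch(solve(-H, grad), error = function(e) NULL)
    if (is.null(step)) {
      diagnostic <- "singular information matrix (separation or collinearity)"
      break
    }
    # step-halving on likelihood decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta_new; ll <- ll_new
  }
  if (!converged && is.null(diagnostic))
    diagnostic <- paste0("gradient max-norm ", format(max(abs(grad))),
                         " at iteration cap; possible separation (e.g. the ",
                         "encounter indicator perfectly predicting observed ",
                         "steps)")
  if (converged && max(abs(beta)) > 15) {
    # a coefficient this large on a standardized/binary covariate means the
    # likelihood is maximized at infinity (separation), not an interior optimum
    converged <- FALSE
    diagnostic <- paste0("coefficient diverging (max |beta| = ",
                         format(max(abs(beta)), digits = 3),
                         "); separation - a covariate perfectly predicts ",
                         "the observed steps")
  }
  eta <- drop(X %*% beta)
  mx <- as.numeric(tapply(eta, sid, max))[sid]
  w <- exp(eta - mx)
  pr <- w / drop(rowsum(w, sid))[sid]
  M <- rowsum(X * pr, sid)
  info <- crossprod(X * sqrt(pr)) - crossprod(M)
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  structure(list(
    coefficients = data.frame(term = covariates, estimate = beta, se = se,
                              z = z, p = 2 * stats::pnorm(-abs(z)),
                              row.names = NULL),
    logLik = ll, n_strata = n_s, converged = converged,
    diagnostic = diagnostic, vcov = V, iterations = it),
    class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("<selection_fit> %d strata, logLik = %.3f, %s (%d iterations)\n",
              x$n_strata, x$logLik,
              if (x$converged) "converged" else
                paste("NOT converged:", x$diagnostic), x$iterations))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 4)
  tab$z <- signif(tab$z, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export a selection fit as JSON
#' @param fit a `selection_fit` or `rsf_fit`.
#' @param path output path.
#' @param settings optional settings list echoed into the file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, settings = NULL) {
  out <- list(coefficients = fit$coefficients, logLik = fit$logLik,
              n_strata = fit$n_strata, converged = fit$converged,
              settings = settings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
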