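# Phenology tracking: weekly mean parturition-habitat RSF scores at carnivore
# relocations, a random-intercept linear mixed model in Julian week (linear
# vs quadratic), and the likelihood-ratio test of the quadratic birth-pulse
# term. A concave quadratic whose peak aligns with the birth pulse indicates
# the predator shifts habitat use to track neonate availability.

#' Weekly mean RSF scores at predator relocations
#'
#' For each animal and Julian week (per calendar year) within the seasonal
#' window, the mean selection-surface score over that animal's fixes; fixes
#' on missing cells are dropped and counted.
#'
#' @param predator_fixes predator fix table.
#' @param surface a `selection_surface` (or single-layer `covariate_stack`).
#' @param start,end season window as `"mm-dd"` strings (applied per calendar
#'   year); defaults 15 April - 31 July.
#' @param min_fixes minimum fixes for a week record to be kept.
#' @param complete_weeks keep only Julian weeks whose full 7-day span lies
#'   inside the season window (the default). Weeks truncated by the window
#'   edge average far fewer fixes, and their inflated sampling variance sits
#'   exactly at the extremes of the week axis, where it loads on the
#'   quadratic term and distorts the phenology test; `FALSE` retains them,
#'   truncated to the fixes inside the window.
#' @return data.frame: `animal_id`, `year`, `julian_week`, `mean_score`,
#'   `n_fixes`; attribute `n_dropped` counts fixes on missing cells.
#' @export
weekly_use <- function(predator_fixes, surface, start = "04-15",
                       end = "07-31", min_fixes = 1L,
                       complete_weeks = TRUE) {
  sc <- if (inherits(surface, "selection_surface"))
    surface_at(surface, predator_fixes) else
      sample_covariates(predator_fixes, surface)[[1]]
  yr <- as.integer(format(predator_fixes$t, "%Y", tz = "UTC"))
  t0 <- as.POSIXct(paste0(yr, "-", start), tz = "UTC")
  t1 <- as.POSIXct(paste0(yr, "-", end), tz = "UTC") + 86400  # end inclusive
  in_window <- predator_fixes$t >= t0 & predator_fixes$t < t1
  if (complete_weeks) {
    doy0 <- as.integer(format(t0, "%j", tz = "UTC"))
    doy1 <- as.integer(format(t1 - 1, "%j", tz = "UTC"))
    wk <- julian_week(predator_fixes$t)
    in_window <- in_window & (7 * wk - 6 >= doy0) & (7 * wk <= doy1)
  }
  keep <- in_window & !is.na(sc)
  n_dropped <- sum(in_window & is.na(sc))
  if (!any(keep)) {
    warning("no fixes with defined scores in the seasonal window")
    out <- data.frame(animal_id = character(), year = integer(),
                      julian_week = integer(), mean_score = numeric(),
                      n_fixes = integer())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  d <- data.frame(animal_id = predator_fixes$animal_id[keep],
                  year = yr[keep],
                  julian_week = julian_week(predator_fixes$t[keep]),
                  score = sc[keep])
  agg <- stats::aggregate(score ~ animal_id + year + julian_week, data = d,
                          FUN = mean)
  cnt <- stats::aggregate(score ~ animal_id + year + julian_week, data = d,
                          FUN = length)
  out <- data.frame(animal_id = agg$animal_id, year = agg$year,
                    julian_week = agg$julian_week, mean_score = agg$score,
                    n_fixes = cnt$score)
  out <- out[out$n_fixes >= min_fixes, , drop = FALSE]
  out <- out[order(out$animal_id, out$year, out$julian_week), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit the phenology mixed model
#'
#' Linear mixed model of weekly mean RSF score on Julian week with a random
#' intercept per animal, fitted by maximum likelihood (not REML) so that
#' likelihood-ratio tests on the fixed effects are valid. Week is centered at
#' the midpoint of its observed range and scaled to unit standard deviation
#' before squaring (`form = "quadratic"`). When the random-intercept variance
#' collapses to zero (singular fit), the model falls back to ordinary least
#' squares and is flagged.
#'
#' @param records data.frame from [weekly_use()].
#' @param form `"linear"` or `"quadratic"`.
#' @return a `phenology_fit`: `fixed` (term, estimate, se), `loglik` (ML),
#'   `form`, `centering` (`mid`, `scale`), `singular`, `n_animals`,
#'   `n_records`, and the underlying `model`.
#' @export
fit_phenology <- function(records, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  if (length(unique(records$animal_id)) < 2)
    stop("need >= 2 animals for a random-intercept model")
  if (length(unique(records$julian_week)) < 3)
    stop("need >= 3 distinct weeks")
  mid <- mean(range(records$julian_week))
  scl <- stats::sd(records$julian_week)
  if (!is.finite(scl) || scl == 0) scl <- 1
  d <- data.frame(score = records$mean_score,
                  wk = (records$julian_week - mid) / scl,
                  animal_id = factor(records$animal_id))
  d$wk2 <- d$wk^2
  fml <- if (form == "quadratic")
    score ~ wk + wk2 + (1 | animal_id) else score ~ wk + (1 | animal_id)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5) ||
    inherits(tryCatch(suppressWarnings(summary(fit)),
                      error = function(e) e), "error")
  if (singular) {
    # zero between-animal variance: profile out the random effect entirely
    fml0 <- if (form == "quadratic") score ~ wk + wk2 else score ~ wk
    fit <- stats::lm(fml0, data = d)
    cf <- suppressWarnings(summary(fit))$coefficients
    fixed <- data.frame(term = rownames(cf), estimate = cf[, 1],
                        se = cf[, 2], row.names = NULL)
    var_animal <- 0
    var_resid <- mean(stats::residuals(fit)^2)
  } else {
    cf <- suppressWarnings(summary(fit))$coefficients
    fixed <- data.frame(term = rownames(cf), estimate = cf[, 1],
                        se = cf[, 2], row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_animal <- vc$vcov[vc$grp == "animal_id"]
    var_resid <- vc$vcov[vc$grp == "Residual"]
  }
  structure(list(fixed = fixed, loglik = as.numeric(stats::logLik(fit)),
                 form = form, centering = list(mid = mid, scale = scl),
                 var_animal = var_animal, var_resid = var_resid,
                 singular = singular,
                 n_animals = length(unique(records$animal_id)),
                 n_records = nrow(records), model = fit),
            class = "phenology_fit")
}

#' @export
print.phenology_fit <- function(x, ...) {
  cat(sprintf("<phenology_fit> %s, ML logLik = %.3f, %d animals, %d records%s\n",
              x$form, x$loglik, x$n_animals, x$n_records,
              if (x$singular) " (singular random intercept; OLS fallback)" else ""))
  tab <- x$fixed
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("var(animal) = %.4g, var(resid) = %.4g\n",
              x$var_animal, x$var_resid))
  invisible(x)
}

#' Likelihood-ratio test between nested phenology fits
#'
#' @param full,reduced `phenology_fit`s on identical records, both ML, the
#'   reduced model nested in the full one.
#' @return list: `statistic` (2 * delta logLik), `df`, `p`.
#' @export
lrt_phenology <- function(full, reduced) {
  if (full$n_records != reduced$n_records)
    stop("fits are not on the same records")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    stop("reduced model has higher likelihood than the full model; ",
         "refit before testing")
  stat <- max(stat, 0)
  df <- nrow(full$fixed) - nrow(reduced$fixed)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Week at which the fitted quadratic peaks
#'
#' Vertex of the quadratic fixed effect, back-transformed to the original
#' Julian-week scale. Requires a concave quadratic (negative week-squared
#' coefficient).
#'
#' @param fit a quadratic `phenology_fit`.
#' @return peak Julian week (numeric).
#' @export
peak_week <- function(fit) {
  stopifnot(inherits(fit, "phenology_fit"))
  if (fit$form != "quadratic") stop("peak_week needs a quadratic fit")
  b <- fit$fixed$estimate[match(c("wk", "wk2"), fit$fixed$term)]
  if (any(is.na(b))) stop("quadratic terms missing from the fit")
  if (b[2] >= 0)
    stop("week-squared coefficient is non-negative: no interior maximum")
  vertex <- -b[1] / (2 * b[2])
  fit$centering$mid + fit$centering$scale * vertex
}
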