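# Shared covariate design construction: raw raster sampling, natural-log
# transform of the distance layers, vegetation dummy coding. Standardization
# is applied afterwards via standardize_design(), once per fitted model over
# that model's full design.

#' Sample model covariates at points, with distance layers log-transformed
#'
#' Extracts every layer at the points (nearest cell), replaces the
#' distance-to-road and distance-to-water layers by `ln_dist_road` /
#' `ln_dist_water` (natural log of distance + 1 m, so on-feature cells stay
#' finite), and leaves the vegetation class as a factor. Values are raw
#' (unstandardized).
#'
#' @param points data.frame with `x`, `y`.
#' @param landscape a `covariate_stack`.
#' @param aspect_mode `"degrees"` keeps aspect as-is; `"sincos"` replaces it
#'   by `aspect_sin` and `aspect_cos` (for the circular-coherent RSF coding).
#' @return data.frame of covariates with attribute `oob`.
#' @export
design_covariates <- function(points, landscape,
                              aspect_mode = c("degrees", "sincos")) {
  aspect_mode <- match.arg(aspect_mode)
  cv <- sample_covariates(points, landscape)
  oob <- attr(cv, "oob")
  for (nm in c("dist_road", "dist_water")) {
    if (nm %in% names(cv)) {
      cv[[sub("dist", "ln_dist", nm)]] <- log1p(cv[[nm]])
      cv[[nm]] <- NULL
    }
  }
  if (aspect_mode == "sincos" && "aspect" %in% names(cv)) {
    rad <- cv$aspect * pi / 180
    cv$aspect_sin <- sin(rad)
    cv$aspect_cos <- cos(rad)
    cv$aspect <- NULL
  }
  attr(cv, "oob") <- oob
  cv
}

# vegetation factor -> dummy columns with open_forest as the reference class
veg_dummies <- function(veg) {
  lev <- levels(veg)
  ref <- if ("open_forest" %in% lev) "open_forest" else lev[1]
  out <- list()
  for (cl in setdiff(lev, ref)) {
    out[[paste0("veg_", cl)]] <- as.numeric(veg == cl)
  }
  as.data.frame(out)
}
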