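# Minimal single-resolution raster stack used throughout the package.
#
# Conventions (fixed so that every module samples pixels identically):
#   * coordinates are planar meters; the stack origin (xmin, ymin) is the
#     LOWER-LEFT corner of the grid;
#   * each layer is a numeric matrix indexed row-major from the TOP-LEFT,
#     i.e. row 1 is the northernmost row;
#   * sampling is nearest-cell (30-m pixel semantics), no interpolation.

#' Construct a covariate raster stack
#'
#' @param layers named list of numeric matrices with identical dimensions.
#'   Categorical layers are integer matrices whose levels are given in
#'   `levels`.
#' @param cell_size cell edge length in meters.
#' @param xmin,ymin coordinates of the lower-left corner.
#' @param categorical character vector naming the categorical layers.
#' @param levels named list mapping categorical layer names to their class
#'   labels (integer code k means `levels[[name]][k]`).
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, cell_size, xmin = 0, ymin = 0,
                            categorical = character(), levels = list()) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)),
            cell_size > 0)
  d <- dim(layers[[1]])
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), d))
      stop("layer '", nm, "' has mismatched dimensions")
  }
  if (!all(categorical %in% names(layers)))
    stop("categorical names must match layer names")
  structure(
    list(layers = layers, cell_size = cell_size, xmin = xmin, ymin = ymin,
         nrow = d[1], ncol = d[2], categorical = categorical,
         levels = levels),
    class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  ext <- stack_extent(x)
  cat(sprintf("<covariate_stack> %d x %d cells @ %g m, extent [%g, %g] x [%g, %g]\n",
              x$nrow, x$ncol, x$cell_size, ext[1], ext[2], ext[3], ext[4]))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (length(x$categorical))
    cat("categorical:", paste(x$categorical, collapse = ", "), "\n")
  invisible(x)
}

#' Extent of a stack as (xmin, xmax, ymin, ymax)
#' @param stack a `covariate_stack`.
#' @return numeric length-4 vector.
#' @export
stack_extent <- function(stack) {
  c(stack$xmin, stack$xmin + stack$ncol * stack$cell_size,
    stack$ymin, stack$ymin + stack$nrow * stack$cell_size)
}

# row/col of the cell containing (x, y); NA outside the extent
cell_rowcol <- function(stack, x, y) {
  col <- floor((x - stack$xmin) / stack$cell_size) + 1
  row <- stack$nrow - floor((y - stack$ymin) / stack$cell_size)
  # points exactly on the top/right edge belong to the last cell
  col[x == stack$xmin + stack$ncol * stack$cell_size] <- stack$ncol
  row[y == stack$ymin + stack$nrow * stack$cell_size] <- 1
  bad <- !is.finite(x) | !is.finite(y) | col < 1 | col > stack$ncol |
    row < 1 | row > stack$nrow
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# x/y coordinates of all cell centers, in layer storage order
cell_centers <- function(stack) {
  cs <- stack$cell_size
  x <- stack$xmin + (seq_len(stack$ncol) - 0.5) * cs
  y <- stack$ymin + (stack$nrow - seq_len(stack$nrow) + 0.5) * cs
  list(x = x, y = y)  # y ordered from top row down
}

#' Sample raster covariates at point locations
#'
#' Nearest-cell extraction of every layer at the supplied points. Categorical
#' layers are returned as factors; out-of-bounds points yield NA rows and are
#' flagged in the `oob` attribute.
#'
#' @param points data.frame or matrix with columns `x` and `y` (meters).
#' @param stack a `covariate_stack`.
#' @param standardization optional list of per-layer `(mean, sd)` as produced
#'   by [standardize_design()]; when supplied, continuous layers are centered
#'   and scaled with these constants. When absent, raw values are returned.
#' @return data.frame with one row per point and one column per layer, plus
#'   attribute `oob` (logical vector marking out-of-bounds points).
#' @export
sample_covariates <- function(points, stack, standardization = NULL) {
  pts <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(pts)))
  rc <- cell_rowcol(stack, pts$x, pts$y)
  oob <- is.na(rc[, 1])
  idx <- (rc[, 2] - 1L) * stack$nrow + rc[, 1]  # column-major matrix index
  out <- data.frame(row.names = seq_len(nrow(pts)))
  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]][idx]
    if (nm %in% stack$categorical) {
      lev <- stack$levels[[nm]] %||% as.character(sort(unique(v)))
      out[[nm]] <- factor(lev[v], levels = lev)
    } else {
      if (!is.null(standardization) && nm %in% names(standardization)) {
        s <- standardization[[nm]]
        v <- (v - s$mean) / s$sd
      }
      out[[nm]] <- v
    }
  }
  attr(out, "oob") <- oob
  out
}

#' Compute or apply standardization constants for a design matrix
#'
#' Continuous covariates are centered to mean 0 and scaled to unit standard
#' deviation over the full design they enter (observed + random steps for an
#' SSF; used + available points for an RSF), so coefficients are comparable
#' within a fit. Zero-variance columns are left unscaled and flagged.
#'
#' @param df data.frame of covariates; non-numeric columns are passed through.
#' @param constants optional previously computed constants to apply.
#' @param exclude column names never standardized (e.g. bounded indices).
#' @return list with `data` (standardized data.frame), `constants` (named list
#'   of `(mean, sd)`), and `skipped` (zero-variance column names).
#' @export
standardize_design <- function(df, constants = NULL, exclude = character()) {
  out <- df
  skipped <- character()
  if (is.null(constants)) {
    constants <- list()
    for (nm in names(df)) {
      if (!is.numeric(df[[nm]]) || nm %in% exclude) next
      m <- mean(df[[nm]], na.rm = TRUE)
      s <- stats::sd(df[[nm]], na.rm = TRUE)
      if (!is.finite(s) || s == 0) { skipped <- c(skipped, nm); next }
      constants[[nm]] <- list(mean = m, sd = s)
    }
  }
  for (nm in names(constants)) {
    if (nm %in% names(out))
      out[[nm]] <- (out[[nm]] - constants[[nm]]$mean) / constants[[nm]]$sd
  }
  list(data = out, constants = constants, skipped = skipped)
}

#' Write a raster stack as ESRI ASCII grids with a JSON sidecar
#'
#' One `<layer>.asc` per layer plus `layers.json` recording layer order,
#' categorical levels and grid geometry.
#'
#' @param stack a `covariate_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    path <- file.path(dir, paste0(nm, ".asc"))
    con <- file(path, "w")
    writeLines(c(
      paste("ncols", stack$ncol), paste("nrows", stack$nrow),
      paste("xllcorner", format(stack$xmin, scientific = FALSE)),
      paste("yllcorner", format(stack$ymin, scientific = FALSE)),
      paste("cellsize", format(stack$cell_size, scientific = FALSE)),
      "NODATA_value -9999"), con)
    m <- stack$layers[[nm]]
    m[!is.finite(m)] <- -9999
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  meta <- list(layers = names(stack$layers), categorical = stack$categorical,
               levels = stack$levels, cell_size = stack$cell_size,
               xmin = stack$xmin, ymin = stack$ymin)
  jsonlite::write_json(meta, file.path(dir, "layers.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a raster stack written by [write_stack()]
#' @param dir directory containing `.asc` layers and `layers.json`.
#' @return a `covariate_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "layers.json"),
                              simplifyVector = TRUE)
  layers <- list()
  for (nm in meta$layers) {
    lines <- readLines(file.path(dir, paste0(nm, ".asc")))
    hdr <- strsplit(lines[1:6], "\\s+")
    vals <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                            tolower(vapply(hdr, `[`, "", 1)))
    m <- matrix(scan(text = lines[-(1:6)], quiet = TRUE),
                nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
    m[m == -9999] <- NA_real_
    if (nm %in% meta$categorical) storage.mode(m) <- "integer"
    layers[[nm]] <- m
  }
  lev <- meta$levels
  if (length(lev) == 0) lev <- list()
  covariate_stack(layers, cell_size = meta$cell_size, xmin = meta$xmin,
                  ymin = meta$ymin,
                  categorical = as.character(meta$categorical %||% character()),
                  levels = lev)
}
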