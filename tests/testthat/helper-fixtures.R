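# Shared fixtures, all generated in code.

# small landscape for unit tests (60 x 60 cells, 30 m)
test_landscape <- local({
  cache <- new.env()
  function(seed = 1L, extent = 1800) {
    key <- paste0("ls_", seed, "_", extent)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_landscape(
        landscape_config(extent = c(extent, extent), seed = seed))
    cache[[key]]
  }
})

# constant-covariate landscape (for zero-variance handling)
constant_landscape <- function(value = 5, n = 40, cell = 30) {
  m <- matrix(value, n, n)
  covariate_stack(list(canopy = m, ruggedness = m, dist_road = m,
                       dist_water = m),
                  cell_size = cell)
}

# minimal fix table builder
make_fixes <- function(xy, start = "2017-06-01", by_min = 30,
                       animal_id = "elk_01", species = "elk", sex = "F") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(animal_id = animal_id, species = species, sex = sex,
             t = t0 + (seq_len(nrow(xy)) - 1) * by_min * 60,
             x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

# trajectory cycling the 4 corners of a square of the given side (m), one
# corner per `by_min` minutes -> every full rolling window sees the square
square_patrol <- function(side, hours, by_min = 60, ...) {
  corners <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  n <- hours * 60 / by_min + 1
  idx <- ((seq_len(n) - 1) %% 4) + 1
  make_fixes(corners[idx, , drop = FALSE], by_min = by_min, ...)
}

# hand-rolled dense grid-search maximizer of the conditional-logistic
# likelihood (independent oracle; refined in two stages)
grid_clogit <- function(dat, covariates, lims = c(-10, 10), step = 0.01) {
  X <- as.matrix(dat[, covariates, drop = FALSE])
  sid <- as.integer(factor(dat$stratum))
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(eta[dat$y == 1]) -
      sum(log(vapply(split(exp(eta - max(eta)), sid), sum, 0))) -
      length(unique(sid)) * max(eta)
  }
  refine <- function(centers, half, step) {
    grids <- lapply(seq_along(centers), function(i)
      seq(centers[i] - half, centers[i] + half, by = step))
    best <- centers; best_ll <- ll(centers)
    if (length(centers) == 1) {
      for (b1 in grids[[1]]) {
        v <- ll(b1)
        if (v > best_ll) { best_ll <- v; best <- b1 }
      }
    } else {
      for (b1 in grids[[1]]) for (b2 in grids[[2]]) {
        v <- ll(c(b1, b2))
        if (v > best_ll) { best_ll <- v; best <- c(b1, b2) }
      }
    }
    best
  }
  ctr <- refine(rep(mean(lims), length(covariates)), diff(lims) / 2,
                if (length(covariates) == 1) step * 5 else 0.1)
  ctr <- refine(ctr, if (length(covariates) == 1) step * 10 else 0.2,
                step / 5)
  refine(ctr, step, step / 25)
}
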