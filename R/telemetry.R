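# Fix-table and event-table I/O plus temporal matching across species.
#
# Canonical fix CSV schema: animal_id,species,sex,timestamp_iso8601,x,y
# with timestamps in UTC and x/y in shared projected meters.

SPECIES_LEVELS <- c("cougar", "coyote", "black_bear", "bobcat",
                    "elk", "mule_deer", "other")
SEX_LEVELS <- c("F", "M", "unknown")

# validate a fixes data.frame; returns it ordered by animal and time
validate_fixes <- function(fixes) {
  need <- c("animal_id", "species", "sex", "t", "x", "y")
  if (!all(need %in% names(fixes)))
    stop("fixes must have columns: ", paste(need, collapse = ", "))
  bad_sp <- setdiff(unique(as.character(fixes$species)), SPECIES_LEVELS)
  if (length(bad_sp))
    stop("unknown species: ", paste(bad_sp, collapse = ", "))
  bad_sex <- setdiff(unique(as.character(fixes$sex)), SEX_LEVELS)
  if (length(bad_sex))
    stop("unknown sex code: ", paste(bad_sex, collapse = ", "))
  if (!inherits(fixes$t, "POSIXct")) stop("column t must be POSIXct")
  if (any(!is.finite(fixes$x) | !is.finite(fixes$y)))
    stop("non-finite coordinates in fixes")
  fixes <- fixes[order(fixes$animal_id, fixes$t), , drop = FALSE]
  dup <- stats::aggregate(t ~ animal_id, data = fixes,
                          FUN = function(tt) anyDuplicated(tt) > 0)
  if (any(dup$t))
    stop("non-increasing timestamps for animal(s): ",
         paste(dup$animal_id[dup$t], collapse = ", "))
  rownames(fixes) <- NULL
  fixes
}

#' Read GPS fixes from the canonical CSV schema
#'
#' Columns: `animal_id,species,sex,timestamp_iso8601,x,y`. Timestamps must be
#' ISO-8601 and are resolved as UTC. Within each animal, timestamps must be
#' strictly increasing; duplicates are rejected naming the offending animal.
#'
#' @param path CSV file path.
#' @return data.frame of fixes with columns `animal_id`, `species`, `sex`,
#'   `t` (POSIXct, UTC), `x`, `y`, ordered by animal and time.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(animal_id = "character",
                                        species = "character",
                                        sex = "character",
                                        timestamp_iso8601 = "character"))
  need <- c("animal_id", "species", "sex", "timestamp_iso8601", "x", "y")
  if (!all(need %in% names(raw)))
    stop("fix CSV must have header: ", paste(need, collapse = ","))
  t <- as.POSIXct(raw$timestamp_iso8601, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(t))) stop("unparseable timestamps in ", path)
  validate_fixes(data.frame(animal_id = as.character(raw$animal_id),
                            species = raw$species, sex = raw$sex, t = t,
                            x = raw$x, y = raw$y,
                            stringsAsFactors = FALSE))
}

#' Write GPS fixes in the canonical CSV schema
#' @param fixes fixes data.frame (see [read_fixes()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  fixes <- validate_fixes(fixes)
  out <- data.frame(animal_id = fixes$animal_id, species = fixes$species,
                    sex = fixes$sex,
                    timestamp_iso8601 = format(fixes$t, "%Y-%m-%dT%H:%M:%S",
                                               tz = "UTC"),
                    x = fixes$x, y = fixes$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write parturition event tables
#'
#' Event CSV schema: `animal_id,event_time,method,x,y` with ISO-8601 UTC
#' times.
#'
#' @param path CSV path.
#' @return data.frame with `animal_id`, `event_time` (POSIXct), `method`,
#'   `x`, `y`.
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  t <- as.POSIXct(raw$event_time, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(t))) stop("unparseable event times in ", path)
  data.frame(animal_id = as.character(raw$animal_id), event_time = t,
             method = raw$method %||% "unknown",
             x = raw$x, y = raw$y, stringsAsFactors = FALSE)
}

#' @rdname read_events
#' @param events events data.frame; the simulator's truth schema
#'   (`birth_time`, `birth_x`, `birth_y`) is accepted as well.
#' @export
write_events <- function(events, path) {
  tt <- events$event_time %||% events$birth_time
  out <- data.frame(animal_id = events$animal_id,
                    event_time = format(tt, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    method = events$method %||% "truth",
                    x = events$x %||% events$birth_x,
                    y = events$y %||% events$birth_y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Vectorized nearest-time match: index into sorted times `t_ref` of the fix
# nearest each query time, ties broken toward the EARLIER fix.
match_nearest_idx <- function(t_query, t_ref) {
  tq <- as.numeric(t_query); tr <- as.numeric(t_ref)
  lo <- findInterval(tq, tr)                # last ref <= query (0 if none)
  hi <- pmin(lo + 1L, length(tr))
  lo_c <- pmax(lo, 1L)
  d_lo <- abs(tq - tr[lo_c]); d_lo[lo == 0L] <- Inf
  d_hi <- abs(tr[hi] - tq)
  ifelse(d_lo <= d_hi, lo_c, hi)            # <= : earlier fix wins ties
}

#' Match a query time to the nearest contemporaneous prey fix
#'
#' Returns the prey fix minimizing |t_prey - t_query| when that gap is within
#' the tolerance, else no match. Exact ties between an earlier and a later
#' prey fix are resolved toward the earlier fix. The default tolerance in the
#' analyses is half the prey's nominal fix interval.
#'
#' @param t_query POSIXct vector of query times.
#' @param prey_trajectory fixes data.frame for ONE prey animal (sorted).
#' @param tolerance matching window as seconds or a `difftime`.
#' @return data.frame with one row per query: `idx` (row in the prey
#'   trajectory, NA if unmatched), `x`, `y`, `dt_s` (|gap| in seconds).
#' @export
match_contemporaneous <- function(t_query, prey_trajectory, tolerance) {
  tol_s <- as.numeric(tolerance, units = "secs")
  stopifnot(tol_s > 0)
  idx <- match_nearest_idx(t_query, prey_trajectory$t)
  dt <- abs(as.numeric(t_query) - as.numeric(prey_trajectory$t)[idx])
  miss <- dt > tol_s
  idx[miss] <- NA_integer_
  data.frame(idx = idx,
             x = ifelse(miss, NA_real_, prey_trajectory$x[idx]),
             y = ifelse(miss, NA_real_, prey_trajectory$y[idx]),
             dt_s = ifelse(miss, NA_real_, dt))
}
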