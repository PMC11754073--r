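#' Climate forcing series
#'
#' A `climate_forcing` object holds a temperature-anomaly time series on the
#' calendar age axis (cal yr BP), stored oldest-first.  Anomalies are in
#' degrees Celsius relative to present.  Before it can drive a simulation the
#' series is padded with a constant glacial spin-up segment
#' ([pad_spinup()]) and linearly regridded to a regular time step
#' ([regrid_forcing()]).
#'
#' @param age_bp Numeric vector of ages in cal yr BP (any order, no
#'   duplicates).
#' @param anomaly_c Numeric vector of temperature anomalies in degrees C
#'   relative to present, same length as `age_bp`.
#' @param step Grid step in years, or `NA` when the series is not (yet)
#'   regular.
#' @return An object of class `climate_forcing` with elements `age_bp`
#'   (sorted decreasing, i.e. oldest first), `anomaly_c` and `step`.
#' @seealso [read_forcing()], [pad_spinup()], [regrid_forcing()]
#' @examples
#' f <- climate_forcing(c(18000, 0), c(-4, 0))
#' forcing_at(f, 9000)
#' @export
climate_forcing <- function(age_bp, anomaly_c, step = NA_real_) {
  age_bp <- as.numeric(age_bp)
  anomaly_c <- as.numeric(anomaly_c)
  if (length(age_bp) != length(anomaly_c))
    stop_input("age_bp and anomaly_c must have the same length")
  if (length(age_bp) < 2)
    stop_input("a climate forcing needs at least 2 points")
  if (anyNA(age_bp) || anyNA(anomaly_c) || any(!is.finite(anomaly_c)))
    stop_input("non-finite values in climate forcing")
  if (anyDuplicated(age_bp))
    stop_input(sprintf("duplicated age(s) in climate forcing: %s",
                       paste(unique(age_bp[duplicated(age_bp)]), collapse = ", ")))
  o <- order(age_bp, decreasing = TRUE)
  structure(list(age_bp = age_bp[o], anomaly_c = anomaly_c[o], step = step),
            class = "climate_forcing")
}

#' @export
print.climate_forcing <- function(x, ...) {
  cat(sprintf("Climate forcing: %d points, %s to %s cal yr BP%s\n",
              length(x$age_bp), format(max(x$age_bp)), format(min(x$age_bp)),
              if (is.na(x$step)) "" else sprintf(", step %g yr", x$step)))
  cat(sprintf("  anomaly range: %.2f to %.2f degC\n",
              min(x$anomaly_c), max(x$anomaly_c)))
  invisible(x)
}

#' Evaluate a forcing by linear interpolation
#'
#' @param f A [climate_forcing()].
#' @param age Ages (cal yr BP) at which to evaluate; must lie within the
#'   series' age span.
#' @return Anomalies (degrees C) at `age`.
#' @export
forcing_at <- function(f, age) {
  stopifnot(inherits(f, "climate_forcing"))
  if (any(age > max(f$age_bp)) || any(age < min(f$age_bp)))
    stop_input("requested age outside the forcing's span")
  # stored oldest-first; approx wants increasing x
  stats::approx(rev(f$age_bp), rev(f$anomaly_c), xout = age,
                method = "linear", ties = "ordered")$y
}

#' Read a climate forcing CSV
#'
#' Expects a UTF-8 CSV with header `age_bp,anomaly_c`.  Rows may be in any
#' order; the series is stored oldest-first.  Duplicate ages and non-numeric
#' fields are rejected with the offending line named.
#'
#' @param path Path to the CSV file.
#' @return A [climate_forcing()].
#' @export
read_forcing <- function(path) {
  d <- read_checked_csv(path, c("age_bp", "anomaly_c"))
  climate_forcing(d$age_bp, d$anomaly_c)
}

# Shared CSV reader: header required, all columns numeric unless listed in
# `character_cols`, >= min_rows data rows.  Errors name the file and line
# (line numbers count the header as line 1).
read_checked_csv <- function(path, columns, character_cols = character(),
                             min_rows = 2) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_input(sprintf("%s: malformed CSV (%s)",
                                           path, conditionMessage(e))))
  missing <- setdiff(columns, names(d))
  if (length(missing))
    stop_input(sprintf("%s: missing column(s): %s", path,
                       paste(missing, collapse = ", ")))
  if (nrow(d) < min_rows)
    stop_input(sprintf("%s: needs at least %d data rows, found %d",
                       path, min_rows, nrow(d)))
  for (col in setdiff(columns, character_cols)) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop_input(sprintf("%s: non-numeric value '%s' in column %s, line %d",
                         path, d[[col]][bad[1]], col, bad[1] + 1L))
    if (anyNA(v))
      stop_input(sprintf("%s: missing value in column %s, line %d",
                         path, col, which(is.na(v))[1] + 1L))
    d[[col]] <- v
  }
  d[columns]
}

#' Pad a forcing with its glacial spin-up segment
#'
#' Extends the series back to `spinup_age` (default 50,000 cal yr BP) by
#' holding the anomaly interpolated at `source_age` (default 21,500 cal yr
#' BP) constant over all older ages.  This gives taxa time to equilibrate
#' with the glacial climate before the analysis window opens.  Ages at or
#' below `source_age` are unchanged; any input points older than
#' `source_age` are replaced by the constant segment.
#'
#' @param f A [climate_forcing()] whose span covers `source_age`.
#' @param spinup_age Oldest age of the padded series, cal yr BP.
#' @param source_age Age whose (interpolated) anomaly is held constant over
#'   the spin-up, cal yr BP.
#' @return A [climate_forcing()] extending to `spinup_age`.
#' @export
pad_spinup <- function(f, spinup_age = 50000, source_age = 21500) {
  stopifnot(inherits(f, "climate_forcing"))
  if (max(f$age_bp) < source_age)
    stop_input(sprintf(
      "forcing must cover %g cal yr BP to define the spin-up anomaly", source_age))
  a0 <- stats::approx(rev(f$age_bp), rev(f$anomaly_c), xout = source_age,
                      ties = "ordered")$y
  keep <- f$age_bp <= source_age
  climate_forcing(c(spinup_age, source_age, f$age_bp[keep & f$age_bp < source_age]),
                  c(a0, a0, f$anomaly_c[keep & f$age_bp < source_age]))
}

#' Regrid a forcing to a regular time step
#'
#' Linearly interpolates the series onto ages `start, start - step, ..., 0`
#' where `start` is the oldest input age rounded down to a multiple of
#' `step`.  Values at input knots that fall on the grid are preserved
#' exactly; regridding an already-regular series is the identity.
#'
#' @param f A [climate_forcing()], normally already padded with
#'   [pad_spinup()].
#' @param step Time step in years (default 25).
#' @return A regular [climate_forcing()] with `step` set.
#' @export
regrid_forcing <- function(f, step = 25) {
  stopifnot(inherits(f, "climate_forcing"))
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop_config("regrid step must be a single positive number")
  if (min(f$age_bp) > 0)
    stop_input("forcing must extend to 0 cal yr BP before regridding")
  start <- floor(max(f$age_bp) / step) * step
  ages <- seq(start, 0, by = -step)
  climate_forcing(ages, forcing_at(f, ages), step = step)
}

#' River terrain profile
#'
#' A `river_profile` is a one-dimensional chain of cells along the river
#' corridor.  Distances are metres along the river with the lake at the
#' origin (cell 1 at distance 0), increasing downstream; upstream catchment
#' cells, if supplied, carry negative distances.  Elevations are metres
#' above sea level.  The simulation requires a regular grid
#' ([regrid_profile()], default cell size 250 m).
#'
#' @param distance_m Numeric vector of strictly increasing distances (m).
#' @param elevation_m Positive elevations (m a.s.l.), same length.
#' @param cell_size Cell size in metres, or `NA` if not regular.
#' @param lake_index Index of the lake cell (distance 0); located
#'   automatically when a distance equals 0.
#' @return An object of class `river_profile` with elements `distance_m`,
#'   `elevation_m`, `cell_size`, `lake_index`, `lake_elevation`.
#' @examples
#' p <- river_profile(c(0, 500), c(4000, 3000))
#' regrid_profile(p, 250)$elevation_m
#' @export
river_profile <- function(distance_m, elevation_m, cell_size = NA_real_,
                          lake_index = NULL) {
  distance_m <- as.numeric(distance_m)
  elevation_m <- as.numeric(elevation_m)
  if (length(distance_m) != length(elevation_m))
    stop_input("distance_m and elevation_m must have the same length")
  if (length(distance_m) < 2)
    stop_input("a river profile needs at least 2 points")
  if (anyNA(distance_m) || anyNA(elevation_m) || any(!is.finite(elevation_m)))
    stop_input("non-finite values in river profile")
  if (any(diff(distance_m) <= 0))
    stop_input("profile distances must be strictly increasing")
  if (any(elevation_m <= 0))
    stop_input("profile elevations must be positive")
  if (is.null(lake_index)) {
    lake_index <- which(distance_m == 0)
    if (length(lake_index) != 1)
      stop_input("profile must contain the lake at distance 0 (or pass lake_index)")
  }
  structure(list(distance_m = distance_m, elevation_m = elevation_m,
                 cell_size = cell_size, lake_index = as.integer(lake_index),
                 lake_elevation = elevation_m[lake_index]),
            class = "river_profile")
}

#' @export
print.river_profile <- function(x, ...) {
  cat(sprintf("River profile: %d cells, %g to %g m along river%s\n",
              length(x$distance_m), min(x$distance_m), max(x$distance_m),
              if (is.na(x$cell_size)) "" else sprintf(", cell %g m", x$cell_size)))
  cat(sprintf("  elevation %g-%g m a.s.l.; lake at cell %d (%g m)\n",
              min(x$elevation_m), max(x$elevation_m), x$lake_index,
              x$lake_elevation))
  invisible(x)
}

#' Read a river profile CSV
#'
#' Expects a UTF-8 CSV with header `distance_m,elevation_m`; distance 0
#' marks the lake.
#'
#' @param path Path to the CSV file.
#' @return A [river_profile()].
#' @export
read_profile <- function(path) {
  d <- read_checked_csv(path, c("distance_m", "elevation_m"))
  river_profile(d$distance_m, d$elevation_m)
}

#' Regrid a river profile to a regular cell size
#'
#' Places cells every `cell` metres from the first to the last input
#' distance (the lake, at distance 0, always falls on the grid) and linearly
#' interpolates elevations.  A profile already on the target grid is
#' returned unchanged up to floating point.
#'
#' @param p A [river_profile()].
#' @param cell Cell size in metres (default 250).
#' @return A regular [river_profile()].
#' @export
regrid_profile <- function(p, cell = 250) {
  stopifnot(inherits(p, "river_profile"))
  if (!is.numeric(cell) || length(cell) != 1 || cell <= 0)
    stop_config("cell size must be a single positive number")
  lo <- ceiling(min(p$distance_m) / cell) * cell
  hi <- floor(max(p$distance_m) / cell) * cell
  d <- seq(lo, hi, by = cell)
  e <- stats::approx(p$distance_m, p$elevation_m, xout = d,
                     ties = "ordered")$y
  river_profile(d, e, cell_size = cell)
}
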