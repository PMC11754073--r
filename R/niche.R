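#' Build a taxon's elevation niche from species records
#'
#' A sedaDNA amplicon sequence variant ("taxon") may correspond to one or
#' more species.  The niche envelope is the union of the species' modern
#' elevation ranges; the median and mean are taken over the pooled record
#' values.  With `pooling = "endpoints"` (the default) each species
#' contributes its range endpoints (min and max) to the pool; with
#' `pooling = "means"` each species contributes its range midpoint.  The
#' distributional breadth, which drives colonization probability in the
#' simulation, is the absolute elevation range divided by the median of the
#' pooled observations.
#'
#' @param taxon_id Character label of the taxon (ASV).
#' @param records A two-column matrix/data.frame of per-species
#'   `(min, max)` elevations in metres, or a numeric vector of observation
#'   values.
#' @param pooling How multi-species records feed the median/mean:
#'   `"endpoints"` pools each species' min and max, `"means"` pools each
#'   species' midpoint.
#' @return An object of class `taxon_niche`: list with `taxon_id`,
#'   `elev_min`, `elev_max`, `elev_median`, `elev_mean`, `breadth`,
#'   `pooling`.
#' @examples
#' n <- build_niche("Picea", rbind(c(3000, 4000), c(3500, 5000)))
#' n$breadth  # (5000 - 3000) / median(c(3000, 4000, 3500, 5000))
#' @export
build_niche <- function(taxon_id, records,
                        pooling = c("endpoints", "means")) {
  pooling <- match.arg(pooling)
  if (is.null(records) || length(records) == 0)
    stop_input(sprintf("taxon %s: no elevation records", taxon_id))
  if (is.data.frame(records)) records <- as.matrix(records)
  if (is.matrix(records)) {
    if (ncol(records) != 2)
      stop_input(sprintf("taxon %s: records matrix must have 2 columns (min,max)",
                         taxon_id))
    lo <- as.numeric(records[, 1]); hi <- as.numeric(records[, 2])
    if (any(hi < lo))
      stop_input(sprintf("taxon %s: record with max < min", taxon_id))
    values <- switch(pooling,
                     endpoints = c(rbind(lo, hi)),
                     means = (lo + hi) / 2)
    emin <- min(lo); emax <- max(hi)
  } else {
    values <- as.numeric(records)
    emin <- min(values); emax <- max(values)
  }
  if (anyNA(values) || any(values <= 0))
    stop_input(sprintf("taxon %s: elevations must be positive and non-missing",
                       taxon_id))
  med <- stats::median(values)
  structure(list(taxon_id = as.character(taxon_id),
                 elev_min = emin, elev_max = emax,
                 elev_median = med, elev_mean = mean(values),
                 breadth = (emax - emin) / med,
                 pooling = pooling),
            class = "taxon_niche")
}

#' @export
print.taxon_niche <- function(x, ...) {
  cat(sprintf("Taxon niche %s: %g-%g m a.s.l. (median %g, mean %g), breadth %.4f\n",
              x$taxon_id, x$elev_min, x$elev_max, x$elev_median, x$elev_mean,
              x$breadth))
  invisible(x)
}

#' Read a taxon niche table
#'
#' Expects a CSV with header `taxon_id,species,elev_min_m,elev_max_m`, one
#' row per species; rows sharing `taxon_id` are pooled into one niche via
#' [build_niche()].
#'
#' @param path Path to the CSV file.
#' @param pooling Passed to [build_niche()].
#' @return A named list of [build_niche()] objects (a "niche set").
#' @export
read_taxa <- function(path, pooling = c("endpoints", "means")) {
  pooling <- match.arg(pooling)
  d <- read_checked_csv(path, c("taxon_id", "species", "elev_min_m", "elev_max_m"),
                        character_cols = c("taxon_id", "species"), min_rows = 1)
  ids <- unique(d$taxon_id)
  out <- lapply(ids, function(id) {
    r <- d[d$taxon_id == id, , drop = FALSE]
    build_niche(id, cbind(r$elev_min_m, r$elev_max_m), pooling = pooling)
  })
  names(out) <- ids
  out
}

#' Shift a niche to its suitable elevation band at a given anomaly
#'
#' The temperature anomaly is converted to an elevation shift through the
#' lapse rate: `shift = anomaly / lapse * 100` metres, so a cooling
#' (negative) anomaly lowers the band.  The band width never changes; the
#' modern envelope is translated rigidly.
#'
#' @param n A [build_niche()] object.
#' @param anomaly Temperature anomaly in degrees C relative to present.
#' @param lapse Temperature lapse rate in degrees C per 100 m (default
#'   0.55).
#' @return A list with `lower` and `upper` (m a.s.l.), class `niche_band`.
#' @examples
#' band_at(build_niche("x", c(4000, 5000)), anomaly = -5.5)  # 3000-4000 m
#' @export
band_at <- function(n, anomaly, lapse = 0.55) {
  stopifnot(inherits(n, "taxon_niche"))
  if (!is.numeric(lapse) || lapse <= 0)
    stop_config("lapse rate must be positive")
  shift <- anomaly / lapse * 100
  structure(list(lower = n$elev_min + shift, upper = n$elev_max + shift),
            class = "niche_band")
}

#' Suitable cells of a profile under a niche band
#'
#' Band membership is inclusive at both ends.
#'
#' @param band A [band_at()] result (or any list with `lower`, `upper`).
#' @param p A [river_profile()].
#' @return Logical vector over the profile's cells.
#' @export
suitable_cells <- function(band, p) {
  stopifnot(inherits(p, "river_profile"))
  p$elevation_m >= band$lower & p$elevation_m <= band$upper
}
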