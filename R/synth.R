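#' Synthetic river corridor profile
#'
#' Builds a monotone-decreasing piecewise-linear terrain profile from a
#' lake down to the lowland, already regridded to the model's cell size.
#' The two stock shapes contrast corridor connectivity: `"steep"` descends
#' over a 100-km corridor and `"gentle"` over a 400-km corridor (the same
#' elevation drop stretched over four times the distance), mirroring a
#' steep versus a gentle river valley below two otherwise comparable
#' alpine lakes.  `"custom"` interpolates user-supplied knots.
#'
#' @param shape `"steep"`, `"gentle"` or `"custom"`.
#' @param corridor_length Corridor length in metres (defaults: 1e5 steep,
#'   4e5 gentle).
#' @param lake_elevation Lake elevation, m a.s.l. (default 4000).
#' @param lowland_elevation Elevation at the corridor's far end (default
#'   3000).
#' @param knots For `"custom"`: two-column matrix of (distance_m,
#'   elevation_m) knots, distance 0 = lake.
#' @param cell Cell size in metres (default 250).
#' @return A regular [river_profile()].
#' @export
make_profile <- function(shape = c("steep", "gentle", "custom"),
                         corridor_length = NULL, lake_elevation = 4000,
                         lowland_elevation = 3000, knots = NULL,
                         cell = 250) {
  shape <- match.arg(shape)
  if (shape == "custom") {
    if (is.null(knots)) stop_input("custom profile needs knots")
    p <- river_profile(knots[, 1], knots[, 2])
  } else {
    corridor_length <- corridor_length %||%
      switch(shape, steep = 1e5, gentle = 4e5)
    if (lake_elevation <= lowland_elevation)
      stop_input("lake_elevation must exceed lowland_elevation")
    p <- river_profile(c(0, corridor_length),
                       c(lake_elevation, lowland_elevation))
  }
  regrid_profile(p, cell)
}

#' Synthetic deglacial climate forcing
#'
#' Piecewise-linear temperature anomaly through a set of (age, anomaly)
#' knots, padded with the constant glacial spin-up and regridded to the
#' model time step.  The default knots sketch a stylised deglaciation:
#' -6 degC at 18 ka, warming to -2 degC by 14 ka (late-glacial warming),
#' a cold reversal to -4 degC at 12 ka (Younger-Dryas-like dip), 0 degC
#' through the early/mid Holocene (10-4 ka) and a mild -1 degC late
#' Holocene cooling at present.
#'
#' @param knots Two-column matrix of (age_bp, anomaly_c) knots.
#' @param step Time step in years (default 25).
#' @param spinup_age,source_age Passed to [pad_spinup()].
#' @return A regular, padded [climate_forcing()].
#' @export
make_forcing <- function(knots = cbind(age_bp = c(18000, 14000, 12000,
                                                  10000, 4000, 0),
                                       anomaly_c = c(-6, -2, -4, 0, 0, -1)),
                         step = 25, spinup_age = 50000, source_age = 21500) {
  f <- climate_forcing(knots[, 1], knots[, 2])
  if (max(f$age_bp) < source_age) {
    # extend flat from the oldest knot so the spin-up anomaly is defined
    f <- climate_forcing(c(source_age, f$age_bp),
                         c(f$anomaly_c[1], f$anomaly_c))
  }
  regrid_forcing(pad_spinup(f, spinup_age, source_age), step)
}

# Envelope ranges (m a.s.l.) the band generator draws from.  Lowland taxa
# top out just above a 4000-m lake so that catchment presence is
# climate-gated; upland taxa live above 4800 m.
band_envelopes <- list(
  lowland = list(min = c(2800, 3200), max = c(4000, 4200)),
  mid     = list(min = c(3800, 4200), max = c(4300, 4800)),
  upland  = list(min = c(4600, 5000), max = c(5000, 5600)))

band_growth_forms <- list(
  lowland = c("tree", "shrub"),
  mid     = c("forb", "shrub", "graminoid"),
  upland  = c("cushion_rosette", "forb"))

band_heights <- list(tree = c(10, 30), shrub = c(1, 5), forb = c(0.1, 1),
                     graminoid = c(0.2, 1), cushion_rosette = c(0.01, 0.1))

#' Synthetic taxon set with niches and traits
#'
#' Draws taxa from three elevation bands (lowland, mid, upland), mirroring
#' the usual grouping of alpine floras by mean species elevation maximum.
#' Each taxon gets an elevation envelope sampled from band-appropriate
#' ranges, a [build_niche()] object (hence a distributional breadth), and a
#' trait row: `elev_max_mean_m` (the envelope maximum), a plant height
#' drawn by growth form (trees tallest, cushion plants smallest) and a
#' growth form typical of the band.
#'
#' @param n_lowland,n_mid,n_upland Taxon counts per band.
#' @param seed Integer seed; draws are reproducible bit-for-bit.
#' @return A list: `niches` (named list of [build_niche()] objects),
#'   `traits` (data.frame `taxon_id, elev_max_mean_m, plant_height_m,
#'   growth_form, band`).
#' @export
make_taxa <- function(n_lowland = 5, n_mid = 5, n_upland = 5, seed = 1) {
  set.seed(seed)
  counts <- c(lowland = n_lowland, mid = n_mid, upland = n_upland)
  niches <- list(); traits <- NULL
  for (band in names(counts)) {
    n <- counts[[band]]
    if (n == 0) next
    env <- band_envelopes[[band]]
    for (i in seq_len(n)) {
      gf <- sample(band_growth_forms[[band]], 1)
      id <- sprintf("%s_%s_%02d", band, gf, i)
      lo <- stats::runif(1, env$min[1], env$min[2])
      hi <- stats::runif(1, env$max[1], env$max[2])
      niches[[id]] <- build_niche(id, c(lo, hi))
      traits <- rbind(traits, data.frame(
        taxon_id = id, elev_max_mean_m = hi,
        plant_height_m = stats::runif(1, band_heights[[gf]][1],
                                      band_heights[[gf]][2]),
        growth_form = gf, band = band))
    }
  }
  list(niches = niches, traits = traits)
}

#' Synthetic sedaDNA-like count table conditioned on simulated presence
#'
#' Emulates a processed metabarcoding count table whose taxon detections
#' track simulated catchment presence.  For each sample age the taxa
#' present (from the majority-vote series of a [smarc()] fit, evaluated at
#' the nearest model step) share the sample's reads multinomially according
#' to their detection weights; a false-detection rate `epsilon` diverts
#' that fraction of reads uniformly to absent taxa.  Sample read totals are
#' negative-binomial (over-dispersed); samples where no taxon is present
#' and `epsilon = 0` receive no reads and are dropped.
#'
#' @param fit A [smarc()] object covering the sample ages.
#' @param sample_ages Ages (cal yr BP) of the simulated samples.
#' @param reads_mean,reads_dispersion Negative-binomial mean and size of
#'   the per-sample read total (defaults 10000 and 20).
#' @param weights Named detection weights per taxon (default equal).
#' @param epsilon False-detection rate for absent taxa (default 0).
#' @param lake_id Label for the output table.
#' @param seed Integer seed.
#' @return A [count_table()] (possibly with fewer samples than ages, if
#'   read-less samples were dropped).
#' @export
make_proxy <- function(fit, sample_ages, reads_mean = 10000,
                       reads_dispersion = 20, weights = NULL, epsilon = 0,
                       lake_id = "synthetic", seed = 1) {
  stopifnot(inherits(fit, "smarc"))
  if (reads_mean <= 0) stop_config("reads_mean must be positive")
  if (epsilon < 0 || epsilon >= 1) stop_config("epsilon must be in [0, 1)")
  taxa <- fit$taxa
  weights <- weights %||% stats::setNames(rep(1, length(taxa)), taxa)
  set.seed(seed)
  counts <- matrix(0L, length(sample_ages), length(taxa),
                   dimnames = list(NULL, taxa))
  for (s in seq_along(sample_ages)) {
    step <- which.min(abs(fit$age_bp - sample_ages[s]))
    present <- vapply(taxa, function(tx) fit$majority[[tx]][step] == 1, TRUE)
    total <- stats::rnbinom(1, size = reads_dispersion, mu = reads_mean)
    if (total == 0) next
    n_false <- stats::rbinom(1, total, epsilon)
    n_true <- total - n_false
    if (any(present) && n_true > 0) {
      w <- weights[taxa[present]]
      counts[s, present] <- counts[s, present] +
        as.integer(stats::rmultinom(1, n_true, w / sum(w)))
    }
    if (any(!present) && n_false > 0) {
      counts[s, !present] <- counts[s, !present] +
        as.integer(stats::rmultinom(1, n_false,
                                    rep(1 / sum(!present), sum(!present))))
    }
  }
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop_input("no sample received any reads")
  count_table(counts[keep, , drop = FALSE], sample_ages[keep],
              lake_id = lake_id,
              sample_ids = sprintf("%s_%03d", lake_id, which(keep)))
}

#' Generate a complete paired-lake scenario
#'
#' Convenience wrapper producing everything a desk-scale study needs: a
#' steep-corridor and a gentle-corridor lake at the same elevation, a
#' shared stylised deglacial forcing, a taxon set spanning the three
#' elevation bands, terrain-mode ensemble simulations for both lakes, and
#' sedaDNA-like count tables conditioned on the simulated presence.
#'
#' @param n_lowland,n_mid,n_upland Taxon counts per band.
#' @param n_runs Ensemble size per lake.
#' @param sample_step Spacing of synthetic samples in years (default 500).
#' @param reads_mean,epsilon Passed to [make_proxy()].
#' @param seed Base seed.
#' @return A list with `forcing`, `profiles`, `taxa`, `fits` (terrain-mode
#'   [smarc()] objects per lake) and `proxies` ([count_table()]s per lake).
#' @export
make_scenario <- function(n_lowland = 4, n_mid = 4, n_upland = 4,
                          n_runs = 30, sample_step = 500,
                          reads_mean = 10000, epsilon = 0, seed = 1) {
  forcing <- make_forcing()
  profiles <- list(steep = make_profile("steep"),
                   gentle = make_profile("gentle"))
  taxa <- make_taxa(n_lowland, n_mid, n_upland, seed = seed)
  sample_ages <- seq(17975, 0, by = -sample_step)
  fits <- list(); proxies <- list()
  for (lk in names(profiles)) {
    cfg <- smarc_config(mode = "terrain", n_runs = n_runs,
                        seed = seed + 1000 * match(lk, names(profiles)))
    fits[[lk]] <- smarc(taxa$niches, profiles[[lk]], forcing, cfg)
    proxies[[lk]] <- make_proxy(fits[[lk]], sample_ages,
                                reads_mean = reads_mean, epsilon = epsilon,
                                lake_id = lk, seed = seed + 7)
  }
  list(forcing = forcing, profiles = profiles, taxa = taxa, fits = fits,
       proxies = proxies, seed = seed)
}

#' Write the files of a synthetic scenario
#'
#' Emits the same CSV/TSV schemas the readers consume: `forcing.csv`,
#' `profile_<lake>.csv`, `taxa.csv`, `traits.csv`, `counts_<lake>.tsv` and
#' a `scenario.txt` recording parameters.
#'
#' @param scenario A [make_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "forcing.csv")
  utils::write.csv(data.frame(age_bp = scenario$forcing$age_bp,
                              anomaly_c = scenario$forcing$anomaly_c),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  for (lk in names(scenario$profiles)) {
    pr <- scenario$profiles[[lk]]
    p <- file.path(dir, sprintf("profile_%s.csv", lk))
    utils::write.csv(data.frame(distance_m = pr$distance_m,
                                elevation_m = pr$elevation_m),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  niches <- scenario$taxa$niches
  p <- file.path(dir, "taxa.csv")
  utils::write.csv(data.frame(
    taxon_id = names(niches),
    species = paste0(names(niches), "_sp"),
    elev_min_m = vapply(niches, `[[`, 0, "elev_min"),
    elev_max_m = vapply(niches, `[[`, 0, "elev_max")),
    p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "traits.csv")
  utils::write.csv(scenario$taxa$traits[c("taxon_id", "elev_max_mean_m",
                                          "plant_height_m", "growth_form")],
                   p, row.names = FALSE)
  paths <- c(paths, p)
  for (lk in names(scenario$proxies)) {
    p <- file.path(dir, sprintf("counts_%s.tsv", lk))
    write_counts(scenario$proxies[[lk]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "scenario.txt")
  writeLines(sprintf("seed = %d", scenario$seed), p)
  paths <- c(paths, p)
  invisible(paths)
}
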