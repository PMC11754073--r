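#' Simulation configuration
#'
#' Collects all tunable parameters of the dispersal simulation.  Defaults
#' are the reference parameterisation: a 25-yr time step on a 250-m cell
#' grid, seed dispersal limited to 100 m/yr (10 cells per step) in
#' `"terrain"` mode, an 80% establishment probability combined with a 1%
#' chance of colonizing the lowest suitable position, colonization
#' probability multipliers of 2 (for 2-10 occupied cells) and 3 (for more
#' than 10), 30 ensemble runs, and an 18,000 cal yr BP output window after
#' a constant-forcing spin-up from 50,000 cal yr BP.
#'
#' @param mode `"terrain"` (dispersal limited along the river corridor) or
#'   `"elevation_only"` (no dispersal limitation: every suitable cell can be
#'   colonized each step).
#' @param dispersal_rate Maximum dispersal speed, m/yr (terrain mode).
#' @param time_step Simulation time step, yr; must match the forcing grid.
#' @param cell_size Cell size, m; must match the profile grid.
#' @param p_establish Establishment probability per step, also the per-cell
#'   colonization probability in elevation-only mode.
#' @param p_lowest Probability of colonizing the lowest suitable position
#'   given establishment; the two draws combine to `p_establish * p_lowest`
#'   per step while the taxon is absent.
#' @param mult_small,mult_large Colonization probability multipliers applied
#'   to the taxon's distributional breadth when 2-10, resp. more than 10,
#'   cells are occupied.
#' @param n_runs Ensemble size.
#' @param seed Base integer seed; run r uses `seed + r`.
#' @param output_start Oldest age (cal yr BP) of the reported presence
#'   window.
#' @param lapse Temperature lapse rate, degrees C per 100 m.
#' @param presence_rule `"gte"` counts the taxon as present in the catchment
#'   when its highest occupied elevation is at or above the lake elevation;
#'   `"gt"` requires strictly above.
#' @param bin_rule `"any"` marks a 1-ka bin present when any of its steps is
#'   present; `"majority"` requires more than half of the steps.
#' @param bin_width Bin width for presence binning, yr.
#' @param deterministic_advance If `TRUE`, a successful front advance always
#'   covers the maximum reachable distance instead of a uniform draw
#'   (useful for deterministic-limit checks).
#' @param p_advance Optional constant advance probability replacing the
#'   breadth-times-multiplier law in terrain mode (`NULL`, the default,
#'   keeps the breadth-based probability; 1 makes colonization certain).
#' @return An object of class `smarc_config` (a validated list).
#' @export
smarc_config <- function(mode = c("terrain", "elevation_only"),
                         dispersal_rate = 100, time_step = 25,
                         cell_size = 250, p_establish = 0.8,
                         p_lowest = 0.01, mult_small = 2, mult_large = 3,
                         n_runs = 30, seed = 1, output_start = 18000,
                         lapse = 0.55,
                         presence_rule = c("gte", "gt"),
                         bin_rule = c("any", "majority"),
                         bin_width = 1000,
                         deterministic_advance = FALSE,
                         p_advance = NULL) {
  mode <- match.arg(mode)
  presence_rule <- match.arg(presence_rule)
  bin_rule <- match.arg(bin_rule)
  for (p in c(p_establish = p_establish, p_lowest = p_lowest))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_config("probabilities must lie in [0, 1]")
  if (time_step <= 0 || cell_size <= 0)
    stop_config("time_step and cell_size must be positive")
  disp_cells <- dispersal_rate * time_step / cell_size
  if (disp_cells <= 0 || abs(disp_cells - round(disp_cells)) > 1e-9)
    stop_config(sprintf(
      "dispersal_rate * time_step / cell_size must be a positive integer (got %g)",
      disp_cells))
  if (n_runs < 1) stop_config("n_runs must be at least 1")
  if (mult_small < 0 || mult_large < 0)
    stop_config("multipliers must be non-negative")
  if (bin_width <= 0 || bin_width %% time_step != 0)
    stop_config("bin_width must be a positive multiple of time_step")
  if (!is.null(p_advance) && (!is.numeric(p_advance) || p_advance < 0 ||
                              p_advance > 1))
    stop_config("p_advance must be NULL or a probability in [0, 1]")
  structure(list(mode = mode, dispersal_rate = dispersal_rate,
                 time_step = time_step, cell_size = cell_size,
                 p_establish = p_establish, p_lowest = p_lowest,
                 mult_small = mult_small, mult_large = mult_large,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 output_start = output_start, lapse = lapse,
                 presence_rule = presence_rule, bin_rule = bin_rule,
                 bin_width = bin_width,
                 disp_cells = as.integer(round(disp_cells)),
                 deterministic_advance = isTRUE(deterministic_advance),
                 p_advance = p_advance),
            class = "smarc_config")
}

#' @export
print.smarc_config <- function(x, ...) {
  cat(sprintf(
    "SMARC config: %s mode, %g m/yr (%d cells/step), dt %g yr, cell %g m\n",
    x$mode, x$dispersal_rate, x$disp_cells, x$time_step, x$cell_size))
  cat(sprintf(
    "  p_establish %.3g x p_lowest %.3g; multipliers x%g (2-10 cells) / x%g (>10)\n",
    x$p_establish, x$p_lowest, x$mult_small, x$mult_large))
  cat(sprintf("  %d runs, seed %d, output from %g cal yr BP\n",
              x$n_runs, x$seed, x$output_start))
  invisible(x)
}

# Build a config from a named list (e.g. parsed from a key=value file),
# rejecting unknown keys by name.
config_from_list <- function(values) {
  known <- names(formals(smarc_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown))
    stop_config(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  do.call(smarc_config, values)
}

# --- single-step rules ------------------------------------------------------
# These operate on a logical occupancy vector `occ` over the profile cells.
# They are exported mainly so the stepping rules can be tested in isolation.

#' Clear occupied cells that fall outside the niche band
#'
#' Retreat and extinction act immediately: any occupied cell whose elevation
#' lies outside the current band is vacated this step, at both band edges.
#'
#' @param occ Logical occupancy vector over cells.
#' @param suitable Logical suitability vector (see [suitable_cells()]).
#' @return Updated occupancy vector.
#' @export
step_extinction <- function(occ, suitable) occ & suitable

#' Establishment attempt for an absent taxon
#'
#' While a taxon occupies no cell it can (re)establish: with probability
#' `p_establish` it establishes in the terrain at all, and with probability
#' `p_lowest` it colonizes the lowest-elevation suitable cell -- two
#' sequential Bernoulli draws, net `p_establish * p_lowest` per step.
#'
#' @param occ Logical occupancy vector (all `FALSE`).
#' @param suitable Logical suitability vector.
#' @param elevation Cell elevations (m).
#' @param p_establish,p_lowest Probabilities.
#' @return Updated occupancy vector (at most one new cell).
#' @export
step_establishment <- function(occ, suitable, elevation, p_establish,
                               p_lowest) {
  if (!any(suitable)) return(occ)
  if (stats::runif(1) < p_establish && stats::runif(1) < p_lowest) {
    idx <- which(suitable)
    occ[idx[which.min(elevation[idx])]] <- TRUE
  }
  occ
}

# Length of the run of TRUEs in x starting at position 1.
leading_run <- function(x) {
  if (!length(x) || !x[1]) return(0L)
  f <- which(!x)
  if (!length(f)) length(x) else f[1] - 1L
}

#' Terrain-mode colonization at the occupied fronts
#'
#' The occupied set spreads only at its two ends along the cell chain.  An
#' advance attempt at a front succeeds with probability
#' `min(1, breadth * multiplier)`, where the multiplier is 1 for a single
#' occupied cell, `mult_small` for 2-10 and `mult_large` for more than 10.
#' On success the front extends by `k` cells, `k` uniform on `{1, ..., K}`
#' with `K` the smaller of the dispersal cap and the contiguous run of
#' suitable unoccupied cells beyond the front, so a front never advances
#' more than `dispersal_rate * time_step` metres per step.
#'
#' @param occ Logical occupancy vector with at least one `TRUE`.
#' @param suitable Logical suitability vector.
#' @param breadth Taxon distributional breadth (see [build_niche()]).
#' @param cfg A [smarc_config()].
#' @return Updated occupancy vector.
#' @export
step_colonize_terrain <- function(occ, suitable, breadth, cfg) {
  n <- length(occ)
  occ_idx <- which(occ)
  n_occ <- length(occ_idx)
  mult <- if (n_occ <= 1) 1 else if (n_occ <= 10) cfg$mult_small else cfg$mult_large
  p_adv <- cfg$p_advance %||% min(1, breadth * mult)
  lo <- occ_idx[1]; hi <- occ_idx[n_occ]
  if (lo > 1) {
    avail <- leading_run(rev(suitable[seq_len(lo - 1)] & !occ[seq_len(lo - 1)]))
    K <- min(cfg$disp_cells, avail)
    if (K >= 1 && stats::runif(1) < p_adv) {
      k <- if (cfg$deterministic_advance) K else sample.int(K, 1)
      occ[(lo - k):(lo - 1)] <- TRUE
    }
  }
  if (hi < n) {
    avail <- leading_run(suitable[(hi + 1):n] & !occ[(hi + 1):n])
    K <- min(cfg$disp_cells, avail)
    if (K >= 1 && stats::runif(1) < p_adv) {
      k <- if (cfg$deterministic_advance) K else sample.int(K, 1)
      occ[(hi + 1):(hi + k)] <- TRUE
    }
  }
  occ
}

#' Elevation-only colonization
#'
#' Without dispersal limitation every suitable unoccupied cell is colonized
#' independently with probability `p_establish` this step.
#'
#' @inheritParams step_colonize_terrain
#' @param p_establish Per-cell colonization probability.
#' @return Updated occupancy vector.
#' @export
step_colonize_elevation_only <- function(occ, suitable, p_establish) {
  cand <- which(suitable & !occ)
  if (length(cand))
    occ[cand] <- stats::runif(length(cand)) < p_establish
  occ
}

#' Catchment presence of a taxon
#'
#' The taxon is recorded as present (1) when the upper limit of its
#' simulated range -- the highest occupied elevation -- reaches the lake
#' elevation, absent (0) otherwise.  A range exactly at the lake elevation
#' counts as present under the default `"gte"` rule.
#'
#' @param occ Logical occupancy vector.
#' @param elevation Cell elevations (m).
#' @param lake_elevation Lake elevation (m a.s.l.).
#' @param rule `"gte"` or `"gt"`.
#' @return 0 or 1.
#' @export
extract_presence <- function(occ, elevation, lake_elevation, rule = "gte") {
  if (!any(occ)) return(0L)
  top <- max(elevation[occ])
  as.integer(if (rule == "gt") top > lake_elevation else top >= lake_elevation)
}

# --- full runs --------------------------------------------------------------

# Precompute the per-step niche bands over the forcing grid.
band_series <- function(niche, forcing, lapse) {
  shift <- forcing$anomaly_c / lapse * 100
  list(lower = niche$elev_min + shift, upper = niche$elev_max + shift)
}

#' Run one stochastic realisation of the dispersal simulation
#'
#' Iterates over the forcing grid from the oldest age to present.  Each step
#' applies, in order: the niche band shift, extinction outside the band,
#' establishment (if the taxon is absent) or mode-specific colonization, and
#' catchment presence extraction.
#'
#' @param niche A [build_niche()] object.
#' @param profile A regular [river_profile()] (see [regrid_profile()]).
#' @param forcing A regular [climate_forcing()] (see [regrid_forcing()])
#'   whose step equals `config$time_step`.
#' @param config A [smarc_config()].
#' @param run_seed Integer seed for this run.
#' @param keep_history If `TRUE`, also return the full occupancy matrix
#'   (steps x cells) and the per-step front positions (memory permitting;
#'   intended for diagnostics on single runs).
#' @return A list with `age_bp` (output window, oldest first), `present`
#'   (0/1 per step), `first_arrival` (oldest output age with presence, or
#'   `NA`), `max_advance_cells` (largest single-step front advance observed
#'   over the whole simulation), and optionally `occupancy` and `fronts`.
#' @export
run_simulation <- function(niche, profile, forcing, config, run_seed,
                           keep_history = FALSE) {
  stopifnot(inherits(niche, "taxon_niche"), inherits(profile, "river_profile"),
            inherits(forcing, "climate_forcing"),
            inherits(config, "smarc_config"))
  if (is.na(forcing$step) || forcing$step != config$time_step)
    stop_config(sprintf("forcing step (%s) must equal config time_step (%g); regrid first",
                        forcing$step, config$time_step))
  if (is.na(profile$cell_size) || profile$cell_size != config$cell_size)
    stop_config(sprintf("profile cell size (%s) must equal config cell_size (%g); regrid first",
                        profile$cell_size, config$cell_size))
  set.seed(run_seed)
  elev <- profile$elevation_m
  n <- length(elev)
  bands <- band_series(niche, forcing, config$lapse)
  n_steps <- length(forcing$age_bp)
  occ <- logical(n)
  present <- integer(n_steps)
  max_adv <- 0L
  suit <- NULL
  prev_band <- c(NA_real_, NA_real_)
  if (keep_history) {
    occupancy <- matrix(FALSE, n_steps, n)
    fronts <- matrix(NA_integer_, n_steps, 4,
                     dimnames = list(NULL, c("lo_post_ext", "hi_post_ext",
                                             "lo", "hi")))
  }
  for (t in seq_len(n_steps)) {
    b <- c(bands$lower[t], bands$upper[t])
    if (!identical(b, prev_band)) {
      suit <- elev >= b[1] & elev <= b[2]
      prev_band <- b
    }
    occ <- step_extinction(occ, suit)
    post_ext <- if (any(occ)) range(which(occ)) else c(NA_integer_, NA_integer_)
    if (!any(occ)) {
      occ <- step_establishment(occ, suit, elev, config$p_establish,
                                config$p_lowest)
    } else if (config$mode == "terrain") {
      occ <- step_colonize_terrain(occ, suit, niche$breadth, config)
      now <- range(which(occ))
      if (!is.na(post_ext[1]))
        max_adv <- max(max_adv, post_ext[1] - now[1], now[2] - post_ext[2])
    } else {
      occ <- step_colonize_elevation_only(occ, suit, config$p_establish)
    }
    present[t] <- extract_presence(occ, elev, profile$lake_elevation,
                                   config$presence_rule)
    if (keep_history) {
      occupancy[t, ] <- occ
      fronts[t, ] <- c(post_ext,
                       if (any(occ)) range(which(occ)) else c(NA, NA))
    }
  }
  win <- forcing$age_bp <= config$output_start
  age <- forcing$age_bp[win]
  pres <- present[win]
  out <- list(age_bp = age, present = pres,
              first_arrival = if (any(pres == 1)) max(age[pres == 1]) else NA_real_,
              max_advance_cells = max_adv)
  if (keep_history) {
    out$occupancy <- occupancy[win, , drop = FALSE]
    out$fronts <- fronts
    out$all_ages <- forcing$age_bp
  }
  out
}

# Presence binning: half-open [k*width, (k+1)*width) bins in cal yr BP;
# only complete bins (width/step member steps) are kept.  Returns oldest
# bin first, with bin midpoints in cal yr BP.
bin_presence <- function(age_bp, present, width, step, rule = "any") {
  k <- floor(age_bp / width)
  counts <- table(k)
  full <- as.numeric(names(counts))[counts == width / step]
  full <- sort(full, decreasing = TRUE)
  val <- vapply(full, function(kk) {
    v <- present[k == kk]
    if (rule == "any") as.integer(any(v == 1)) else as.integer(mean(v) > 0.5)
  }, integer(1))
  list(bin_mid_bp = full * width + width / 2, bin_k = full, present = val)
}

#' Simulate taxon migration along a river corridor (SMARC)
#'
#' The central simulation interface.  For each taxon an ensemble of
#' `config$n_runs` independent stochastic runs is performed (run `r` is
#' seeded with `config$seed + r`), and the per-step catchment presence is
#' aggregated into an ensemble presence fraction, a majority-vote series
#' (present when more than half of the runs are present) and a binned
#' series on `config$bin_width`-yr bins.
#'
#' @param niche A single [build_niche()] object or a (named) list of them,
#'   e.g. from [read_taxa()] or [make_taxa()].
#' @param profile A regular [river_profile()].
#' @param forcing A regular, spin-up-padded [climate_forcing()].
#' @param config A [smarc_config()].
#' @return An object of class `smarc`: list with
#'   \describe{
#'     \item{taxa}{taxon ids}
#'     \item{age_bp}{output ages, oldest first}
#'     \item{presence}{per taxon, an `n_runs x n_steps` 0/1 matrix}
#'     \item{fraction}{per taxon, the ensemble presence fraction per step}
#'     \item{majority}{per taxon, the majority-vote 0/1 series}
#'     \item{bin_mid_bp}{midpoints (cal yr BP) of the complete presence bins}
#'     \item{binned}{bins x taxa 0/1 matrix of binned majority presence}
#'     \item{first_arrival}{taxa x runs matrix of first-presence ages}
#'     \item{max_advance_cells}{taxa x runs matrix of the largest
#'       single-step front advance}
#'     \item{config, lake_elevation}{inputs echoed back}
#'   }
#' @examples
#' prof <- make_profile("steep")
#' forc <- make_forcing()
#' ni <- build_niche("lowland_tree", c(3000, 4100))
#' fit <- smarc(ni, prof, forc, smarc_config(n_runs = 3, seed = 42))
#' fit
#' @export
smarc <- function(niche, profile, forcing, config = smarc_config()) {
  if (inherits(niche, "taxon_niche")) niche <- list(niche)
  if (!length(niche) || !all(vapply(niche, inherits, TRUE, "taxon_niche")))
    stop_input("niche must be a taxon_niche or a list of them")
  ids <- vapply(niche, `[[`, "", "taxon_id")
  names(niche) <- ids
  n_runs <- config$n_runs
  presence <- vector("list", length(ids)); names(presence) <- ids
  first_arr <- matrix(NA_real_, length(ids), n_runs,
                      dimnames = list(ids, NULL))
  max_adv <- matrix(0L, length(ids), n_runs, dimnames = list(ids, NULL))
  age <- NULL
  for (i in seq_along(ids)) {
    runs <- lapply(seq_len(n_runs), function(r)
      run_simulation(niche[[i]], profile, forcing, config,
                     run_seed = config$seed + r))
    age <- runs[[1]]$age_bp
    presence[[i]] <- do.call(rbind, lapply(runs, `[[`, "present"))
    first_arr[i, ] <- vapply(runs, `[[`, 0, "first_arrival")
    max_adv[i, ] <- vapply(runs, `[[`, 0L, "max_advance_cells")
  }
  fraction <- lapply(presence, colMeans)
  majority <- lapply(fraction, function(f) as.integer(f > 0.5))
  b1 <- bin_presence(age, majority[[1]], config$bin_width, config$time_step,
                     config$bin_rule)
  binned <- vapply(majority, function(m)
    bin_presence(age, m, config$bin_width, config$time_step,
                 config$bin_rule)$present,
    integer(length(b1$present)))
  binned <- matrix(binned, ncol = length(ids),
                   dimnames = list(NULL, ids))
  structure(list(taxa = ids, age_bp = age, presence = presence,
                 fraction = fraction, majority = majority,
                 bin_mid_bp = b1$bin_mid_bp, bin_k = b1$bin_k,
                 binned = binned, first_arrival = first_arr,
                 max_advance_cells = max_adv, config = config,
                 lake_elevation = profile$lake_elevation,
                 niche = niche, profile = profile, forcing = forcing,
                 call = match.call()),
            class = "smarc")
}

#' Bin each ensemble run's presence series separately
#'
#' @param fit A [smarc()] object.
#' @return Per taxon, an `n_runs x n_bins` 0/1 matrix.
#' @export
presence_bins_per_run <- function(fit) {
  stopifnot(inherits(fit, "smarc"))
  cfg <- fit$config
  lapply(fit$presence, function(P)
    t(apply(P, 1, function(p)
      bin_presence(fit$age_bp, p, cfg$bin_width, cfg$time_step,
                   cfg$bin_rule)$present)))
}

#' @export
print.smarc <- function(x, ...) {
  cat(sprintf("SMARC simulation: %d taxa, %d runs, %s mode\n",
              length(x$taxa), x$config$n_runs, x$config$mode))
  cat(sprintf("  window %g-%g cal yr BP (%d steps, %d complete %g-yr bins)\n",
              max(x$age_bp), min(x$age_bp), length(x$age_bp),
              length(x$bin_mid_bp), x$config$bin_width))
  cat(sprintf("  lake elevation %g m a.s.l.\n", x$lake_elevation))
  invisible(x)
}

#' @export
summary.smarc <- function(object, ...) {
  med_arr <- apply(object$first_arrival, 1, stats::median, na.rm = TRUE)
  d <- data.frame(
    taxon_id = object$taxa,
    breadth = vapply(object$niche, `[[`, 0, "breadth"),
    mean_presence = vapply(object$fraction, mean, 0),
    bins_present = colSums(object$binned),
    median_first_arrival = med_arr,
    row.names = NULL)
  class(d) <- c("summary.smarc", class(d))
  d
}

#' @export
plot.smarc <- function(x, taxa = x$taxa, ...) {
  age_ka <- x$age_bp / 1000
  fr <- do.call(cbind, x$fraction[taxa])
  graphics::matplot(age_ka, fr, type = "l", lty = 1,
                    xlim = rev(range(age_ka)),
                    xlab = "Age (cal ka BP)",
                    ylab = "Ensemble presence fraction", ...)
  graphics::legend("topleft", legend = taxa, lty = 1,
                   col = seq_along(taxa), bty = "n", cex = 0.7)
  invisible(x)
}

#' Re-draw ensemble runs from a fitted simulation
#'
#' Repeats the simulation with a fresh base seed, leaving all other inputs
#' unchanged.
#'
#' @param object A [smarc()] object.
#' @param nsim Number of runs in the new ensemble.
#' @param seed New base seed (default: previous seed + previous run count).
#' @param ... Unused.
#' @return A new `smarc` object.
#' @export
simulate.smarc <- function(object, nsim = object$config$n_runs,
                           seed = NULL, ...) {
  cfg <- object$config
  cfg$n_runs <- as.integer(nsim)
  cfg$seed <- as.integer(seed %||% (cfg$seed + object$config$n_runs))
  smarc(object$niche, object$profile, object$forcing, cfg)
}
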