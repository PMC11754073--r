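# Small, fast fixtures shared across test files.  Everything is built in
# code; nothing is read from disk except through explicit round-trip tests.

# A short deglacial-style forcing: 4 ka of history at 25-yr steps with a
# 1-ka spin-up margin, so engine unit tests run in milliseconds.
tiny_forcing <- function() {
  make_forcing(knots = cbind(age_bp = c(3000, 1500, 0),
                             anomaly_c = c(-4, 0, -1)),
               spinup_age = 5000, source_age = 4000)
}

# A 10-km corridor from a 4000-m lake down to 3200 m (41 cells).
tiny_profile <- function() {
  make_profile("custom", knots = cbind(c(0, 1e4), c(4000, 3200)))
}

tiny_config <- function(...) {
  args <- utils::modifyList(list(output_start = 3000, n_runs = 3, seed = 7),
                            list(...))
  do.call(smarc_config, args)
}

# Lowland-style niche whose band reaches the 4000-m lake only near
# anomaly 0.
tiny_lowland <- function() build_niche("lowland_tree", c(3200, 4100))

# Writes a complete miniature input set (forcing/profile/taxa CSVs) and
# returns the paths; used by the command-driver tests.
write_tiny_inputs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- tiny_forcing()
  forcing_path <- file.path(dir, "forcing.csv")
  utils::write.csv(data.frame(age_bp = f$age_bp, anomaly_c = f$anomaly_c),
                   forcing_path, row.names = FALSE)
  p <- tiny_profile()
  profile_path <- file.path(dir, "profile.csv")
  utils::write.csv(data.frame(distance_m = p$distance_m,
                              elevation_m = p$elevation_m),
                   profile_path, row.names = FALSE)
  taxa_path <- file.path(dir, "taxa.csv")
  utils::write.csv(data.frame(taxon_id = c("low_1", "low_1", "up_1"),
                              species = c("sp_a", "sp_b", "sp_c"),
                              elev_min_m = c(3200, 3400, 3800),
                              elev_max_m = c(4000, 4150, 4600)),
                   taxa_path, row.names = FALSE)
  list(forcing = forcing_path, profile = profile_path, taxa = taxa_path)
}

# Independent deterministic-limit oracle: replays the stepping rules as a
# set-valued recursion with all probabilities at 1 and no dispersal cap,
# using only the forcing, niche and profile (no engine code).
oracle_presence <- function(niche, profile, forcing, lapse = 0.55,
                            output_start = 18000) {
  elev <- profile$elevation_m
  shift <- forcing$anomaly_c / lapse * 100
  occ <- rep(FALSE, length(elev))
  present <- integer(length(forcing$age_bp))
  for (t in seq_along(forcing$age_bp)) {
    suit <- elev >= niche$elev_min + shift[t] & elev <= niche$elev_max + shift[t]
    occ <- occ & suit
    if (!any(occ)) {
      if (any(suit)) {
        idx <- which(suit)
        occ[idx[which.min(elev[idx])]] <- TRUE
      }
    } else {
      occ <- suit  # full suitable set colonized in one step
    }
    present[t] <- as.integer(any(occ) && max(elev[occ]) >= profile$lake_elevation)
  }
  win <- forcing$age_bp <= output_start
  list(age_bp = forcing$age_bp[win], present = present[win])
}
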