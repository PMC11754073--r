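test_that("config invariants are enforced before any stepping", {
  expect_s3_class(smarc_config(), "smarc_config")
  expect_equal(smarc_config()$disp_cells, 10L)
  expect_error(smarc_config(p_establish = 1.2), class = "smarc_config_error")
  # 15 m/yr x 25 yr / 250 m = 1.5 cells per step: not a whole number
  expect_error(smarc_config(dispersal_rate = 15), "positive integer",
               class = "smarc_config_error")
  expect_error(smarc_config(n_runs = 0), class = "smarc_config_error")
  expect_error(smarc_config(bin_width = 990), class = "smarc_config_error")
})

test_that("extinction immediately clears occupied cells outside the band", {
  occ <- c(TRUE, TRUE, TRUE)
  expect_equal(step_extinction(occ, c(FALSE, TRUE, TRUE)),
               c(FALSE, TRUE, TRUE))                     # top cell cleared
  expect_equal(step_extinction(occ, c(TRUE, TRUE, TRUE)), occ)  # identity
  expect_equal(step_extinction(occ, rep(FALSE, 3)), rep(FALSE, 3))
})

test_that("establishment occupies the lowest suitable cell with p_est x p_lowest", {
  elev <- c(4000, 3600, 3200)
  # degenerate probabilities: guaranteed at the lowest suitable cell
  occ <- step_establishment(rep(FALSE, 3), c(TRUE, TRUE, FALSE), elev, 1, 1)
  expect_equal(occ, c(FALSE, TRUE, FALSE))
  # no suitable cells: vacuous
  expect_equal(step_establishment(rep(FALSE, 3), rep(FALSE, 3), elev, 1, 1),
               rep(FALSE, 3))
  # empirical establishment frequency ~ 0.8 * 0.01 = 0.008
  set.seed(11)
  hits <- sum(replicate(10000, any(
    step_establishment(rep(FALSE, 3), rep(TRUE, 3), elev, 0.8, 0.01))))
  se <- sqrt(0.008 * 0.992 / 10000)
  expect_lt(abs(hits / 10000 - 0.008), 3 * se)
})

test_that("terrain colonization follows the breadth-multiplier rule", {
  cfg <- smarc_config(mode = "terrain")
  n <- 30
  suit <- rep(TRUE, n)
  # breadth 0: never advances beyond the establishment cell
  occ <- rep(FALSE, n); occ[15] <- TRUE
  set.seed(3)
  for (i in 1:50) expect_equal(sum(step_colonize_terrain(occ, suit, 0, cfg)), 1)

  # single occupied cell, breadth 0.5 -> multiplier 1, p_adv 0.5 per front
  set.seed(5)
  adv1 <- replicate(4000, {
    out <- step_colonize_terrain(occ, suit, 0.5, cfg)
    c(any(out[1:14]), any(out[16:30]))  # low/high front advanced?
  })
  expect_lt(abs(mean(adv1) - 0.5), 3 * sqrt(0.25 / 8000))

  # 5 occupied cells, breadth 0.5 -> p_adv = min(1, 0.5 * 2) = 1: always advances
  occ5 <- rep(FALSE, n); occ5[13:17] <- TRUE
  set.seed(6)
  for (i in 1:50) {
    out <- step_colonize_terrain(occ5, suit, 0.5, cfg)
    expect_true(any(out[1:12]) && any(out[18:30]))
  }
})

test_that("advance length is uniform on 1..K with K capped by suitable space", {
  cfg <- smarc_config(mode = "terrain")
  n <- 20
  # high front at cell 10; only 3 suitable unoccupied cells beyond it
  occ <- rep(FALSE, n); occ[1:10] <- TRUE
  suit <- rep(TRUE, n); suit[14:20] <- FALSE
  suit[1] <- FALSE  # block the low front so only the high front can move
  occ[1] <- FALSE
  set.seed(8)
  lens <- replicate(9000, {
    out <- step_colonize_terrain(occ, suit, 1, cfg)  # p_adv = 1
    sum(out) - sum(occ)
  })
  expect_true(all(lens %in% 1:3))
  tab <- table(factor(lens, levels = 1:3))
  expect_gt(stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value, 1e-3)
})

test_that("elevation-only colonization hits each suitable cell independently", {
  occ <- c(TRUE, rep(FALSE, 9))
  suit <- rep(TRUE, 10)
  expect_equal(step_colonize_elevation_only(occ, suit, 1), rep(TRUE, 10))
  expect_equal(step_colonize_elevation_only(occ, suit, 0), occ)
  set.seed(13)
  frac <- mean(replicate(2000, {
    out <- step_colonize_elevation_only(occ, suit, 0.8)
    mean(out[-1])
  }))
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / (2000 * 9)))
})

test_that("catchment presence keys on the highest occupied elevation", {
  elev <- c(4100, 3800, 3500)
  expect_equal(extract_presence(c(TRUE, TRUE, FALSE), elev, 4000), 1L)
  expect_equal(extract_presence(rep(FALSE, 3), elev, 4000), 0L)
  # documented tie-break: exactly at lake elevation counts as present
  expect_equal(extract_presence(c(FALSE, TRUE, FALSE), c(4100, 4000, 3500),
                                4000), 1L)
  expect_equal(extract_presence(c(FALSE, TRUE, FALSE), c(4100, 4000, 3500),
                                4000, rule = "gt"), 0L)
})

test_that("runs are reproducible by seed and never outrun the dispersal cap", {
  forc <- tiny_forcing(); prof <- tiny_profile(); ni <- tiny_lowland()
  cfg <- tiny_config(mode = "terrain")
  r1 <- run_simulation(ni, prof, forc, cfg, run_seed = 5, keep_history = TRUE)
  r2 <- run_simulation(ni, prof, forc, cfg, run_seed = 5, keep_history = TRUE)
  expect_identical(r1$occupancy, r2$occupancy)
  r3 <- run_simulation(ni, prof, forc, cfg, run_seed = 6, keep_history = TRUE)
  expect_false(identical(r1$occupancy, r3$occupancy))

  # front-speed bound: colonization moves each front <= disp_cells per step
  fr <- r1$fronts
  ok <- is.na(fr[, "lo_post_ext"]) |
    (fr[, "lo_post_ext"] - fr[, "lo"] <= cfg$disp_cells &
     fr[, "hi"] - fr[, "hi_post_ext"] <= cfg$disp_cells)
  expect_true(all(ok))
  expect_lte(max(r1$max_advance_cells), cfg$disp_cells)
})

test_that("occupancy stays inside the suitable band after every full step", {
  forc <- tiny_forcing(); prof <- tiny_profile(); ni <- tiny_lowland()
  for (mode in c("terrain", "elevation_only")) {
    r <- run_simulation(ni, prof, forc, tiny_config(mode = mode),
                        run_seed = 2, keep_history = TRUE)
    shift <- forcing_at(forc, r$age_bp) / 0.55 * 100
    for (t in seq_along(r$age_bp)) {
      suit <- prof$elevation_m >= ni$elev_min + shift[t] &
              prof$elevation_m <= ni$elev_max + shift[t]
      expect_true(all(suit[r$occupancy[t, ]]))
    }
  }
})

test_that("terrain-mode occupancy is a contiguous interval of cells", {
  r <- run_simulation(tiny_lowland(), tiny_profile(), tiny_forcing(),
                      tiny_config(mode = "terrain"), run_seed = 9,
                      keep_history = TRUE)
  for (t in seq_len(nrow(r$occupancy))) {
    idx <- which(r$occupancy[t, ])
    if (length(idx) > 1) expect_equal(idx, idx[1]:idx[length(idx)])
  }
})

test_that("a taxon whose band never reaches the lake is never present", {
  # band top 3500 m, lake 4000 m, anomalies <= 0: upper limit always < lake
  ni <- build_niche("deep_lowland", c(3000, 3500))
  fit <- smarc(ni, tiny_profile(), tiny_forcing(), tiny_config())
  expect_true(all(fit$presence[[1]] == 0))
})

test_that("deterministic limit reproduces the closed-form suitability oracle", {
  forc <- tiny_forcing(); prof <- tiny_profile()
  ni <- tiny_lowland()
  orc <- oracle_presence(ni, prof, forc, output_start = 3000)
  for (mode in c("terrain", "elevation_only")) {
    cfg <- tiny_config(mode = mode, p_establish = 1, p_lowest = 1,
                       p_advance = 1, dispersal_rate = 10000,
                       deterministic_advance = TRUE)
    r <- run_simulation(ni, prof, forc, cfg, run_seed = 1)
    expect_equal(r$present, orc$present)
  }
})

test_that("ensembles aggregate by majority vote and any-step binning", {
  forc <- tiny_forcing(); prof <- tiny_profile(); ni <- tiny_lowland()
  fit1 <- smarc(ni, prof, forc, tiny_config(n_runs = 1))
  expect_equal(fit1$majority[[1]], as.integer(fit1$presence[[1]][1, ]))

  # all-deterministic config: every run identical
  cfgd <- tiny_config(n_runs = 5, p_establish = 1, p_lowest = 1,
                      mode = "elevation_only")
  fitd <- smarc(ni, prof, forc, cfgd)
  expect_true(all(apply(fitd$presence[[1]], 2,
                        function(col) length(unique(col)) == 1)))

  fit <- smarc(ni, prof, forc, tiny_config(n_runs = 5))
  fr <- fit$fraction[[1]]
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(fit$majority[[1]], as.integer(fr > 0.5))

  # any-step bin rule: bin present iff any member step present
  b <- fit$binned[, 1]
  k <- floor(fit$age_bp / 1000)
  for (i in seq_along(fit$bin_k)) {
    expect_equal(b[i],
                 as.integer(any(fit$majority[[1]][k == fit$bin_k[i]] == 1)))
  }
})

test_that("simulate() re-draws the ensemble with a fresh seed", {
  fit <- smarc(tiny_lowland(), tiny_profile(), tiny_forcing(),
               tiny_config(n_runs = 2))
  fit2 <- simulate(fit, nsim = 2)
  expect_s3_class(fit2, "smarc")
  expect_equal(fit2$config$seed, fit$config$seed + 2L)
  expect_equal(dim(fit2$presence[[1]]), dim(fit$presence[[1]]))
  s <- summary(fit)
  expect_true(all(c("breadth", "mean_presence") %in% names(s)))
})
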