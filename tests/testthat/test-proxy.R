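make_counts <- function(m, ages, lake = "lk") {
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  count_table(m, ages, lake_id = lake)
}

test_that("rarefaction conserves depth and matches hypergeometric expectation", {
  # single-taxon sample: the full depth lands on that taxon
  t1 <- make_counts(matrix(c(10000, 0), 1, 2), ages = 500)
  r1 <- rarefy_counts(t1, depth = 6652, reps = 5, seed = 1)
  expect_equal(unname(r1$counts[1, ]), c(6652, 0))

  # sample total exactly at depth: every replicate equals the original
  t2 <- make_counts(matrix(c(4000, 2652), 1, 2), ages = 500)
  r2 <- rarefy_counts(t2, depth = 6652, reps = 3, seed = 1,
                      return_replicates = TRUE)
  for (rep in r2$replicates)
    expect_equal(unname(rep[1, ]), c(4000, 2652))

  # every replicate row sums exactly to the depth
  t3 <- make_counts(matrix(c(7000, 3000, 8000, 4000), 2, 2), ages = c(500, 1500))
  r3 <- rarefy_counts(t3, depth = 6652, reps = 20, seed = 2,
                      return_replicates = TRUE)
  for (rep in r3$replicates) expect_true(all(rowSums(rep) == 6652))

  # unbiasedness: mean of 7000/3000 split within 3 SE of depth * p
  reps <- 400
  r4 <- rarefy_counts(make_counts(matrix(c(7000, 3000), 1, 2), 500),
                      depth = 6652, reps = reps, seed = 3)
  N <- 10000; n <- 6652; p <- 0.7
  var_h <- n * p * (1 - p) * (N - n) / (N - 1)
  se <- sqrt(var_h / reps)
  expect_lt(abs(r4$counts[1, 1] - n * p), 3 * se)

  # samples below depth are dropped with a warning
  t5 <- make_counts(matrix(c(7000, 3000, 100, 50), 2, 2, byrow = TRUE),
                    ages = c(500, 1500))
  expect_warning(r5 <- rarefy_counts(t5, depth = 6652, reps = 2),
                 "below rarefaction depth")
  expect_equal(nrow(r5$counts), 1)
  expect_error(rarefy_counts(t5, depth = -1), class = "smarc_config_error")
})

test_that("taxon filter applies frequency and abundance criteria, in any order", {
  # 4 samples x 4 taxa; grand total 20000
  m <- rbind(c(4000, 4, 0, 2), c(4000, 3, 0, 0), c(3990, 0, 4, 0),
             c(3990, 5, 3, 1))
  ct <- make_counts(m, ages = c(500, 1500, 2500, 3500))
  # t1: 4 samples, 79.8% -> kept; t2: 3 samples, 15/20000 = 0.075% -> kept
  # t3: 2 samples -> dropped by frequency; t4: 3/20000 = 0.015% -> dropped
  f <- filter_taxa(ct, min_samples = 3, min_rel_abundance = 3e-4)
  expect_equal(colnames(f$counts), c("t1", "t2"))

  # brute-force oracle: evaluate both criteria exhaustively per taxon
  keep_oracle <- vapply(seq_len(ncol(m)), function(j) {
    sum(m[, j] > 0) >= 3 && sum(m[, j]) / sum(m) > 3e-4
  }, TRUE)
  expect_equal(colnames(f$counts), colnames(ct$counts)[keep_oracle])

  # order of criteria does not matter: filter never widens the set
  f_freq_first <- filter_taxa(filter_taxa(ct, 3, 0), 0, 3e-4)
  expect_equal(colnames(f_freq_first$counts), colnames(f$counts))

  expect_error(filter_taxa(ct, min_samples = 10),
               class = "smarc_input_error")
})

test_that("age binning is half-open with per-bin means", {
  m <- rbind(c(10, 0), c(30, 2), c(5, 5))
  ct <- make_counts(m, ages = c(14100, 14900, 14000))
  b <- bin_by_age(ct, 1000)
  expect_equal(b$bin_k, 14)  # all three samples in the 14-15 ka bin
  expect_equal(unname(b$values[1, ]), c(15, 7 / 3))
  expect_equal(b$bin_mid_bp, 14500)

  # single sample per bin: values pass through
  ct2 <- make_counts(m, ages = c(2500, 1500, 500))
  b2 <- bin_by_age(ct2, 1000)
  expect_equal(b2$bin_k, c(2, 1, 0))
  expect_equal(unname(b2$values), m)
})

test_that("Box-Cox-chord gives unit-norm rows and handles zeros", {
  # closed form: (0, e-1, e-1) -> log1p (0,1,1) -> chord (0, 1/sqrt2, 1/sqrt2)
  x <- rbind(c(0, exp(1) - 1, exp(1) - 1))
  expect_equal(unname(boxcox_chord(x)[1, ]), c(0, 1, 1) / sqrt(2))

  # all-zero rows stay zero
  expect_equal(unname(boxcox_chord(rbind(c(0, 0, 0)))[1, ]), c(0, 0, 0))

  # random counts: every non-zero row has norm 1
  set.seed(4)
  m <- matrix(rpois(9, 3), 3, 3)
  norms <- sqrt(rowSums(boxcox_chord(m)^2))
  expect_equal(norms[rowSums(m) > 0], rep(1, sum(rowSums(m) > 0)),
               tolerance = 1e-12)

  # the chord step is idempotent (exponent 1 = plain chord scaling)
  once <- boxcox_chord(m, exponent = 1)
  expect_equal(boxcox_chord(once, exponent = 1), once, tolerance = 1e-12)

  expect_error(boxcox_chord(rbind(c(-1, 2))), class = "smarc_input_error")
})

test_that("presence binarization respects the threshold", {
  m <- rbind(c(0, 0.4, 0.6))
  expect_equal(unname(to_presence(m)[1, ]), c(0, 1, 1))
  expect_equal(unname(to_presence(m, threshold = 0.5)[1, ]), c(0, 0, 1))
})

test_that("grouped richness partitions total richness by elevation band", {
  traits <- data.frame(
    taxon_id = paste0("t", 1:5),
    elev_max_mean_m = c(3500, 3900, 4400, 4900, 5200),
    plant_height_m = c(20, 5, 1, 0.1, 0.05),
    growth_form = c("tree", "shrub", "forb", "cushion_rosette",
                    "cushion_rosette"))
  pres <- rbind(rep(1, 5), c(1, 1, 0, 0, 1), rep(0, 5))
  colnames(pres) <- traits$taxon_id
  rownames(pres) <- c(17, 16, 15)
  r <- group_richness(pres, traits)
  # hand tally: lowland {t1 3500, t2 3900}, mid {t3 4400},
  # upland {t4 4900, t5 5200}
  expect_equal(r$lowland, c(2, 2, 0))
  expect_equal(r$mid, c(1, 0, 0))
  expect_equal(r$upland, c(2, 1, 0))
  expect_equal(r$total, unname(rowSums(pres)))
  expect_equal(r$lowland + r$mid + r$upland, r$total)

  # unknown taxon is skipped and reported
  pres2 <- cbind(pres, mystery = c(1, 1, 1))
  r2 <- group_richness(pres2, traits)
  expect_equal(attr(r2, "skipped_taxa"), "mystery")
  expect_equal(r2$total, r$total)
})

test_that("community trait mean averages present taxa, NA for empty bins", {
  traits <- data.frame(taxon_id = c("a", "b", "c", "d"),
                       elev_max_mean_m = c(4000, 4200, 4500, 5000),
                       plant_height_m = c(1, 3, 10, 0.1),
                       growth_form = rep("forb", 4))
  pres <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 0),
                c(1, 1, 1, 1))
  colnames(pres) <- traits$taxon_id
  cm <- community_trait_mean(pres, traits, "plant_height_m")
  expect_equal(cm, c(2, 10, NA, mean(c(1, 3, 10, 0.1))))
  expect_error(community_trait_mean(pres, traits, "bark_thickness"),
               class = "smarc_input_error")
})

test_that("count tables round-trip through TSV", {
  m <- matrix(c(5000, 2000, 1500, 6000, 500, 3000), 2, 3)
  ct <- make_counts(m, ages = c(1200, 3400), lake = "testlake")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(ct, path)
  back <- read_counts(path)
  expect_equal(back$counts, ct$counts)
  expect_equal(back$sample_ages, ct$sample_ages)
  expect_equal(back$lake_id, "testlake")
})
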