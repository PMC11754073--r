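#' Simple matching coefficient of two binary series
#'
#' The fraction of aligned positions at which the two series agree,
#' counting both 1-1 and 0-0 matches.
#'
#' @param a,b Binary (0/1 or logical) vectors of equal length.
#' @return A fraction in `[0, 1]`.
#' @export
smc <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop_input(sprintf("series lengths differ (%d vs %d)", length(a), length(b)))
  if (!length(a)) stop_input("series must have length >= 1")
  mean(a == b)
}

# All permutations of seq_len(n) as an n! x n matrix (n <= 8).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation test for the simple matching coefficient
#'
#' Tests whether the observed agreement between two aligned binary series
#' exceeds what random time-ordering would produce.  The null distribution
#' is built by permuting the time order of `b` (free permutation); the
#' p-value is `(1 + #\{SMC_perm >= SMC_obs\}) / (n_perm + 1)`.  For series
#' of length 8 or fewer, all permutations are enumerated and the p-value is
#' exact (`#\{SMC_perm >= SMC_obs\} / n!`, which includes the identity
#' permutation and is therefore positive).  If `b` is constant every
#' permutation leaves it unchanged and the p-value is 1 (with a message).
#'
#' @param a,b Binary vectors of equal length (`a` typically the proxy
#'   series, `b` the simulated series being permuted).
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates when `length(b) <= 8`.
#' @return A list of class `smc_test`: `smc`, `p_value`, `n_bins`,
#'   `method` (`"exact"` or `"permutation"`), `n_perm`.
#' @export
smc_test <- function(a, b, n_perm = 999, seed = 1, exact = NULL) {
  obs <- smc(a, b)
  a <- as.integer(a); b <- as.integer(b)
  n <- length(b)
  if (length(unique(b)) == 1) {
    message("constant series: all permutations identical, p = 1")
    return(structure(list(smc = obs, p_value = 1, n_bins = n,
                          method = "degenerate", n_perm = 0L),
                     class = "smc_test"))
  }
  use_exact <- exact %||% (n <= 8)
  if (use_exact) {
    P <- all_perms(n)
    stat <- rowMeans(matrix(b[P], nrow(P), n) == matrix(a, nrow(P), n,
                                                        byrow = TRUE))
    p <- mean(stat >= obs - 1e-12)
    method <- "exact"; n_perm <- nrow(P)
  } else {
    set.seed(seed)
    stat <- vapply(seq_len(n_perm), function(i) mean(a == b[sample.int(n)]),
                   0)
    p <- (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
    method <- "permutation"
  }
  structure(list(smc = obs, p_value = p, n_bins = n, method = method,
                 n_perm = n_perm),
            class = "smc_test")
}

#' @export
print.smc_test <- function(x, ...) {
  cat(sprintf("SMC = %.4f over %d bins, p = %.4g (%s, %d permutations)\n",
              x$smc, x$n_bins, x$p_value, x$method, x$n_perm))
  invisible(x)
}

#' Joint principal component analysis of community trajectories
#'
#' Stacks the (transformed) bins x taxa matrices of two or more lakes --
#' which must share an identical taxon set -- into one matrix, centers each
#' column (no variance scaling), and extracts principal components, so both
#' lakes' time slices live in the same ordination space.  Explained
#' variance fractions are eigenvalues of the covariance matrix over their
#' sum.
#'
#' @param mats Named list (by lake) of numeric bins x taxa matrices or
#'   `binned_table`s sharing the same columns, rows ordered old to young.
#' @param transform `"boxcox_chord"` applies [boxcox_chord()] to each
#'   matrix before stacking (so binary simulation output and proxy
#'   compositions share the same geometry); `"none"` uses the matrices as
#'   given.
#' @return An object of class `trajectory_pca`: `scores` (rows x PCs),
#'   `explained_variance`, `loadings`, `lake` (row lake ids), `bin_mid_bp`
#'   (row ages when available), `transform`.
#' @export
joint_pca <- function(mats, transform = c("none", "boxcox_chord")) {
  transform <- match.arg(transform)
  if (!is.list(mats) || length(mats) < 1) stop_input("mats must be a list")
  ages <- lapply(mats, function(m)
    if (inherits(m, "binned_table")) m$bin_mid_bp else
      suppressWarnings(as.numeric(rownames(as.matrix(m)))))
  mats <- lapply(mats, function(m)
    if (inherits(m, "binned_table")) m$values else as.matrix(m))
  cols <- lapply(mats, colnames)
  if (length(mats) > 1 &&
      !all(vapply(cols[-1], identical, TRUE, cols[[1]])))
    stop_input("all matrices must share an identical taxon set")
  if (transform == "boxcox_chord") mats <- lapply(mats, boxcox_chord)
  x <- do.call(rbind, mats)
  if (nrow(x) < 3) stop_input("joint PCA needs at least 3 rows")
  lake <- rep(names(mats) %||% paste0("m", seq_along(mats)),
              vapply(mats, nrow, 0L))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, explained_variance = ev,
                 loadings = pc$rotation, lake = lake,
                 bin_mid_bp = unlist(ages, use.names = FALSE),
                 transform = transform),
            class = "trajectory_pca")
}

#' @export
print.trajectory_pca <- function(x, ...) {
  cat(sprintf("Joint trajectory PCA: %d time slices (%s), %d taxa\n",
              nrow(x$scores), paste(unique(x$lake), collapse = " + "),
              nrow(x$loadings)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance (transform: %s)\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2],
              x$transform))
  invisible(x)
}

#' @export
plot.trajectory_pca <- function(x, ...) {
  lakes <- unique(x$lake)
  cols <- seq_along(lakes)
  graphics::plot(x$scores[, 1], x$scores[, 2], type = "n",
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 ...)
  for (i in seq_along(lakes)) {
    s <- x$scores[x$lake == lakes[i], 1:2, drop = FALSE]
    graphics::lines(s, col = cols[i])
    graphics::points(s, col = cols[i], pch = 16, cex = 0.6)
  }
  graphics::legend("topright", legend = lakes, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Trajectory segment lengths
#'
#' Euclidean distances between consecutive time slices of one lake's
#' trajectory in the PC1-PC2 plane (or the full score space with
#' `plane = FALSE`); a measure of between-step compositional change.
#'
#' @param traj A [joint_pca()] result.
#' @param lake_id Which lake's trajectory to measure.
#' @param plane Use only PC1-PC2 (default) or all components.
#' @return Numeric vector of `n_bins - 1` segment lengths, oldest pair
#'   first.
#' @export
trajectory_segments <- function(traj, lake_id, plane = TRUE) {
  stopifnot(inherits(traj, "trajectory_pca"))
  s <- traj$scores[traj$lake == lake_id, , drop = FALSE]
  if (nrow(s) < 2) stop_input("need at least 2 bins for segment lengths")
  if (plane) s <- s[, 1:2, drop = FALSE]
  sqrt(rowSums(diff(s)^2))
}

#' Pearson correlation between proxy and simulated trajectories
#'
#' Correlates either the PC1 scores or the segment lengths of the same
#' lake's trajectory in two ordinations (proxy vs simulation), with the
#' usual two-sided t-test on `n - 2` degrees of freedom.
#'
#' @param proxy,sim [joint_pca()] results over aligned bins.
#' @param what `"pc1_scores"` or `"segments"`.
#' @param lake_id Lake to compare.
#' @return `htest` object from [stats::cor.test()].
#' @export
trajectory_correlation <- function(proxy, sim,
                                   what = c("pc1_scores", "segments"),
                                   lake_id) {
  what <- match.arg(what)
  get <- function(tr) switch(what,
    pc1_scores = tr$scores[tr$lake == lake_id, 1],
    segments = trajectory_segments(tr, lake_id))
  x <- get(proxy); y <- get(sim)
  if (length(x) != length(y))
    stop_input(sprintf("bin/segment counts differ (%d vs %d); align the windows",
                       length(x), length(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("zero variance in a trajectory; correlation undefined")
  stats::cor.test(x, y, method = "pearson")
}

#' Per-taxon model-proxy agreement for one simulation
#'
#' Aligns the simulation's binned presence series with the proxy's binned
#' presence matrix on their common bins and computes the simple matching
#' coefficient and permutation p-value per taxon.
#'
#' @param fit A [smarc()] object.
#' @param proxy_presence A `binned_table` of 0/1 proxy presences (see
#'   [to_presence()]) or a bins x taxa 0/1 matrix with bin indices as row
#'   names.
#' @param n_perm,seed Passed to [smc_test()].
#' @param per_run If `TRUE`, additionally report the mean over per-run SMC
#'   values instead of relying only on the majority-vote series.
#' @return A data.frame of class `smarc_comparison` with columns
#'   `taxon_id`, `mode`, `smc`, `p_value`, `n_bins` (and `smc_per_run_mean`
#'   if requested).
#' @export
compare_presence <- function(fit, proxy_presence, n_perm = 999, seed = 1,
                             per_run = FALSE) {
  stopifnot(inherits(fit, "smarc"))
  if (inherits(proxy_presence, "binned_table")) {
    pk <- proxy_presence$bin_k
    pm <- proxy_presence$values
  } else {
    pm <- as.matrix(proxy_presence)
    pk <- as.numeric(rownames(pm))
  }
  common <- intersect(fit$bin_k, pk)
  if (!length(common))
    stop_input(sprintf(
      "no overlapping bins: simulation covers k = %s..%s, proxy k = %s..%s",
      min(fit$bin_k), max(fit$bin_k), min(pk), max(pk)))
  common <- sort(common, decreasing = TRUE)
  taxa <- intersect(fit$taxa, colnames(pm))
  if (!length(taxa)) stop_input("no shared taxa between simulation and proxy")
  si <- match(common, fit$bin_k)
  pi <- match(common, pk)
  run_bins <- if (per_run) presence_bins_per_run(fit)
  rows <- lapply(taxa, function(tx) {
    tst <- smc_test(pm[pi, tx], fit$binned[si, tx], n_perm = n_perm,
                    seed = seed)
    r <- data.frame(taxon_id = tx, mode = fit$config$mode, smc = tst$smc,
                    p_value = tst$p_value, n_bins = length(common))
    if (per_run)
      r$smc_per_run_mean <- mean(apply(run_bins[[tx]][, si, drop = FALSE], 1,
                                       smc, b = pm[pi, tx]))
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("smarc_comparison", class(out))
  attr(out, "bin_k") <- common
  out
}

#' Contrast terrain-mode and elevation-only agreement per taxon
#'
#' For each taxon evaluated in both modes, the change in simple matching
#' coefficient `delta_smc = smc_terrain - smc_elevation_only` is reported
#' together with the percentage of taxa that improved, worsened or tied
#' under the terrain mode, overall and (when a trait table with
#' `growth_form` is supplied) per growth form.
#'
#' @param terrain,elevation_only [compare_presence()] results for the two
#'   modes over identical taxa and bins.
#' @param traits Optional trait data.frame with `taxon_id` and
#'   `growth_form`.
#' @return A list of class `mode_contrast`: `per_taxon` data.frame,
#'   `summary` (percentages), and `by_growth_form` when traits are given.
#' @export
compare_modes <- function(terrain, elevation_only, traits = NULL) {
  m <- merge(terrain[c("taxon_id", "smc", "n_bins")],
             elevation_only[c("taxon_id", "smc")],
             by = "taxon_id", suffixes = c("_terrain", "_elevation_only"))
  if (!nrow(m)) stop_input("no shared taxa between the two mode results")
  m$delta_smc <- m$smc_terrain - m$smc_elevation_only
  cls <- function(d) c(improved = mean(d > 0), worsened = mean(d < 0),
                       tied = mean(d == 0)) * 100
  out <- list(per_taxon = m, summary = cls(m$delta_smc))
  if (!is.null(traits)) {
    gf <- traits$growth_form[match(m$taxon_id, traits$taxon_id)]
    out$by_growth_form <- t(sapply(split(m$delta_smc, gf), cls))
  }
  class(out) <- "mode_contrast"
  out
}

#' @export
print.mode_contrast <- function(x, ...) {
  cat(sprintf("Terrain vs elevation-only: %d taxa; %.1f%% improved, %.1f%% worsened, %.1f%% tied\n",
              nrow(x$per_taxon), x$summary["improved"], x$summary["worsened"],
              x$summary["tied"]))
  invisible(x)
}
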