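#' sedaDNA count table
#'
#' A samples x taxa matrix of sequence read counts with per-sample ages and
#' a lake identifier.  Values are non-negative; retained samples must have a
#' positive read total.  After rarefaction the values are real-valued means
#' over rarefaction replicates.
#'
#' @param counts Numeric samples x taxa matrix (column names = taxon ids).
#' @param sample_ages Ages in cal yr BP, one per row.
#' @param lake_id Single lake identifier.
#' @param sample_ids Row labels; default `S1, S2, ...`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_ages, lake_id = "lake",
                        sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop_input("count table needs taxon ids as column names")
  if (nrow(counts) != length(sample_ages))
    stop_input("one sample age per count-table row is required")
  if (anyNA(counts) || any(counts < 0))
    stop_input("counts must be non-negative and non-missing")
  if (anyNA(sample_ages) || any(!is.finite(sample_ages)))
    stop_input("sample ages must be finite")
  if (any(rowSums(counts) <= 0))
    stop_input("samples with zero total reads must be dropped before construction")
  rownames(counts) <- sample_ids %||% rownames(counts) %||%
    paste0("S", seq_len(nrow(counts)))
  structure(list(counts = counts, sample_ages = as.numeric(sample_ages),
                 lake_id = lake_id),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("sedaDNA count table '%s': %d samples x %d taxa, %g-%g cal yr BP\n",
              x$lake_id, nrow(x$counts), ncol(x$counts),
              max(x$sample_ages), min(x$sample_ages)))
  cat(sprintf("  read totals: %g-%g (median %g)\n",
              min(rowSums(x$counts)), max(rowSums(x$counts)),
              stats::median(rowSums(x$counts))))
  invisible(x)
}

#' Read a sedaDNA count table (TSV)
#'
#' Expects a tab-separated table whose first columns are
#' `sample_id`, `age_bp`, `lake_id`, followed by one integer column per
#' taxon.
#'
#' @param path Path to the TSV file.
#' @return A [count_table()] (one lake per file).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_bp", "lake_id")
  if (!all(need %in% names(d)))
    stop_input(sprintf("%s: first columns must be %s", path,
                       paste(need, collapse = ", ")))
  taxa <- setdiff(names(d), need)
  if (!length(taxa)) stop_input(sprintf("%s: no taxon columns", path))
  m <- as.matrix(d[taxa])
  storage.mode(m) <- "double"
  count_table(m, d$age_bp, lake_id = unique(d$lake_id)[1],
              sample_ids = d$sample_id)
}

#' Write a count table as TSV
#'
#' @param t A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(t, path) {
  stopifnot(inherits(t, "count_table"))
  d <- data.frame(sample_id = rownames(t$counts), age_bp = t$sample_ages,
                  lake_id = t$lake_id, t$counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to a common read depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads,
#' `reps` times (via [vegan::rrarefy()]); the returned table holds the
#' per-cell mean over replicates, so values are real numbers whose row sums
#' equal `depth`.  Samples whose total is below `depth` cannot be
#' subsampled and are dropped with a warning.
#'
#' @param t A [count_table()] of integer counts.
#' @param depth Target read depth (default 6652, a typical minimum sample
#'   total in sedaDNA metabarcoding datasets).
#' @param reps Number of rarefaction replicates (default 100).
#' @param seed Integer seed.
#' @param return_replicates If `TRUE`, also return the list of replicate
#'   matrices (integer, each row summing to `depth`).
#' @return A rarefied [count_table()]; with `return_replicates = TRUE`, a
#'   list `list(mean = count_table, replicates = list)`.
#' @export
rarefy_counts <- function(t, depth = 6652, reps = 100, seed = 1,
                          return_replicates = FALSE) {
  stopifnot(inherits(t, "count_table"))
  if (!is.numeric(depth) || depth <= 0) stop_config("depth must be positive")
  if (reps < 1) stop_config("reps must be at least 1")
  totals <- rowSums(t$counts)
  keep <- totals >= depth
  if (!any(keep)) stop_input("all samples fall below the rarefaction depth")
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) below rarefaction depth %g: %s",
                    sum(!keep), depth,
                    paste(rownames(t$counts)[!keep], collapse = ", ")))
  m <- t$counts[keep, , drop = FALSE]
  set.seed(seed)
  acc <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  replicates <- if (return_replicates) vector("list", reps)
  # vegan heuristically warns when counts look large; ours are real counts
  quiet_rrarefy <- function(x, d) withCallingHandlers(
    vegan::rrarefy(x, d),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  for (r in seq_len(reps)) {
    rep_r <- quiet_rrarefy(m, depth)
    acc <- acc + rep_r
    if (return_replicates) replicates[[r]] <- rep_r
  }
  out <- count_table(acc / reps, t$sample_ages[keep], lake_id = t$lake_id,
                     sample_ids = rownames(m))
  if (return_replicates) list(mean = out, replicates = replicates) else out
}

#' Filter taxa by occurrence frequency and overall relative abundance
#'
#' Keeps taxa that occur (count > 0) in at least `min_samples` samples and
#' whose overall relative abundance (taxon total over grand total) exceeds
#' `min_rel_abundance`.  The two criteria commute.
#'
#' @param t A [count_table()] (raw or rarefied).
#' @param min_samples Minimum number of samples with a positive count
#'   (default 3).
#' @param min_rel_abundance Strict lower bound on overall relative
#'   abundance; e.g. `3e-4` (0.03%) for a model-evaluation taxon set or
#'   `2e-4` (0.02%) for a display set.
#' @return A filtered [count_table()].
#' @export
filter_taxa <- function(t, min_samples = 3, min_rel_abundance = 3e-4) {
  stopifnot(inherits(t, "count_table"))
  freq <- colSums(t$counts > 0)
  rel <- colSums(t$counts) / sum(t$counts)
  keep <- freq >= min_samples & rel > min_rel_abundance
  if (!any(keep))
    stop_input("no taxa survive the frequency/abundance filter")
  count_table(t$counts[, keep, drop = FALSE], t$sample_ages,
              lake_id = t$lake_id, sample_ids = rownames(t$counts))
}

#' Average a count table into fixed-width age bins
#'
#' Samples are grouped into half-open `[k*width, (k+1)*width)` cal yr BP
#' bins (so a sample aged exactly 14,000 falls into the 14-15 ka bin) and
#' each bin's value is the mean over its member samples.  Empty bins are
#' omitted.
#'
#' @param t A [count_table()].
#' @param width Bin width in years (default 1000).
#' @return A list of class `binned_table`: `bin_mid_bp` (midpoints, oldest
#'   first), `bin_k` (bin indices), `values` (bins x taxa matrix),
#'   `n_samples` per bin, `lake_id`.
#' @export
bin_by_age <- function(t, width = 1000) {
  stopifnot(inherits(t, "count_table"))
  k <- floor(t$sample_ages / width)
  ks <- sort(unique(k), decreasing = TRUE)
  vals <- do.call(rbind, lapply(ks, function(kk)
    colMeans(t$counts[k == kk, , drop = FALSE])))
  rownames(vals) <- ks
  structure(list(bin_mid_bp = ks * width + width / 2, bin_k = ks,
                 values = vals, n_samples = as.integer(table(k)[as.character(ks)]),
                 lake_id = t$lake_id, transform_tag = "counts"),
            class = "binned_table")
}

#' @export
print.binned_table <- function(x, ...) {
  cat(sprintf("Binned table '%s': %d bins x %d taxa (%s)\n", x$lake_id,
              nrow(x$values), ncol(x$values), x$transform_tag))
  invisible(x)
}

#' Box-Cox-chord transformation of a community matrix
#'
#' With exponent 0 the Box-Cox power transform is the log, implemented as
#' `log(y + 1)` so zero counts map to zero; each row is then scaled to unit
#' Euclidean norm (the chord transformation), giving a double-zero
#' asymmetrical geometry suitable for ordination of sparse compositional
#' data.  All-zero rows are left as zeros.  Exponents other than 0 apply
#' `y^exponent` before the chord step.
#'
#' @param m A non-negative matrix, or a `binned_table` (its `values` are
#'   transformed and the object returned with an updated `transform_tag`).
#' @param exponent Box-Cox exponent (default 0 = log1p).
#' @return Same shape as the input.
#' @export
boxcox_chord <- function(m, exponent = 0) {
  if (inherits(m, "binned_table")) {
    m$values <- boxcox_chord(m$values, exponent)
    m$transform_tag <- sprintf("boxcox_chord(exponent=%g)", exponent)
    return(m)
  }
  m <- as.matrix(m)
  if (anyNA(m) || any(m < 0)) stop_input("matrix must be non-negative")
  y <- if (exponent == 0) log1p(m) else m^exponent
  nrm <- sqrt(rowSums(y^2))
  nrm[nrm == 0] <- 1
  y / nrm
}

#' Binarize a (binned) abundance matrix to presence/absence
#'
#' @param m Matrix or `binned_table`.
#' @param threshold Values strictly greater than this count as present
#'   (default 0, i.e. any positive mean rarefied count).
#' @return 0/1 matrix (or `binned_table` with 0/1 values).
#' @export
to_presence <- function(m, threshold = 0) {
  if (inherits(m, "binned_table")) {
    m$values <- to_presence(m$values, threshold)
    m$transform_tag <- sprintf("presence(>%g)", threshold)
    return(m)
  }
  (as.matrix(m) > threshold) * 1L
}

#' Richness per elevation band and per time bin
#'
#' Taxa are grouped by their mean species elevation maximum
#' (`elev_max_mean` in the trait table) into elevation bands -- by default
#' lowland (< 4000 m), mid (4000-4800 m) and upland (> 4800 m a.s.l.) --
#' and the number of present taxa per band is counted in every bin.  Taxa
#' lacking the trait are excluded and reported.
#'
#' @param presence A bins x taxa 0/1 matrix (or `binned_table` of
#'   presences).
#' @param traits A data.frame with columns `taxon_id` and `elev_max_mean_m`
#'   (see [read_traits()]).
#' @param breaks Band boundaries in metres (default `c(4000, 4800)`).
#' @param band_labels Labels, one more than `breaks`.
#' @return A data.frame with one row per bin: per-band richness columns,
#'   `total`, and attribute `skipped_taxa` listing taxa without traits.
#' @export
group_richness <- function(presence, traits, breaks = c(4000, 4800),
                           band_labels = c("lowland", "mid", "upland")) {
  if (inherits(presence, "binned_table")) presence <- presence$values
  presence <- as.matrix(presence)
  idx <- match(colnames(presence), traits$taxon_id)
  skipped <- colnames(presence)[is.na(idx)]
  if (length(skipped))
    presence <- presence[, !is.na(idx), drop = FALSE]
  elev <- traits$elev_max_mean_m[idx[!is.na(idx)]]
  # lowland < breaks[1] <= mid <= breaks[last] < upland: the lowest band is
  # open above, the highest open below, so e.g. 4000 and 4800 both fall in
  # the middle band under the defaults
  bi <- 1L
  for (j in seq_along(breaks))
    bi <- bi + (if (j == length(breaks)) elev > breaks[j] else elev >= breaks[j])
  band <- factor(band_labels[bi], levels = band_labels)
  out <- sapply(band_labels, function(b)
    rowSums(presence[, band == b, drop = FALSE]))
  out <- as.data.frame(matrix(out, nrow = nrow(presence),
                              dimnames = list(rownames(presence), band_labels)))
  out$total <- unname(rowSums(presence))
  attr(out, "skipped_taxa") <- skipped
  out
}

#' Community-mean trait value per time bin
#'
#' Unweighted mean of a trait over the taxa present in each bin; bins with
#' no present (trait-bearing) taxa yield `NA`.
#'
#' @param presence A bins x taxa 0/1 matrix (or `binned_table`).
#' @param traits Trait data.frame with `taxon_id` and the trait column.
#' @param trait Name of the trait column (e.g. `"elev_max_mean_m"` or
#'   `"plant_height_m"`).
#' @return Numeric vector, one value per bin.
#' @export
community_trait_mean <- function(presence, traits, trait) {
  if (inherits(presence, "binned_table")) presence <- presence$values
  presence <- as.matrix(presence)
  if (!trait %in% names(traits))
    stop_input(sprintf("trait column '%s' not found", trait))
  idx <- match(colnames(presence), traits$taxon_id)
  presence <- presence[, !is.na(idx), drop = FALSE]
  v <- traits[[trait]][idx[!is.na(idx)]]
  apply(presence, 1, function(p)
    if (any(p > 0)) mean(v[p > 0]) else NA_real_)
}

#' Read a taxon trait table
#'
#' CSV with header
#' `taxon_id,elev_max_mean_m,plant_height_m,growth_form`.
#'
#' @param path Path to the CSV.
#' @return A data.frame.
#' @export
read_traits <- function(path) {
  d <- read_checked_csv(path,
                        c("taxon_id", "elev_max_mean_m", "plant_height_m",
                          "growth_form"),
                        character_cols = c("taxon_id", "growth_form"),
                        min_rows = 1)
  if (any(d$elev_max_mean_m <= 0) || any(d$plant_height_m < 0))
    stop_input(sprintf("%s: elevation maxima must be positive and heights non-negative",
                       path))
  d
}
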