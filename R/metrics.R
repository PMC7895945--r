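#' Validate a nucleus table
#'
#' The per-nucleus table is the substrate of all cellular metrics: one row
#' per segmented nucleus with centroid coordinates (um), volume, and the
#' `(animal_id, position_id, timepoint, nucleus_id)` key.
#'
#' @param df data frame with columns `animal_id`, `position_id`,
#'   `timepoint`, `nucleus_id`, `x_um`, `y_um`, `z_um`, `volume_voxels`,
#'   `volume_um3`.
#' @return the validated data frame (class `nucleus_table` prepended).
#' @export
nucleus_table <- function(df) {
  need <- c("animal_id", "position_id", "timepoint", "nucleus_id",
            "x_um", "y_um", "z_um", "volume_voxels", "volume_um3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$volume_um3 <= 0, na.rm = TRUE)) stop("volumes must be > 0")
    if (any(df$z_um < 0)) stop("z_um must be >= 0")
    key <- paste(df$animal_id, df$position_id, df$timepoint, df$nucleus_id)
    if (anyDuplicated(key)) stop("duplicate nucleus keys")
  }
  class(df) <- unique(c("nucleus_table", class(df)))
  df
}

#' Nucleus size categories
#'
#' Four left-closed, right-open volume bins; the last bin is closed at the
#' upper edge and nuclei above it are counted as overflow.  Defaults: 750,
#' 1500, 2250, 3000 um^3 edges, making the largest category the 2250-3000
#' um^3 bin used as the strongest GMV predictor.
#'
#' @param edges_um3 strictly increasing bin edges including 0 and the top.
#' @return A `size_categories` object.
#' @export
size_categories <- function(edges_um3 = c(0, 750, 1500, 2250, 3000)) {
  edges_um3 <- as.numeric(edges_um3)
  if (any(diff(edges_um3) <= 0)) stop("edges must be strictly increasing")
  structure(list(edges_um3 = edges_um3), class = "size_categories")
}

#' Count nuclei by depth bin
#'
#' @param table a [nucleus_table()] (possibly empty).
#' @param binning a [depth_binning()].
#' @return list with `counts` (named per-bin vector), `total` (in-range
#'   count) and `n_excluded` (rows outside `[0, depth]`).
#' @export
count_by_depth <- function(table, binning = depth_binning()) {
  stopifnot(inherits(binning, "depth_binning"))
  nb <- length(binning$edges) - 1L
  lab <- depth_bin_labels(binning)
  if (nrow(table) == 0)
    return(list(counts = setNames(rep(0L, nb), lab), total = 0L,
                n_excluded = 0L))
  idx <- depth_bin_index(table$z_um, binning)
  n_ex <- sum(is.na(idx))
  if (n_ex > 0)
    message(sprintf("count_by_depth: %d nuclei outside [0, %g] um excluded",
                    n_ex, binning$total_depth_um))
  counts <- tabulate(idx[!is.na(idx)], nbins = nb)
  list(counts = setNames(as.integer(counts), lab),
       total = sum(counts), n_excluded = n_ex)
}

#' Nearest-neighbor distance statistics
#'
#' 3D Euclidean distance from each nucleus centroid to its closest
#' neighboring centroid, with the stack mean and optional depth-binned
#' means.  A nucleus is assigned to a depth bin by its own z coordinate
#' while the neighbor search always runs over the whole stack.
#'
#' @param table a [nucleus_table()] with >= 2 rows.
#' @param binning optional [depth_binning()] for per-layer means.
#' @return list with `distances` (per row, um), `mean` and, if `binning`
#'   is given, `by_depth` (named per-bin mean vector).
#' @export
nearest_neighbor_stats <- function(table, binning = NULL) {
  if (nrow(table) < 2) stop("need at least 2 nuclei for NN distances")
  pts <- cbind(table$x_um, table$y_um, table$z_um)
  d <- cpp_nn_distances(pts)
  out <- list(distances = d, mean = mean(d))
  if (!is.null(binning)) {
    stopifnot(inherits(binning, "depth_binning"))
    idx <- depth_bin_index(table$z_um, binning)
    lab <- depth_bin_labels(binning)
    by <- vapply(seq_along(lab), function(b) {
      sel <- !is.na(idx) & idx == b
      if (any(sel)) mean(d[sel]) else NA_real_
    }, numeric(1))
    out$by_depth <- setNames(by, lab)
  }
  out
}

#' Nucleus-volume statistics and size-category fractions
#'
#' @param table a non-empty [nucleus_table()].
#' @param categories a [size_categories()].
#' @return list with `mean_um3`, `fractions` (per category; denominator is
#'   the total nucleus count including overflow) and `overflow_fraction`
#'   (volume above the top edge).
#' @export
nucleus_volume_stats <- function(table, categories = size_categories()) {
  stopifnot(inherits(categories, "size_categories"))
  if (nrow(table) == 0) stop("empty nucleus table")
  v <- table$volume_um3
  e <- categories$edges_um3
  nb <- length(e) - 1L
  idx <- findInterval(v, e, rightmost.closed = TRUE)
  idx[v < e[1] | v > e[length(e)]] <- NA_integer_
  counts <- tabulate(idx[!is.na(idx)], nbins = nb)
  n <- length(v)
  lab <- sprintf("[%g,%g)", e[-length(e)], e[-1])
  lab[nb] <- sprintf("[%g,%g]", e[nb], e[nb + 1L])
  list(mean_um3 = mean(v),
       fractions = setNames(counts / n, lab),
       overflow_fraction = sum(v > e[length(e)]) / n)
}

#' Relative change as percent of baseline
#'
#' @param value_t value at the later timepoint.
#' @param value_baseline baseline value (nonzero).
#' @return `100 * value_t / value_baseline` (vectorized).
#' @export
relative_change <- function(value_t, value_baseline) {
  if (any(value_baseline == 0)) stop("zero baseline in relative_change")
  100 * value_t / value_baseline
}

#' Join cellular-metric and GMV change tables
#'
#' Inner join on `(animal_id, position_id, interval)`; rows missing on
#' either side are dropped (and reported via a message), duplicated keys on
#' either side are an error.
#'
#' @param metrics data frame keyed by `animal_id`, `position_id`,
#'   `interval` with metric columns.
#' @param gmv data frame keyed the same way with a `gmv_pct` column.
#' @return the joined long-format data frame, one row per position and
#'   interval.
#' @export
build_correlation_table <- function(metrics, gmv) {
  keycols <- c("animal_id", "position_id", "interval")
  stopifnot(all(keycols %in% names(metrics)), all(keycols %in% names(gmv)))
  km <- do.call(paste, c(metrics[keycols], sep = "\r"))
  kg <- do.call(paste, c(gmv[keycols], sep = "\r"))
  if (anyDuplicated(km)) stop("duplicate (animal, position, interval) keys in metrics")
  if (anyDuplicated(kg)) stop("duplicate (animal, position, interval) keys in gmv")
  common <- intersect(km, kg)
  dropped <- (nrow(metrics) - length(common)) + (nrow(gmv) - length(common))
  if (dropped > 0)
    message(sprintf("build_correlation_table: %d unmatched rows dropped",
                    dropped))
  m <- metrics[match(common, km), , drop = FALSE]
  g <- gmv[match(common, kg), setdiff(names(gmv), keycols), drop = FALSE]
  out <- cbind(m, g)
  rownames(out) <- NULL
  out
}
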