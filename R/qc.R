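#' Region of interest in stack voxel coordinates
#'
#' @param z,y,x integer ranges (each `c(from, to)`, 1-based inclusive).
#' @param role `"signal"` or `"background"`.
#' @return A `region_of_interest` object.
#' @export
region_of_interest <- function(z, y, x, role = c("signal", "background")) {
  role <- match.arg(role)
  rng <- function(r) {
    r <- as.integer(r)
    stopifnot(length(r) == 2, r[1] >= 1, r[2] >= r[1])
    r
  }
  structure(list(z = rng(z), y = rng(y), x = rng(x), role = role),
            class = "region_of_interest")
}

roi_values <- function(stack, roi) {
  d <- stack$geometry$shape
  if (roi$z[2] > d[1] || roi$y[2] > d[2] || roi$x[2] > d[3])
    stop("ROI exceeds stack bounds")
  stack$data[roi$z[1]:roi$z[2], roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]]
}

#' Signal-to-noise ratio of an image stack
#'
#' `SNR = mu_sig / sigma_bg`: mean pixel intensity of a signal ROI divided
#' by the standard deviation (n - 1 denominator) of a reference background
#' ROI.  Matching ROIs at a depth of about 300 um are compared between
#' timepoints for the stability rating.
#'
#' @param stack an [image_stack()].
#' @param signal_roi a signal [region_of_interest()].
#' @param background_roi a background [region_of_interest()] with > 1
#'   voxel.
#' @return SNR (dimensionless).
#' @export
compute_snr <- function(stack, signal_roi, background_roi) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(signal_roi, "region_of_interest"),
            inherits(background_roi, "region_of_interest"))
  bg <- roi_values(stack, background_roi)
  if (length(bg) < 2) stop("background ROI must have more than one voxel")
  s <- sd(as.vector(bg))
  if (s == 0) stop("zero background variance: SNR undefined")
  mean(roi_values(stack, signal_roi)) / s
}

#' Rate SNR stability between timepoints
#'
#' Stable iff each of at least `min_regions` paired reference areas changed
#' its SNR by no more than `tolerance` (default 10 percent).
#'
#' @param snr_t SNR values at the tested timepoint.
#' @param snr_ref paired SNR values at the reference timepoint.
#' @param tolerance maximum allowed relative deviation.
#' @param min_regions minimum number of reference areas.
#' @return logical: `TRUE` when stable.
#' @export
rate_snr_stability <- function(snr_t, snr_ref, tolerance = 0.10,
                               min_regions = 3L) {
  if (length(snr_t) != length(snr_ref))
    stop("snr_t and snr_ref must be paired (equal length)")
  if (length(snr_t) < min_regions)
    stop(sprintf("need at least %d reference areas, got %d", min_regions,
                 length(snr_t)))
  all(abs(snr_t / snr_ref - 1) <= tolerance)
}

#' Z-density-profile comparability score
#'
#' Surrogate for image-quality changes between timepoints: Gaussian kernel
#' densities of the nucleus z coordinates are evaluated on a common grid
#' over `[0, depth]`, scaled by the respective nucleus counts to
#' cells-per-um, and the score is the trapezoidal integral of their
#' absolute difference (units: cells).  Datasets whose score exceeds the
#' threshold (500 cells by default) are flagged for manual inspection
#' against the exclusion causes.
#'
#' @param table_t,table_ref non-empty [nucleus_table()]s of the two
#'   timepoints.
#' @param total_depth_um grid range (um).
#' @param n_grid number of grid points.
#' @param bw numeric bandwidth (um), or `"nrd0"` for Silverman's rule on
#'   the pooled z coordinates; one common bandwidth is used for both
#'   profiles so that nuclei present in both tables cancel exactly.
#' @param threshold flag threshold in cells.
#' @return list with `score` (cells), `flag` (`score > threshold`) and
#'   `threshold`.
#' @export
density_profile_score <- function(table_t, table_ref, total_depth_um = 700,
                                  n_grid = 512L, bw = "nrd0",
                                  threshold = 500) {
  if (nrow(table_t) == 0 || nrow(table_ref) == 0)
    stop("empty nucleus table")
  grid <- seq(0, total_depth_um, length.out = n_grid)
  # one common bandwidth for both profiles so that shared nuclei cancel
  bw_common <- if (is.numeric(bw)) bw else
    stats::bw.nrd0(c(table_t$z_um, table_ref$z_um))
  prof <- function(tab) {
    d <- density(tab$z_um, bw = bw_common, n = n_grid, from = 0,
                 to = total_depth_um)
    d$y * nrow(tab)      # cells per um
  }
  dif <- abs(prof(table_t) - prof(table_ref))
  h <- diff(grid)
  score <- sum((dif[-1] + dif[-length(dif)]) / 2 * h)
  list(score = score, flag = score > threshold, threshold = threshold)
}

#' Detect laser-blankout planes
#'
#' A z plane is flagged when its mean intensity falls below `fraction`
#' times the median of all plane means (acquisition software failures zero
#' or nearly zero whole planes).
#'
#' @param stack an [image_stack()].
#' @param fraction relative threshold (default 0.05).
#' @return integer vector of flagged plane indices (1-based).
#' @export
detect_blankouts <- function(stack, fraction = 0.05) {
  stopifnot(inherits(stack, "image_stack"), fraction >= 0)
  pm <- apply(stack$data, 1, mean)
  which(pm < fraction * median(pm))
}

#' Assemble a QC report for one dataset pair
#'
#' Combines the exclusion criteria into one record: SNR stability of
#' paired reference areas, the z-density-profile score, blankout planes,
#' and a manually set inhomogeneity flag (screened by eye at ~300 um in
#' practice; no automatic detector is claimed).  A dataset is excluded when
#' at least one reason code applies.
#'
#' @param animal_id,position_id,timepoint_pair identifying keys.
#' @param snr_t,snr_ref paired SNR lists (see [rate_snr_stability()]).
#' @param density a result of [density_profile_score()], or `NULL`.
#' @param blankout_planes integer vector from [detect_blankouts()].
#' @param inhomogeneity_suspect logical, set manually.
#' @param snr_tolerance,snr_min_regions passed to [rate_snr_stability()].
#' @return A `qc_report` object (also a one-row data frame) with logical
#'   `excluded` and a comma-separated `reasons` string drawn from
#'   `blankout`, `inhomogeneity-suspect`, `snr-unstable`, `density-flag`.
#' @export
qc_report <- function(animal_id, position_id, timepoint_pair,
                      snr_t = NULL, snr_ref = NULL, density = NULL,
                      blankout_planes = integer(0),
                      inhomogeneity_suspect = FALSE,
                      snr_tolerance = 0.10, snr_min_regions = 3L) {
  reasons <- character(0)
  snr_stable <- NA
  if (!is.null(snr_t)) {
    snr_stable <- rate_snr_stability(snr_t, snr_ref, snr_tolerance,
                                     snr_min_regions)
    if (!snr_stable) reasons <- c(reasons, "snr-unstable")
  }
  density_flag <- NA
  density_score <- NA_real_
  if (!is.null(density)) {
    density_flag <- density$flag
    density_score <- density$score
    if (density$flag) reasons <- c(reasons, "density-flag")
  }
  if (length(blankout_planes)) reasons <- c(reasons, "blankout")
  if (isTRUE(inhomogeneity_suspect))
    reasons <- c(reasons, "inhomogeneity-suspect")
  out <- data.frame(animal_id = animal_id, position_id = position_id,
                    timepoint_pair = timepoint_pair,
                    snr_stable = snr_stable,
                    density_score = density_score,
                    density_flag = density_flag,
                    n_blankout_planes = length(blankout_planes),
                    inhomogeneity_suspect = inhomogeneity_suspect,
                    excluded = length(reasons) > 0,
                    reasons = paste(reasons, collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("qc_report", class(out))
  out
}
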