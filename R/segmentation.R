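#' Segmentation configuration
#'
#' Parameters of the seed-detection / watershed / size-filter chain.  The
#' voxel-count filters default to 1500 and 18,000 voxels, the established
#' cutoffs at 0.29 x 0.29 x 2 um in vivo sampling; the probability thresholds were not
#' published and default to values that work on the synthetic phantoms.
#'
#' @param foreground_threshold probability threshold t_fg in (0, 1)
#'   defining the watershed foreground mask and the minimum seed value.
#' @param seed_prominence noise tolerance h: a 2D maximum is dropped when
#'   it is connected to a higher maximum through pixels above its value
#'   minus h.
#' @param seed_dilation_radius in-plane dilation radius of detected maxima
#'   (voxels).
#' @param min_voxels objects below this voxel count are removed.
#' @param max_voxels objects above this voxel count are re-segmented.
#' @param reseg_threshold_factor factor in (0, 1) applied to
#'   `foreground_threshold` (and to `seed_prominence`) during local
#'   re-segmentation of oversized objects.
#' @param smoothing_sd_um Gaussian pre-smoothing for
#'   [compute_foreground_probability()] (um).
#' @param background_percentile percentile subtracted as background in
#'   [compute_foreground_probability()].
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(foreground_threshold = 0.5,
                                seed_prominence = 0.1,
                                seed_dilation_radius = 2L,
                                min_voxels = 1500L,
                                max_voxels = 18000L,
                                reseg_threshold_factor = 0.8,
                                smoothing_sd_um = 1,
                                background_percentile = 0.5) {
  stopifnot(foreground_threshold > 0, foreground_threshold < 1,
            seed_prominence > 0, seed_dilation_radius >= 0,
            min_voxels >= 1, min_voxels < max_voxels,
            reseg_threshold_factor > 0, reseg_threshold_factor < 1,
            smoothing_sd_um >= 0,
            background_percentile >= 0, background_percentile <= 1)
  structure(list(foreground_threshold = foreground_threshold,
                 seed_prominence = seed_prominence,
                 seed_dilation_radius = as.integer(seed_dilation_radius),
                 min_voxels = as.integer(min_voxels),
                 max_voxels = as.integer(max_voxels),
                 reseg_threshold_factor = reseg_threshold_factor,
                 smoothing_sd_um = smoothing_sd_um,
                 background_percentile = background_percentile),
            class = "segmentation_config")
}

reflect_index <- function(i, n) {
  # reflect out-of-range indices at the borders (half-sample symmetric)
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  pmin(pmax(i, 1L), n)
}

smooth_axis <- function(a, axis, sigma_vox) {
  if (sigma_vox < 1e-8) return(a)
  d <- dim(a)
  n <- d[axis]
  r <- max(1L, ceiling(3.5 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (o in -r:r) {
    j <- reflect_index(seq_len(n) + o, n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[o + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  sm <- K %*% m
  out <- array(sm, dim = d[perm])
  aperm(out, order(perm))
}

#' Separable 3D Gaussian smoothing in physical units
#'
#' @param a 3D array in `(z, y, x)` order.
#' @param geometry the array's [voxel_geometry()].
#' @param sd_um isotropic smoothing standard deviation (um); per-axis voxel
#'   sigmas are derived from the voxel sizes.
#' @return smoothed array.
#' @export
gaussian_smooth_3d <- function(a, geometry, sd_um) {
  stopifnot(inherits(geometry, "voxel_geometry"), sd_um >= 0)
  for (axis in 1:3)
    a <- smooth_axis(a, axis, sd_um / geometry$voxel_size[axis])
  a
}

#' Foreground probability stand-in
#'
#' Simple replacement for the machine-learning foreground classifier used
#' upstream of seed detection: the stack is Gaussian-smoothed, a background
#' percentile is subtracted, and the result is rescaled by its 99.9th
#' percentile and clipped to `[0, 1]`.  A constant stack maps to an
#' all-zero map.  Externally computed probability volumes can be supplied
#' directly via [probability_map()] and used unchanged.
#'
#' @param stack an [image_stack()].
#' @param smoothing_sd_um Gaussian smoothing sd in um.
#' @param background_percentile quantile (in `[0, 1]`) subtracted as
#'   background.
#' @return A [probability_map()].
#' @export
compute_foreground_probability <- function(stack, smoothing_sd_um = 1,
                                           background_percentile = 0.5) {
  stopifnot(inherits(stack, "image_stack"), smoothing_sd_um >= 0)
  a <- gaussian_smooth_3d(stack$data, stack$geometry, smoothing_sd_um)
  bg <- quantile(a, background_percentile, names = FALSE)
  a <- a - bg
  top <- quantile(a, 0.999, names = FALSE)
  # guard against constant input (top is then numerical noise)
  if (top <= 1e-8 * max(abs(bg), 1)) {
    a[] <- 0
  } else {
    a <- pmin(pmax(a / top, 0), 1)
  }
  out <- probability_map(a, stack$geometry)
  attr(out, "background") <- bg     # intensity subtracted (ADU)
  attr(out, "scale") <- max(top, 0) # 99.9th percentile used for rescaling
  out
}

disk_offsets <- function(radius) {
  o <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  o[o$dy^2 + o$dx^2 <= radius^2, , drop = FALSE]
}

#' Detect watershed seeds on a probability map
#'
#' Per z plane, 2D local maxima with value >= t_fg and noise tolerance h
#' are detected, dilated in-plane by a disk, and 26-connected components
#' across z become one seed label each (maxima columns of one nucleus link
#' up across planes).
#'
#' @param prob a [probability_map()].
#' @param cfg a [segmentation_config()].
#' @return A seed [label_volume()].
#' @export
detect_seeds <- function(prob, cfg = segmentation_config()) {
  stopifnot(inherits(prob, "probability_map"),
            inherits(cfg, "segmentation_config"))
  dims <- prob$geometry$shape
  marks <- array(FALSE, dim = dims)
  for (z in seq_len(dims[1])) {
    plane <- prob$data[z, , ]
    idx <- cpp_find_maxima_2d(as.numeric(plane), dims[2], dims[3],
                              cfg$seed_prominence, cfg$foreground_threshold)
    if (length(idx)) {
      iy <- (idx %% dims[2]) + 1L
      ix <- (idx %/% dims[2]) + 1L
      marks[cbind(z, iy, ix)] <- TRUE
    }
  }
  if (cfg$seed_dilation_radius > 0 && any(marks)) {
    off <- disk_offsets(cfg$seed_dilation_radius)
    pos <- which(marks, arr.ind = TRUE)
    dil <- marks
    for (k in seq_len(nrow(off))) {
      iy <- pos[, 2] + off$dy[k]
      ix <- pos[, 3] + off$dx[k]
      okk <- iy >= 1L & iy <= dims[2] & ix >= 1L & ix <= dims[3]
      dil[cbind(pos[okk, 1], iy[okk], ix[okk])] <- TRUE
    }
    marks <- dil
  }
  lab <- cpp_label_components(as.logical(marks), dims)
  label_volume(array(lab, dim = dims), prob$geometry, provenance = "seeds")
}

#' Seeded watershed segmentation
#'
#' Priority-flood watershed on the negated probability restricted to the
#' foreground mask `prob >= t_fg`.  Foreground voxels unreachable from any
#' seed stay background.  Flooding order is deterministic: highest
#' probability first, ties broken by raster index.
#'
#' @param prob a [probability_map()].
#' @param seeds a seed [label_volume()] sharing the geometry.
#' @param cfg a [segmentation_config()].
#' @return A raw [label_volume()].
#' @export
watershed_segment <- function(prob, seeds, cfg = segmentation_config()) {
  stopifnot(inherits(prob, "probability_map"),
            inherits(seeds, "label_volume"),
            inherits(cfg, "segmentation_config"))
  if (!identical(prob$geometry$shape, seeds$geometry$shape))
    stop("probability map and seeds have different geometries")
  dims <- prob$geometry$shape
  if (all(seeds$data == 0L)) {
    warning("no seeds: returning an empty labeling")
    return(label_volume(array(0L, dim = dims), prob$geometry, "raw"))
  }
  mask <- prob$data >= cfg$foreground_threshold
  lab <- cpp_watershed(as.numeric(prob$data), as.integer(seeds$data),
                       as.logical(mask), dims)
  label_volume(array(lab, dim = dims), prob$geometry, provenance = "raw")
}

object_sizes <- function(data) {
  v <- as.vector(data)
  v <- v[v > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v)
}

#' Size-filter and re-segment a watershed labeling
#'
#' Objects below `min_voxels` are removed (false-positive suppression).
#' Objects above `max_voxels`, suggesting wrongly merged nuclei, are
#' re-segmented inside their bounding box with the foreground threshold and
#' seed tolerance lowered by `reseg_threshold_factor`; the minimum-size
#' filter is re-applied to the products (recursion depth 1).  If
#' re-segmentation yields no surviving part, the original object is kept
#' and flagged.  Output labels are consecutive `1..K`.
#'
#' @param labels a raw [label_volume()] from [watershed_segment()].
#' @param prob the [probability_map()] the labels were derived from.
#' @param cfg a [segmentation_config()].
#' @return A filtered [label_volume()]; the attribute `"flagged_labels"`
#'   lists output labels kept despite failed re-segmentation.
#' @export
filter_and_resegment <- function(labels, prob, cfg = segmentation_config()) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(prob, "probability_map"),
            inherits(cfg, "segmentation_config"))
  dims <- labels$geometry$shape
  sizes <- object_sizes(labels$data)
  out <- array(0L, dim = dims)
  nextid <- 0L
  flagged <- integer(0)
  cfg_lo <- cfg
  cfg_lo$foreground_threshold <-
    cfg$foreground_threshold * cfg$reseg_threshold_factor
  cfg_lo$seed_prominence <- cfg$seed_prominence * cfg$reseg_threshold_factor
  for (lb in seq_along(sizes)) {
    sz <- sizes[lb]
    if (sz == 0L || sz < cfg$min_voxels) next
    vox <- which(labels$data == lb)
    if (sz <= cfg$max_voxels) {
      nextid <- nextid + 1L
      out[vox] <- nextid
      next
    }
    # oversized: local re-segmentation inside the bounding box
    co <- arrayInd(vox, dims)
    rz <- range(co[, 1]); ry <- range(co[, 2]); rx <- range(co[, 3])
    sub <- array(0, dim = c(diff(rz) + 1L, diff(ry) + 1L, diff(rx) + 1L))
    loc <- cbind(co[, 1] - rz[1] + 1L, co[, 2] - ry[1] + 1L,
                 co[, 3] - rx[1] + 1L)
    sub[loc] <- prob$data[vox]
    subgeo <- voxel_geometry(dim(sub), labels$geometry$voxel_size)
    submap <- probability_map(sub, subgeo)
    subseeds <- detect_seeds(submap, cfg_lo)
    parts <- suppressWarnings(watershed_segment(submap, subseeds, cfg_lo))
    psizes <- object_sizes(parts$data)
    good <- which(psizes >= cfg$min_voxels)
    if (length(good) == 0L) {
      nextid <- nextid + 1L
      out[vox] <- nextid
      flagged <- c(flagged, nextid)
      next
    }
    for (g in good) {
      pv <- which(parts$data == g)
      nextid <- nextid + 1L
      pco <- arrayInd(pv, dim(sub))
      gco <- cbind(pco[, 1] + rz[1] - 1L, pco[, 2] + ry[1] - 1L,
                   pco[, 3] + rx[1] - 1L)
      gi <- gco[, 1] + dims[1] * (gco[, 2] - 1L) +
        dims[1] * dims[2] * (gco[, 3] - 1L)
      # only voxels of the original object may be claimed
      gi <- gi[labels$data[gi] == lb]
      out[gi] <- nextid
    }
  }
  res <- label_volume(out, labels$geometry, provenance = "filtered")
  attr(res, "flagged_labels") <- flagged
  res
}

#' Extract the nucleus table from a label volume
#'
#' Per object: centroid as the unweighted mean of member voxel centers
#' (um), voxel count, and physical volume `count * dx * dy * dz`.
#'
#' @param labels a filtered [label_volume()].
#' @param animal_id,position_id,timepoint keys attached to every row.
#' @return A [nucleus_table()] data frame.
#' @export
extract_nuclei <- function(labels, animal_id = "a1", position_id = "p1",
                           timepoint = 0) {
  stopifnot(inherits(labels, "label_volume"))
  dims <- labels$geometry$shape
  vs <- labels$geometry$voxel_size
  idx <- which(labels$data > 0L)
  if (!length(idx)) {
    return(nucleus_table(data.frame(
      animal_id = character(0), position_id = character(0),
      timepoint = numeric(0), nucleus_id = integer(0),
      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
      volume_voxels = numeric(0), volume_um3 = numeric(0))))
  }
  lb <- labels$data[idx]
  co <- arrayInd(idx, dims)
  zc <- (co[, 1] - 0.5) * vs[1]
  yc <- (co[, 2] - 0.5) * vs[2]
  xc <- (co[, 3] - 0.5) * vs[3]
  ids <- sort(unique(lb))
  f <- factor(lb, levels = ids)
  cnt <- as.numeric(table(f))
  sums <- rowsum(cbind(xc, yc, zc), f)
  tab <- data.frame(
    animal_id = animal_id, position_id = position_id,
    timepoint = timepoint, nucleus_id = as.integer(ids),
    x_um = sums[, 1] / cnt, y_um = sums[, 2] / cnt, z_um = sums[, 3] / cnt,
    volume_voxels = cnt, volume_um3 = cnt * prod(vs),
    stringsAsFactors = FALSE, row.names = NULL)
  nucleus_table(tab)
}

#' Run the full segmentation chain on a stack
#'
#' Convenience wrapper: probability stand-in (unless a map is supplied),
#' seed detection, watershed, size filtering / re-segmentation, and table
#' extraction.
#'
#' @param stack an [image_stack()].
#' @param cfg a [segmentation_config()].
#' @param prob optional externally computed [probability_map()]; when given
#'   it is used unchanged.
#' @param animal_id,position_id,timepoint keys for the output table.
#' @return list with `labels` (filtered [label_volume()]) and `nuclei`
#'   (a [nucleus_table()]).
#' @export
segment_stack <- function(stack, cfg = segmentation_config(), prob = NULL,
                          animal_id = "a1", position_id = "p1",
                          timepoint = 0) {
  if (is.null(prob))
    prob <- compute_foreground_probability(stack, cfg$smoothing_sd_um,
                                           cfg$background_percentile)
  seeds <- detect_seeds(prob, cfg)
  raw <- watershed_segment(prob, seeds, cfg)
  filt <- filter_and_resegment(raw, prob, cfg)
  list(labels = filt,
       nuclei = extract_nuclei(filt, animal_id, position_id, timepoint))
}
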