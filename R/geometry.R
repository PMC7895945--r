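#' Voxel geometry of a 3D image stack
#'
#' Describes the sampling grid of an image stack or MRI volume.  Arrays are
#' stored in `(z, y, x)` index order; `z = 0` is the tissue surface and z
#' increases with cortical depth.  The physical origin is fixed at
#' `(0, 0, 0)` and the voxel with index `(i, j, k)` (1-based) has its center
#' at `((i - 0.5) * dz, (j - 0.5) * dy, (k - 0.5) * dx)` micrometers.
#'
#' @param shape integer triple `(nz, ny, nx)`, all >= 1.
#' @param voxel_size numeric triple `(dz, dy, dx)` in micrometers, all > 0.
#'   The default `c(2, 1, 1)` is the desk-scale test geometry; in vivo
#'   acquisitions sample 0.29 x 0.29 um in-plane with 2-um steps.
#' @return An object of class `voxel_geometry` with fields `shape`,
#'   `voxel_size` and derived `extent_um` (physical size `(z, y, x)` in um).
#' @examples
#' g <- voxel_geometry(c(100, 200, 200), c(2, 1, 1))
#' g$extent_um  # 200 x 200 x 200 um
#' @export
voxel_geometry <- function(shape = c(100L, 200L, 200L),
                           voxel_size = c(2, 1, 1)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3, length(voxel_size) == 3)
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  if (any(voxel_size <= 0)) stop("all voxel sizes must be > 0")
  structure(
    list(shape = shape, voxel_size = voxel_size,
         extent_um = shape * voxel_size),
    class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g um -> extent %.4g x %.4g x %.4g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$extent_um[1], x$extent_um[2], x$extent_um[3]))
  invisible(x)
}

#' Physical voxel-center coordinates along one axis
#'
#' @param geometry a [voxel_geometry()].
#' @param axis 1 = z, 2 = y, 3 = x.
#' @return numeric vector of center coordinates in um.
#' @export
voxel_centers <- function(geometry, axis) {
  stopifnot(inherits(geometry, "voxel_geometry"), axis %in% 1:3)
  (seq_len(geometry$shape[axis]) - 0.5) * geometry$voxel_size[axis]
}

new_volume <- function(data, geometry, class, extra = list()) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!identical(dim(data), as.integer(geometry$shape)))
    stop("array shape does not match geometry shape")
  structure(c(list(data = data, geometry = geometry), extra), class = class)
}

#' Construct an image stack
#'
#' Wraps a 3D intensity array (unsigned 16-bit semantics, `(z, y, x)` order)
#' together with its [voxel_geometry()].
#'
#' @param data 3D numeric array with non-negative values.
#' @param geometry a [voxel_geometry()] whose shape matches `dim(data)`.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, geometry) {
  if (min(data) < 0) stop("image stack values must be non-negative")
  new_volume(data, geometry, "image_stack")
}

#' Construct a foreground-probability map
#'
#' @param data 3D array with values in `[0, 1]`, `(z, y, x)` order.
#' @param geometry a [voxel_geometry()] whose shape matches `dim(data)`.
#' @return A `probability_map` object.
#' @export
probability_map <- function(data, geometry) {
  if (min(data) < 0 || max(data) > 1)
    stop("probability values must lie in [0, 1]")
  new_volume(data, geometry, "probability_map")
}

#' Construct a label volume
#'
#' @param data 3D integer array; 0 is background, positive integers are
#'   object labels.
#' @param geometry a [voxel_geometry()] whose shape matches `dim(data)`.
#' @param provenance one of `"seeds"`, `"raw"`, `"filtered"`.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, geometry, provenance = "raw") {
  provenance <- match.arg(provenance, c("seeds", "raw", "filtered"))
  storage.mode(data) <- "integer"
  if (min(data) < 0L) stop("labels must be non-negative")
  new_volume(data, geometry, "label_volume", list(provenance = provenance))
}

#' Number of distinct objects in a label volume
#' @param labels a [label_volume()].
#' @return integer count of distinct nonzero labels.
#' @export
n_labels <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  length(setdiff(unique(as.vector(labels$data)), 0L))
}

#' Depth binning of a cortical stack
#'
#' Half-open bins `[a, b)` along z; the last bin is closed so that the full
#' `[0, total_depth]` interval is covered.  Defaults follow the 175-um layer
#' convention used for layer-confined metrics over a 700-um deep stack.
#'
#' @param width_um bin width in um (default 175).
#' @param total_depth_um total depth in um (default 700); must be an exact
#'   multiple of `width_um`.
#' @return A `depth_binning` object with `edges` (length nbins + 1).
#' @export
depth_binning <- function(width_um = 175, total_depth_um = 700) {
  stopifnot(width_um > 0, total_depth_um > 0)
  nb <- total_depth_um / width_um
  if (abs(nb - round(nb)) > 1e-9)
    stop("total depth must be an integer multiple of the bin width")
  edges <- seq(0, total_depth_um, by = width_um)
  structure(list(width_um = width_um, total_depth_um = total_depth_um,
                 edges = edges),
            class = "depth_binning")
}

#' Assign depth coordinates to bins
#'
#' @param z_um numeric vector of depths in um.
#' @param binning a [depth_binning()].
#' @return integer bin index per value (1-based); `NA` outside
#'   `[0, total_depth]`.
#' @export
depth_bin_index <- function(z_um, binning) {
  stopifnot(inherits(binning, "depth_binning"))
  nb <- length(binning$edges) - 1L
  idx <- findInterval(z_um, binning$edges, rightmost.closed = TRUE)
  idx[z_um < 0 | z_um > binning$total_depth_um] <- NA_integer_
  idx[idx < 1L | idx > nb] <- NA_integer_
  idx
}

#' Bin labels such as "[0,175)" for reporting
#' @param binning a [depth_binning()].
#' @return character vector of interval labels.
#' @export
depth_bin_labels <- function(binning) {
  e <- binning$edges
  nb <- length(e) - 1L
  lab <- sprintf("[%g,%g)", e[-length(e)], e[-1])
  lab[nb] <- sprintf("[%g,%g]", e[nb], e[nb + 1L])
  lab
}
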