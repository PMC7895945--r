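#' Per-voxel displacement field on an MRI grid
#'
#' @param data 4D array `(nz, ny, nx, 3)`; the last axis holds the
#'   displacement components in `(z, y, x)` order, in micrometers.
#' @param geometry a [voxel_geometry()] for the spatial axes.
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(data, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  d <- dim(data)
  if (length(d) != 4 || d[4] != 3 ||
      !identical(d[1:3], as.integer(geometry$shape)))
    stop("displacement array must be (nz, ny, nx, 3) matching the geometry")
  if (any(!is.finite(data))) stop("displacements must be finite")
  structure(list(data = data, geometry = geometry),
            class = "deformation_field")
}

central_diff <- function(a, axis, spacing) {
  d <- dim(a); n <- d[axis]
  if (n < 3) stop("grid must have >= 3 voxels per axis")
  idx <- function(i) {
    args <- list(a)
    args[1 + seq_along(d)] <- lapply(d, seq_len)
    args[[1 + axis]] <- i
    do.call(`[`, c(args, list(drop = FALSE)))
  }
  out <- array(0, dim = d)
  assign_slab <- function(i, val) {
    args <- lapply(d, seq_len)
    args[[axis]] <- i
    eval(as.call(c(list(as.name("[<-"), as.name("out")), args,
                   list(quote(val)))), list(out = out, val = val))
  }
  # interior: central; borders: one-sided
  ctr <- (idx(3:n) - idx(1:(n - 2))) / (2 * spacing)
  lo <- (idx(2) - idx(1)) / spacing
  hi <- (idx(n) - idx(n - 1)) / spacing
  out <- assign_slab(2:(n - 1), ctr)
  out <- assign_slab(1, lo)
  out <- assign_slab(n, hi)
  out
}

#' Jacobian-determinant field of a deformation
#'
#' Computes the per-voxel determinant of the deformation gradient
#' `I + grad(u)` from a displacement field, using central differences in
#' the interior and one-sided differences at the borders.  The determinant
#' is the local volume-change factor: values below 1 indicate shrinkage.
#'
#' @param field a [deformation_field()].
#' @return A `jacobian_field` object with `data` (3D determinant array),
#'   `geometry`, and `all_positive` (logical; orientation preserved
#'   everywhere).
#' @export
jacobian_determinant_field <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  vs <- field$geometry$voxel_size   # (dz, dy, dx)
  # components stored (z, y, x); map to displacement u_z, u_y, u_x
  u <- field$data
  g <- array(0, dim = c(dim(u)[1:3], 3, 3))
  for (comp in 1:3) {          # 1 = z, 2 = y, 3 = x
    for (axis in 1:3) {        # derivative along z, y, x
      g[, , , comp, axis] <- central_diff(u[, , , comp, drop = FALSE][, , , 1],
                                          axis, vs[axis])
    }
  }
  F11 <- 1 + g[, , , 1, 1]; F12 <- g[, , , 1, 2]; F13 <- g[, , , 1, 3]
  F21 <- g[, , , 2, 1]; F22 <- 1 + g[, , , 2, 2]; F23 <- g[, , , 2, 3]
  F31 <- g[, , , 3, 1]; F32 <- g[, , , 3, 2]; F33 <- 1 + g[, , , 3, 3]
  det <- F11 * (F22 * F33 - F23 * F32) -
    F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
  if (any(!is.finite(det))) stop("non-finite Jacobian determinant")
  structure(list(data = det, geometry = field$geometry,
                 all_positive = all(det > 0)),
            class = "jacobian_field")
}

#' Fit a 2D affine registration from corresponding point pairs
#'
#' Maps two-photon in-plane coordinates to MRI in-plane physical
#' coordinates using >= 3 corresponding landmarks (vessel branching
#' points).  Exactly 3 non-collinear pairs give the exact interpolating
#' affine; more pairs give the least-squares fit.
#'
#' @param src n x 2 matrix of source (two-photon XY, um) points.
#' @param dst n x 2 matrix of destination (MRI XY, um) points.
#' @return An `affine2d` object with `A` (2x2 linear part), `b`
#'   (translation) and `residuals` (n x 2 fit residuals).
#' @export
fit_affine_xy <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < 3) stop("need at least 3 point pairs")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3)
    stop("degenerate input: source points are collinear")
  beta <- qr.solve(X, dst)          # 3 x 2: rows = (a1, a2, b)
  A <- t(beta[1:2, , drop = FALSE])
  b <- as.numeric(beta[3, ])
  if (abs(det(A)) <= 1e-12) stop("degenerate affine: singular linear part")
  res <- dst - (X %*% beta)
  structure(list(A = A, b = b, residuals = res), class = "affine2d")
}

#' Apply a fitted 2D affine to points
#' @param transform an `affine2d` from [fit_affine_xy()].
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_affine_xy <- function(transform, pts) {
  stopifnot(inherits(transform, "affine2d"))
  pts <- as.matrix(pts)
  sweep(pts %*% t(transform$A), 2, transform$b, "+")
}

point_in_quad <- function(px, py, quad) {
  # quad: 4 x 2, vertices in order; convex; inside-or-on test via
  # consistent cross-product signs
  s <- matrix(0, length(px), 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    ex <- quad[j, 1] - quad[i, 1]; ey <- quad[j, 2] - quad[i, 2]
    s[, i] <- ex * (py - quad[i, 2]) - ey * (px - quad[i, 1])
  }
  apply(s >= -1e-9, 1, all) | apply(s <= 1e-9, 1, all)
}

#' Rasterize a two-photon stack footprint into an MRI mask
#'
#' Transforms the square in-plane footprint of a stack through the fitted
#' affine and marks every MRI voxel whose in-plane center lies inside the
#' transformed quadrilateral.  In depth, exactly `n_planes` consecutive
#' planes starting at `surface_plane` are occupied (default 3, restricting
#' GMV extraction to the superficial cortex).
#'
#' @param transform an `affine2d` from [fit_affine_xy()].
#' @param stack_extent_xy side length of the square stack footprint (um),
#'   default 700.
#' @param mri_geometry a [voxel_geometry()] of the MRI grid.
#' @param surface_plane 1-based index of the first occupied z plane.
#' @param n_planes number of occupied planes.
#' @return A `mask_volume` object with logical `data`, `geometry`,
#'   `surface_plane` and `n_planes`.
#' @export
rasterize_stack_mask <- function(transform, stack_extent_xy = 700,
                                 mri_geometry, surface_plane = 1L,
                                 n_planes = 3L) {
  stopifnot(inherits(transform, "affine2d"),
            inherits(mri_geometry, "voxel_geometry"),
            stack_extent_xy > 0, n_planes >= 1)
  dims <- mri_geometry$shape
  if (surface_plane < 1L || surface_plane + n_planes - 1L > dims[1])
    stop("requested z planes fall outside the MRI grid")
  corners <- rbind(c(0, 0), c(stack_extent_xy, 0),
                   c(stack_extent_xy, stack_extent_xy),
                   c(0, stack_extent_xy))
  quad <- apply_affine_xy(transform, corners)
  xc <- voxel_centers(mri_geometry, 3)
  yc <- voxel_centers(mri_geometry, 2)
  px <- rep(xc, each = length(yc))
  py <- rep(yc, times = length(xc))
  inside <- matrix(point_in_quad(px, py, quad),
                   nrow = length(yc), ncol = length(xc))
  if (!any(inside)) stop("empty mask: footprint does not cover any voxel center")
  m <- array(FALSE, dim = dims)
  for (k in seq(surface_plane, surface_plane + n_planes - 1L))
    m[k, , ] <- inside
  structure(list(data = m, geometry = mri_geometry,
                 surface_plane = as.integer(surface_plane),
                 n_planes = as.integer(n_planes)),
            class = "mask_volume")
}

#' GMV change within a mask from a Jacobian field
#'
#' The gray-matter-volume change is read out as 100 times the mean Jacobian
#' determinant over the mask voxels (percent of baseline), together with the
#' slicewise (per-z-plane) profile over the mask's occupied planes.
#'
#' @param jfield a `jacobian_field` from [jacobian_determinant_field()].
#' @param mask a `mask_volume` sharing the geometry.
#' @return list with `percent` (scalar) and `profile` (data frame with
#'   `plane` and `percent` per occupied plane).
#' @export
gmv_change_in_mask <- function(jfield, mask) {
  stopifnot(inherits(jfield, "jacobian_field"),
            inherits(mask, "mask_volume"))
  if (!identical(jfield$geometry$shape, mask$geometry$shape))
    stop("jacobian field and mask geometries differ")
  if (!any(mask$data)) stop("empty mask")
  percent <- 100 * mean(jfield$data[mask$data])
  planes <- seq(mask$surface_plane, mask$surface_plane + mask$n_planes - 1L)
  prof <- vapply(planes, function(k) {
    sel <- mask$data[k, , ]
    100 * mean(jfield$data[k, , ][sel])
  }, numeric(1))
  list(percent = percent,
       profile = data.frame(plane = planes, percent = prof))
}

#' RARE acquisition parameters
#'
#' @param te_ms echo time (ms).
#' @param tr_s repetition time (s).
#' @param rare_factor RARE echo-train length.
#' @param echo_spacing_ms inter-echo spacing (ms).
#' @param t2_ms tissue T2 relaxation time (ms); 45 ms is a typical
#'   measured cortical value at 9.4 T.
#' @return An `acquisition_params` object including the derived trajectory
#'   time `tk_ms = rare_factor * echo_spacing_ms`.
#' @export
acquisition_params <- function(te_ms = 50, tr_s = 1.2, rare_factor = 16,
                               echo_spacing_ms = 6.25, t2_ms = 45) {
  stopifnot(te_ms > 0, tr_s > 0, rare_factor > 0, echo_spacing_ms > 0,
            t2_ms > 0)
  structure(list(te_ms = te_ms, tr_s = tr_s,
                 rare_factor = as.integer(rare_factor),
                 echo_spacing_ms = echo_spacing_ms, t2_ms = t2_ms,
                 tk_ms = rare_factor * echo_spacing_ms),
            class = "acquisition_params")
}

#' PSF blurring factor of a RARE echo train
#'
#' Evaluates the truncation-and-decay FWHM polynomial
#' `1.23 - 0.05 (Tk/T2) + 0.08 (Tk/T2)^2`, the factor by which T2 decay
#' along the echo train inflates the nominal voxel size in the phase-encode
#' direction.  At the reference acquisition (Tk = 100 ms, T2 = 45 ms)
#' this is 1.514.
#'
#' @param acq an [acquisition_params()], or a trajectory time in ms when
#'   `t2_ms` is also given.
#' @param t2_ms optional T2 override (ms).
#' @return dimensionless FWHM factor.
#' @export
psf_blurring_factor <- function(acq, t2_ms = NULL) {
  if (inherits(acq, "acquisition_params")) {
    tk <- acq$tk_ms
    t2 <- if (is.null(t2_ms)) acq$t2_ms else t2_ms
  } else {
    tk <- as.numeric(acq)
    if (is.null(t2_ms)) stop("t2_ms required when acq is a trajectory time")
    t2 <- t2_ms
  }
  if (t2 <= 0) stop("T2 must be positive")
  if (tk < 0) stop("trajectory time must be non-negative")
  r <- tk / t2
  1.23 - 0.05 * r + 0.08 * r^2
}
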