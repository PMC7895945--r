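#' Imaging model for rendering synthetic two-photon stacks
#'
#' @param attenuation_length_um depth attenuation length L (um); rendered
#'   peak decays as `exp(-z / L)`.  `Inf` disables attenuation.  The default
#'   200 um is a typical effective attenuation length for two-photon
#'   excitation in cortex.
#' @param offset_adu constant background offset (ADU).
#' @param noise_sd_adu additive Gaussian noise standard deviation (ADU).
#' @param vessels list of vessel cylinders, each a list with `point`
#'   (xyz um on the axis), `direction` (xyz, need not be unit length) and
#'   `radius_um`; voxels within the cylinder carry offset-only signal
#'   (the vessel "shadow").
#' @param blankout_planes integer vector of 1-based z-plane indices zeroed
#'   after rendering (acquisition blankout artifact).
#' @return An `imaging_model` object.
#' @export
imaging_model <- function(attenuation_length_um = 200, offset_adu = 100,
                          noise_sd_adu = 10, vessels = list(),
                          blankout_planes = integer(0)) {
  stopifnot(attenuation_length_um > 0, offset_adu >= 0, noise_sd_adu >= 0)
  structure(list(attenuation_length_um = attenuation_length_um,
                 offset_adu = offset_adu, noise_sd_adu = noise_sd_adu,
                 vessels = vessels,
                 blankout_planes = as.integer(blankout_planes)),
            class = "imaging_model")
}

#' Render a ground-truth field into an image stack
#'
#' Each nucleus is rendered as an anisotropic Gaussian blob with per-axis
#' standard deviation `radius / 2` and peak brightness `peak * exp(-z / L)`.
#' Voxels inside vessel cylinders are set to offset-only signal, blankout
#' planes are zeroed, then Gaussian noise is added and values are clipped to
#' the unsigned 16-bit range.
#'
#' @param field a `ground_truth_field` whose extent fits `geometry`.
#' @param geometry a [voxel_geometry()].
#' @param imaging an [imaging_model()].
#' @param seed integer RNG seed for the noise.
#' @param truncate_sd blob support half-width in standard deviations.
#' @return An [image_stack()].
#' @export
render_stack <- function(field, geometry = voxel_geometry(),
                         imaging = imaging_model(), seed = 1L,
                         truncate_sd = 3.5) {
  stopifnot(inherits(field, "ground_truth_field"),
            inherits(geometry, "voxel_geometry"),
            inherits(imaging, "imaging_model"))
  ext <- geometry$extent_um
  if (field$extent_um[["z"]] > ext[1] + 1e-9 ||
      field$extent_um[["y"]] > ext[2] + 1e-9 ||
      field$extent_um[["x"]] > ext[3] + 1e-9)
    stop("field extent does not fit the rendering geometry")
  set.seed(as.integer(seed))
  dims <- geometry$shape
  img <- array(0, dim = dims)
  zc <- voxel_centers(geometry, 1)
  yc <- voxel_centers(geometry, 2)
  xc <- voxel_centers(geometry, 3)
  vs <- geometry$voxel_size
  nuc <- field$nuclei
  L <- imaging$attenuation_length_um
  for (i in seq_len(nrow(nuc))) {
    sdz <- nuc$radius_z_um[i] / 2
    sdy <- nuc$radius_y_um[i] / 2
    sdx <- nuc$radius_x_um[i] / 2
    if (any(c(sdz, sdy, sdx) * 2 < vs)) {
      warning(sprintf("nucleus %d radius below one voxel; rendered as a single voxel",
                      nuc$id[i]))
      iz <- which.min(abs(zc - nuc$z_um[i]))
      iy <- which.min(abs(yc - nuc$y_um[i]))
      ix <- which.min(abs(xc - nuc$x_um[i]))
      peak <- nuc$peak[i] * if (is.finite(L)) exp(-nuc$z_um[i] / L) else 1
      img[iz, iy, ix] <- img[iz, iy, ix] + peak
      next
    }
    zi <- which(abs(zc - nuc$z_um[i]) <= truncate_sd * sdz)
    yi <- which(abs(yc - nuc$y_um[i]) <= truncate_sd * sdy)
    xi <- which(abs(xc - nuc$x_um[i]) <= truncate_sd * sdx)
    if (!length(zi) || !length(yi) || !length(xi)) next
    gz <- exp(-((zc[zi] - nuc$z_um[i])^2) / (2 * sdz^2))
    gy <- exp(-((yc[yi] - nuc$y_um[i])^2) / (2 * sdy^2))
    gx <- exp(-((xc[xi] - nuc$x_um[i])^2) / (2 * sdx^2))
    peak <- nuc$peak[i] * if (is.finite(L)) exp(-nuc$z_um[i] / L) else 1
    blob <- peak * outer(outer(gz, gy), gx)
    img[zi, yi, xi] <- img[zi, yi, xi] + blob
  }
  img <- img + imaging$offset_adu
  # vessel shadows: offset-only inside each cylinder
  if (length(imaging$vessels)) {
    grid_x <- array(rep(xc, each = dims[1] * dims[2]), dim = dims)
    grid_y <- array(rep(rep(yc, each = dims[1]), times = dims[3]), dim = dims)
    grid_z <- array(rep(zc, times = dims[2] * dims[3]), dim = dims)
    for (v in imaging$vessels) {
      d <- v$direction / sqrt(sum(v$direction^2))
      rx <- grid_x - v$point[1]; ry <- grid_y - v$point[2]
      rz <- grid_z - v$point[3]
      t <- rx * d[1] + ry * d[2] + rz * d[3]
      dist2 <- (rx - t * d[1])^2 + (ry - t * d[2])^2 + (rz - t * d[3])^2
      img[dist2 < v$radius_um^2] <- imaging$offset_adu
    }
  }
  bp <- imaging$blankout_planes
  bp <- bp[bp >= 1L & bp <= dims[1]]
  if (length(bp)) img[bp, , ] <- 0
  if (imaging$noise_sd_adu > 0)
    img <- img + array(rnorm(prod(dims), 0, imaging$noise_sd_adu), dim = dims)
  img <- round(pmin(pmax(img, 0), 65535))
  image_stack(img, geometry)
}

#' Smooth sinusoidal deformation field
#'
#' Builds a differentiable displacement function `u(x, y, z)` as a sum of
#' random-phase sinusoids with wavelengths of order `period_um`, useful as a
#' ground-truth nonlinear deformation for MRI phantoms.  Peak displacement
#' magnitude per axis is about `amplitude_um`.
#'
#' @param amplitude_um displacement amplitude per axis (um).
#' @param period_um spatial period of the modulation (um).
#' @param seed integer RNG seed fixing the phases and directions.
#' @return function `(x, y, z) -> n x 3 matrix` of displacements (um).
#' @export
smooth_deformation <- function(amplitude_um = 5, period_um = 2000,
                               seed = 1L) {
  set.seed(as.integer(seed))
  k <- 2 * pi / period_um
  ph <- matrix(runif(9, 0, 2 * pi), 3, 3)
  w <- matrix(rnorm(9), 3, 3)
  w <- w / sqrt(rowSums(w^2))
  force(amplitude_um)
  function(x, y, z) {
    out <- matrix(0, length(x), 3)
    for (a in 1:3)
      out[, a] <- amplitude_um *
        sin(k * (w[a, 1] * x + w[a, 2] * y + w[a, 3] * z) + ph[a, 1])
    out
  }
}

trilinear_sample <- function(vol, geometry, x, y, z) {
  vs <- geometry$voxel_size; dims <- geometry$shape
  # continuous voxel coordinates (1-based, voxel centers at i)
  fz <- z / vs[1] + 0.5; fy <- y / vs[2] + 0.5; fx <- x / vs[3] + 0.5
  fz <- pmin(pmax(fz, 1), dims[1]); fy <- pmin(pmax(fy, 1), dims[2])
  fx <- pmin(pmax(fx, 1), dims[3])
  z0 <- pmin(floor(fz), dims[1] - 1L); y0 <- pmin(floor(fy), dims[2] - 1L)
  x0 <- pmin(floor(fx), dims[3] - 1L)
  wz <- fz - z0; wy <- fy - y0; wx <- fx - x0
  at <- function(iz, iy, ix) vol[cbind(iz, iy, ix)]
  v000 <- at(z0, y0, x0);     v100 <- at(z0 + 1, y0, x0)
  v010 <- at(z0, y0 + 1, x0); v110 <- at(z0 + 1, y0 + 1, x0)
  v001 <- at(z0, y0, x0 + 1); v101 <- at(z0 + 1, y0, x0 + 1)
  v011 <- at(z0, y0 + 1, x0 + 1); v111 <- at(z0 + 1, y0 + 1, x0 + 1)
  (1 - wx) * ((1 - wy) * ((1 - wz) * v000 + wz * v100) +
              wy * ((1 - wz) * v010 + wz * v110)) +
    wx * ((1 - wy) * ((1 - wz) * v001 + wz * v101) +
          wy * ((1 - wz) * v011 + wz * v111))
}

#' Generate an MRI-like phantom pair with known deformation
#'
#' Builds a smooth baseline volume (a large tissue blob plus low-frequency
#' texture), a forward deformation `phi(x) = x + u(x)` mapping baseline to
#' follow-up space, and the follow-up volume obtained by resampling the
#' baseline through the (approximate) inverse deformation, plus noise.  The
#' per-voxel displacement `u` is returned on the baseline grid so that the
#' Jacobian determinant of `I + grad(u)` is the local volume-change factor
#' of the ground truth.
#'
#' @param deformation either a 3x3 matrix `A` (affine about the volume
#'   center, `phi(x) = c + A (x - c)`), or a displacement function as
#'   returned by [smooth_deformation()], or `NULL` for identity.
#' @param mri_geometry a [voxel_geometry()]; default emulates a
#'   156 x 78 x 78 um RARE grid on a small matrix.
#' @param noise_sd additive Gaussian noise on the follow-up volume.
#' @param seed integer RNG seed.
#' @return list with `baseline` ([image_stack()]), `followup`
#'   ([image_stack()]) and `displacement` (a [deformation_field()]).
#' @export
generate_mri_phantom <- function(deformation = NULL,
                                 mri_geometry = voxel_geometry(
                                   c(24L, 48L, 48L), c(156, 78, 78)),
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(mri_geometry, "voxel_geometry"))
  set.seed(as.integer(seed))
  dims <- mri_geometry$shape
  zc <- voxel_centers(mri_geometry, 1)
  yc <- voxel_centers(mri_geometry, 2)
  xc <- voxel_centers(mri_geometry, 3)
  ext <- mri_geometry$extent_um
  ctr <- ext / 2
  gz <- exp(-((zc - ctr[1])^2) / (2 * (ext[1] / 3)^2))
  gy <- exp(-((yc - ctr[2])^2) / (2 * (ext[2] / 3)^2))
  gx <- exp(-((xc - ctr[3])^2) / (2 * (ext[3] / 3)^2))
  base <- 1000 * outer(outer(gz, gy), gx)
  # low-frequency texture so that resampling differences are visible
  tex <- smooth_deformation(amplitude_um = 1, period_um = min(ext) / 2,
                            seed = as.integer(seed) + 13L)
  grid_x <- rep(xc, each = dims[1] * dims[2])
  grid_y <- rep(rep(yc, each = dims[1]), times = dims[3])
  grid_z <- rep(zc, times = dims[2] * dims[3])
  base <- base + 100 * array(tex(grid_x, grid_y, grid_z)[, 1], dim = dims)
  base <- base - min(base)
  ctr_xyz <- c(ctr[3], ctr[2], ctr[1])   # center in (x, y, z)
  if (is.null(deformation)) {
    ufun <- function(x, y, z) matrix(0, length(x), 3)
    inv <- function(x, y, z) cbind(x, y, z)
  } else if (is.matrix(deformation)) {
    A <- deformation
    stopifnot(nrow(A) == 3, ncol(A) == 3)
    Ainv <- solve(A)
    ufun <- function(x, y, z) {
      p <- cbind(x - ctr_xyz[1], y - ctr_xyz[2], z - ctr_xyz[3])
      p %*% t(A) - p
    }
    inv <- function(x, y, z) {
      p <- cbind(x - ctr_xyz[1], y - ctr_xyz[2], z - ctr_xyz[3])
      sweep(p %*% t(Ainv), 2, ctr_xyz, "+")
    }
  } else if (is.function(deformation)) {
    ufun <- deformation
    inv <- function(x, y, z) {
      # fixed-point inversion of x + u(x) = y for small smooth u
      px <- x; py <- y; pz <- z
      for (it in 1:4) {
        u <- ufun(px, py, pz)
        px <- x - u[, 1]; py <- y - u[, 2]; pz <- z - u[, 3]
      }
      cbind(px, py, pz)
    }
  } else stop("deformation must be NULL, a 3x3 matrix, or a function")
  u <- ufun(grid_x, grid_y, grid_z)
  if (any(!is.finite(u))) stop("deformation produced non-finite displacements")
  maxdisp <- max(abs(u))
  if (maxdisp > min(ext) / 2)
    stop("displacement exceeds the phantom domain")
  src <- inv(grid_x, grid_y, grid_z)
  fup <- array(trilinear_sample(base, mri_geometry,
                                src[, 1], src[, 2], src[, 3]), dim = dims)
  if (noise_sd > 0)
    fup <- fup + array(rnorm(prod(dims), 0, noise_sd), dim = dims)
  fup <- pmax(fup, 0)
  disp <- array(0, dim = c(dims, 3L))
  disp[, , , 1] <- array(u[, 3], dim = dims)   # z component
  disp[, , , 2] <- array(u[, 2], dim = dims)   # y component
  disp[, , , 3] <- array(u[, 1], dim = dims)   # x component
  list(baseline = image_stack(base, mri_geometry),
       followup = image_stack(fup, mri_geometry),
       displacement = deformation_field(disp, mri_geometry))
}
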