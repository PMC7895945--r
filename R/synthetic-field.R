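#' Layered nucleus density profile
#'
#' Returns a function `f(z)` giving the expected nucleus intensity
#' (nuclei per cubic micrometer) at cortical depth `z` (um).  The default
#' emulates the layered neocortex seen in nucleus-labeled stacks: a sparse
#' molecular layer above `sparse_depth_um` followed by uniform density.  The
#' default base intensity is calibrated so that the depth-averaged density
#' over a 700-um stack is about 5.7e-5 nuclei/um^3, i.e. roughly 19,500
#' nuclei in a 700 x 700 x 700 um volume.
#'
#' @param base_intensity nuclei per um^3 below the sparse layer.
#' @param sparse_depth_um depth extent of the sparse superficial layer.
#' @param sparse_factor relative intensity of the sparse layer.
#' @return function mapping depth (um, vectorized) to intensity (/um^3).
#' @export
layer_profile <- function(base_intensity = 6.28e-5,
                          sparse_depth_um = 100,
                          sparse_factor = 0.35) {
  stopifnot(base_intensity >= 0, sparse_depth_um >= 0,
            sparse_factor >= 0)
  force(base_intensity); force(sparse_depth_um); force(sparse_factor)
  function(z) {
    base_intensity * ifelse(z < sparse_depth_um, sparse_factor, 1)
  }
}

#' Uniform nucleus density profile
#' @param intensity nuclei per um^3.
#' @return function mapping depth to the constant intensity.
#' @export
uniform_profile <- function(intensity) {
  force(intensity)
  function(z) rep_len(intensity, length(z))
}

#' Two-component lognormal nucleus-volume mixture
#'
#' Glial and neuronal nuclei are modeled as lognormal volume distributions.
#' Defaults: glia median 600 um^3, neurons median 1450 um^3, neuron fraction
#' 0.55, lognormal sdlog 0.2 for both components, giving a mixture mean of
#' about 1089 um^3, close to the ~1054 um^3 baseline mean observed per
#' stack.
#'
#' @param glia_median_um3,neuron_median_um3 component medians (um^3).
#' @param glia_sdlog,neuron_sdlog lognormal shape parameters.
#' @param neuron_fraction probability that a nucleus is neuronal.
#' @return A `size_mixture` object.
#' @export
size_mixture <- function(glia_median_um3 = 600, neuron_median_um3 = 1450,
                         glia_sdlog = 0.2, neuron_sdlog = 0.2,
                         neuron_fraction = 0.55) {
  stopifnot(glia_median_um3 > 0, neuron_median_um3 > 0,
            glia_sdlog >= 0, neuron_sdlog >= 0,
            neuron_fraction >= 0, neuron_fraction <= 1)
  structure(list(glia_median_um3 = glia_median_um3,
                 neuron_median_um3 = neuron_median_um3,
                 glia_sdlog = glia_sdlog, neuron_sdlog = neuron_sdlog,
                 neuron_fraction = neuron_fraction),
            class = "size_mixture")
}

#' Theoretical mean of a size mixture
#' @param mixture a [size_mixture()].
#' @return mean nucleus volume in um^3.
#' @export
size_mixture_mean <- function(mixture) {
  stopifnot(inherits(mixture, "size_mixture"))
  g <- mixture$glia_median_um3 * exp(mixture$glia_sdlog^2 / 2)
  n <- mixture$neuron_median_um3 * exp(mixture$neuron_sdlog^2 / 2)
  (1 - mixture$neuron_fraction) * g + mixture$neuron_fraction * n
}

draw_mixture <- function(mixture, n, neuron_fraction = NULL) {
  if (is.null(neuron_fraction)) neuron_fraction <- mixture$neuron_fraction
  cls <- ifelse(runif(n) < neuron_fraction, "neuron", "glia")
  vol <- numeric(n)
  isn <- cls == "neuron"
  vol[isn] <- rlnorm(sum(isn), log(mixture$neuron_median_um3),
                     mixture$neuron_sdlog)
  vol[!isn] <- rlnorm(sum(!isn), log(mixture$glia_median_um3),
                      mixture$glia_sdlog)
  list(class = cls, volume_um3 = vol)
}

#' Generate a ground-truth nucleus field
#'
#' Draws nucleus centroids from an inhomogeneous Poisson process along depth
#' (density given by `layer_profile`, uniform in-plane) with a hard-core
#' minimum separation enforced by dart throwing: the target count is a
#' Poisson draw from the integrated intensity, and candidate points are
#' proposed until the target is reached or the attempt budget is exhausted.
#' Nucleus class and volume come from the two-component lognormal mixture;
#' the nucleus radius is the radius of the sphere of the drawn volume.  A
#' random subset of nuclei is designated as stable fiducial markers.
#'
#' @param geometry a [voxel_geometry()]; its physical extent defines the
#'   field's bounding box.
#' @param profile depth-intensity function from [layer_profile()] or
#'   [uniform_profile()].
#' @param mixture a [size_mixture()].
#' @param min_separation_um hard-core distance between centroids (um).
#' @param n_fiducials number of nuclei marked as fiducials (clamped to the
#'   realized count); more than 30 is recommended for reliable hull
#'   volumetry.
#' @param peak_intensity rendered peak brightness (ADU) per nucleus.
#' @param seed integer RNG seed; same seed gives bit-identical fields.
#' @param max_attempts_per_point dart-throwing budget multiplier.
#' @param n exact nucleus count; when given, the Poisson draw of the total
#'   is replaced by this fixed count (a conditioned, binomial-process
#'   field), useful for phantoms with a known number of objects.
#' @param margin_um inset margin: centroids are kept at least this far from
#'   every face of the box (phantoms rendered fully inside the field of
#'   view); intensity integration still uses the full box.
#' @return A `ground_truth_field`: data frame `nuclei` with columns `id`,
#'   `x_um`, `y_um`, `z_um`, `radius_x_um`, `radius_y_um`, `radius_z_um`,
#'   `peak`, `class`, `volume_um3`; plus `extent_um` (x, y, z), numeric
#'   `fiducial_ids`, `min_separation_um` and `provenance`.
#' @export
generate_nucleus_field <- function(geometry = voxel_geometry(),
                                   profile = layer_profile(),
                                   mixture = size_mixture(),
                                   min_separation_um = 8,
                                   n_fiducials = 40,
                                   peak_intensity = 3000,
                                   seed = 1L,
                                   max_attempts_per_point = 200,
                                   n = NULL, margin_um = 0) {
  stopifnot(inherits(geometry, "voxel_geometry"), is.function(profile),
            min_separation_um >= 0)
  ext <- geometry$extent_um          # (z, y, x)
  depth <- ext[1]
  area <- ext[2] * ext[3]
  set.seed(as.integer(seed))
  # integrated intensity over the box (fine trapezoid along z)
  zg <- seq(0, depth, length.out = 2048)
  lam_z <- profile(zg)
  if (any(lam_z < 0)) stop("layer profile must be non-negative")
  total <- sum((lam_z[-1] + lam_z[-length(lam_z)]) / 2 * diff(zg)) * area
  n_target <- if (is.null(n)) rpois(1, total) else as.integer(n)
  lam_max <- max(lam_z)
  pts <- matrix(numeric(0), ncol = 3)
  if (n_target > 0) {
    if (lam_max <= 0) stop("layer profile is identically zero but target count > 0")
    acc <- matrix(NA_real_, nrow = n_target, ncol = 3)  # x, y, z
    n_acc <- 0L
    attempts <- 0L
    budget <- max_attempts_per_point * n_target
    # spatial hash for the hard-core test
    cell <- max(min_separation_um, 1e-6)
    hash <- new.env(hash = TRUE, parent = emptyenv())
    keyof <- function(i, j, k) paste(i, j, k, sep = ",")
    while (n_acc < n_target) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop(sprintf(
          "packing error: only %d of %d nuclei placed after %d attempts; reduce min_separation_um or density",
          n_acc, n_target, attempts - 1L))
      z <- runif(1, margin_um, depth - margin_um)
      if (runif(1) * lam_max > profile(z)) next   # depth-profile thinning
      x <- runif(1, margin_um, ext[3] - margin_um)
      y <- runif(1, margin_um, ext[2] - margin_um)
      ok <- TRUE
      if (min_separation_um > 0 && n_acc > 0L) {
        ci <- floor(x / cell); cj <- floor(y / cell); ck <- floor(z / cell)
        for (i in (ci - 1):(ci + 1)) {
          for (j in (cj - 1):(cj + 1)) {
            for (k in (ck - 1):(ck + 1)) {
              ids <- hash[[keyof(i, j, k)]]
              if (!is.null(ids)) {
                d2 <- (acc[ids, 1] - x)^2 + (acc[ids, 2] - y)^2 +
                  (acc[ids, 3] - z)^2
                if (any(d2 < min_separation_um^2)) { ok <- FALSE; break }
              }
            }
            if (!ok) break
          }
          if (!ok) break
        }
      }
      if (!ok) next
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- c(x, y, z)
      if (min_separation_um > 0) {
        key <- keyof(floor(x / cell), floor(y / cell), floor(z / cell))
        hash[[key]] <- c(hash[[key]], n_acc)
      }
    }
    pts <- acc[seq_len(n_acc), , drop = FALSE]
  }
  n <- nrow(pts)
  mix <- draw_mixture(mixture, n)
  r <- (3 * mix$volume_um3 / (4 * pi))^(1 / 3)
  nuclei <- data.frame(
    id = seq_len(n),
    x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
    radius_x_um = r, radius_y_um = r, radius_z_um = r,
    peak = rep_len(peak_intensity, n),
    class = mix$class,
    volume_um3 = mix$volume_um3,
    stringsAsFactors = FALSE)
  fid <- if (n > 0) sort(sample(nuclei$id, min(n_fiducials, n))) else integer(0)
  structure(
    list(nuclei = nuclei,
         extent_um = c(x = ext[3], y = ext[2], z = ext[1]),
         fiducial_ids = fid,
         min_separation_um = min_separation_um,
         provenance = list(seed = as.integer(seed), preset = "baseline")),
    class = "ground_truth_field")
}

#' @export
print.ground_truth_field <- function(x, ...) {
  cat(sprintf("<ground_truth_field> %d nuclei (%d fiducials) in %.0f x %.0f x %.0f um (x,y,z), preset '%s'\n",
              nrow(x$nuclei), length(x$fiducial_ids),
              x$extent_um[1], x$extent_um[2], x$extent_um[3],
              x$provenance$preset))
  invisible(x)
}

#' Longitudinal change preset
#'
#' Parameters describing how a ground-truth field evolves between two
#' imaging timepoints.
#'
#' @param volume_change_fraction fractional tissue volume change (> -1);
#'   e.g. -0.05 is a 5 percent shrinkage.
#' @param cell_loss_probability per-nucleus probability of disappearing.
#' @param cell_gain_rate new nuclei per um^3 appearing at the later
#'   timepoint.
#' @param nucleus_volume_scale multiplicative change of nucleus volumes.
#' @param composition_shift additive change of the neuron fraction applied
#'   to gained cells.
#' @param fiducial_noise_sd re-localization noise (um per axis, Gaussian)
#'   added to fiducial coordinates only, emulating manual re-identification
#'   error.
#' @return A `longitudinal_preset` object.
#' @export
longitudinal_preset <- function(volume_change_fraction = 0,
                                cell_loss_probability = 0,
                                cell_gain_rate = 0,
                                nucleus_volume_scale = 1,
                                composition_shift = 0,
                                fiducial_noise_sd = 0) {
  stopifnot(volume_change_fraction > -1,
            cell_loss_probability >= 0, cell_loss_probability <= 1,
            cell_gain_rate >= 0, nucleus_volume_scale > 0,
            fiducial_noise_sd >= 0)
  structure(list(volume_change_fraction = volume_change_fraction,
                 cell_loss_probability = cell_loss_probability,
                 cell_gain_rate = cell_gain_rate,
                 nucleus_volume_scale = nucleus_volume_scale,
                 composition_shift = composition_shift,
                 fiducial_noise_sd = fiducial_noise_sd),
            class = "longitudinal_preset")
}

#' Study-emulating longitudinal presets
#'
#' `"week1"` emulates the observed 1-week state: hull volume at 98.74
#' percent of baseline and a drop of detected cells to about 91 percent.
#' `"week12"` emulates the 12-week state: tissue shrinkage to 95 percent of
#' baseline with cell count at about 93 percent.  Fiducial re-localization
#' noise defaults to 1 um per axis in both.
#'
#' @param name `"week1"`, `"week12"` or `"identity"`.
#' @return A [longitudinal_preset()].
#' @export
study_preset <- function(name = c("week12", "week1", "identity")) {
  name <- match.arg(name)
  switch(name,
    week12 = longitudinal_preset(volume_change_fraction = -0.05,
                                 cell_loss_probability = 0.07,
                                 fiducial_noise_sd = 1),
    week1 = longitudinal_preset(volume_change_fraction = -0.0126,
                                cell_loss_probability = 0.09,
                                fiducial_noise_sd = 1),
    identity = longitudinal_preset())
}

#' Apply a longitudinal preset to a ground-truth field
#'
#' Coordinates are mapped by an isotropic affine with per-axis scale
#' `(1 + volume_change_fraction)^(1/3)` about the extent center, so the
#' convex hull of any corresponding point set changes volume by exactly
#' `1 + volume_change_fraction`.  Non-fiducial nuclei are lost with
#' probability `cell_loss_probability` (fiducials are stable,
#' re-identifiable cells by definition and are exempt); gains are appended
#' with fresh ids; nucleus volumes are scaled; fiducial coordinates are
#' additionally jittered by Gaussian noise of sd `fiducial_noise_sd`.
#'
#' @param field a `ground_truth_field`.
#' @param preset a [longitudinal_preset()].
#' @param seed integer RNG seed.
#' @return list with `field` (the later-timepoint field) and
#'   `correspondence`, a data frame `old_id`, `new_id` listing survivors.
#' @export
apply_longitudinal_preset <- function(field, preset, seed = 1L) {
  stopifnot(inherits(field, "ground_truth_field"),
            inherits(preset, "longitudinal_preset"))
  set.seed(as.integer(seed))
  nuc <- field$nuclei
  s <- (1 + preset$volume_change_fraction)^(1 / 3)
  ctr <- field$extent_um / 2                      # (x, y, z)
  nuc$x_um <- ctr[["x"]] + s * (nuc$x_um - ctr[["x"]])
  nuc$y_um <- ctr[["y"]] + s * (nuc$y_um - ctr[["y"]])
  nuc$z_um <- ctr[["z"]] + s * (nuc$z_um - ctr[["z"]])
  keep <- rbinom(nrow(nuc), 1, 1 - preset$cell_loss_probability) == 1
  keep[nuc$id %in% field$fiducial_ids] <- TRUE
  nuc <- nuc[keep, , drop = FALSE]
  nuc$volume_um3 <- nuc$volume_um3 * preset$nucleus_volume_scale
  rs <- preset$nucleus_volume_scale^(1 / 3)
  nuc$radius_x_um <- nuc$radius_x_um * rs
  nuc$radius_y_um <- nuc$radius_y_um * rs
  nuc$radius_z_um <- nuc$radius_z_um * rs
  correspondence <- data.frame(old_id = nuc$id, new_id = nuc$id)
  # gains: uniform in the deformed box, fresh ids
  vol_box <- prod(field$extent_um)
  n_gain <- rpois(1, preset$cell_gain_rate * vol_box)
  if (n_gain > 0) {
    mix <- draw_mixture(size_mixture(), n_gain,
                        neuron_fraction =
                          min(1, max(0, size_mixture()$neuron_fraction +
                                       preset$composition_shift)))
    r <- (3 * mix$volume_um3 / (4 * pi))^(1 / 3)
    lo <- ctr * (1 - s); hi <- ctr * (1 - s) + s * field$extent_um
    gained <- data.frame(
      id = max(field$nuclei$id, 0L) + seq_len(n_gain),
      x_um = runif(n_gain, lo[["x"]], hi[["x"]]),
      y_um = runif(n_gain, lo[["y"]], hi[["y"]]),
      z_um = runif(n_gain, lo[["z"]], hi[["z"]]),
      radius_x_um = r, radius_y_um = r, radius_z_um = r,
      peak = rep_len(field$nuclei$peak[1], n_gain),
      class = mix$class,
      volume_um3 = mix$volume_um3,
      stringsAsFactors = FALSE)
    nuc <- rbind(nuc, gained)
  }
  fid <- intersect(field$fiducial_ids, nuc$id)
  if (preset$fiducial_noise_sd > 0 && length(fid) > 0) {
    i <- match(fid, nuc$id)
    nuc$x_um[i] <- nuc$x_um[i] + rnorm(length(i), 0, preset$fiducial_noise_sd)
    nuc$y_um[i] <- nuc$y_um[i] + rnorm(length(i), 0, preset$fiducial_noise_sd)
    nuc$z_um[i] <- nuc$z_um[i] + rnorm(length(i), 0, preset$fiducial_noise_sd)
  }
  out <- field
  out$nuclei <- nuc
  out$fiducial_ids <- fid
  out$provenance <- list(seed = as.integer(seed), preset = "derived")
  list(field = out, correspondence = correspondence)
}

#' Extract the ground-truth nucleus table of a field
#'
#' Converts a `ground_truth_field` into the standard nucleus table used by
#' the metrics module, attaching the given keys.
#'
#' @param field a `ground_truth_field`.
#' @param animal_id,position_id,timepoint key columns to attach.
#' @return data frame with the [nucleus_table()] columns.
#' @export
field_nucleus_table <- function(field, animal_id = "a1", position_id = "p1",
                                timepoint = 0) {
  stopifnot(inherits(field, "ground_truth_field"))
  nuc <- field$nuclei
  data.frame(animal_id = animal_id, position_id = position_id,
             timepoint = timepoint, nucleus_id = nuc$id,
             x_um = nuc$x_um, y_um = nuc$y_um, z_um = nuc$z_um,
             volume_voxels = NA_real_, volume_um3 = nuc$volume_um3,
             stringsAsFactors = FALSE)
}

#' Extract the fiducial coordinate table of a field
#'
#' @param field a `ground_truth_field`.
#' @param animal_id,position_id,timepoint key columns to attach.
#' @return data frame with columns `animal_id`, `position_id`, `timepoint`,
#'   `fiducial_id`, `x_um`, `y_um`, `z_um`.
#' @export
field_fiducial_table <- function(field, animal_id = "a1", position_id = "p1",
                                 timepoint = 0) {
  stopifnot(inherits(field, "ground_truth_field"))
  i <- match(field$fiducial_ids, field$nuclei$id)
  data.frame(animal_id = animal_id, position_id = position_id,
             timepoint = timepoint, fiducial_id = field$nuclei$id[i],
             x_um = field$nuclei$x_um[i], y_um = field$nuclei$y_um[i],
             z_um = field$nuclei$z_um[i], stringsAsFactors = FALSE)
}
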