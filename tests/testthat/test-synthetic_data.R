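test_that("generated counts follow the Poisson intensity", {
  # 200 um cube at 5.7e-5 /um^3: lambda * V = 456; with no hard core the
  # realized count is exactly Poisson, so it must fall inside the central
  # 99% interval
  g <- voxel_geometry(c(100L, 200L, 200L), c(2, 1, 1))
  f <- generate_nucleus_field(g, uniform_profile(5.7e-5),
                              min_separation_um = 0, seed = 1)
  lam <- 5.7e-5 * prod(g$extent_um)
  expect_gte(nrow(f$nuclei), qpois(0.005, lam))
  expect_lte(nrow(f$nuclei), qpois(0.995, lam))
})

test_that("hard-core separation and layer gating hold by construction", {
  g <- voxel_geometry(c(100L, 150L, 150L), c(2, 1, 1))
  for (seed in 1:3) {
    f <- generate_nucleus_field(g, uniform_profile(4e-5),
                                min_separation_um = 8, seed = seed)
    pts <- cbind(f$nuclei$x_um, f$nuclei$y_um, f$nuclei$z_um)
    expect_gte(nucleomorph:::cpp_min_pairwise_distance(pts), 8)
  }
  # zero intensity above 100 um depth -> no centroid with z < 100
  f0 <- generate_nucleus_field(g, layer_profile(6e-5, sparse_depth_um = 100,
                                                sparse_factor = 0),
                               seed = 4)
  expect_true(all(f0$nuclei$z_um >= 100))
  # fiducials are a subset of nucleus ids
  expect_true(all(f0$fiducial_ids %in% f0$nuclei$id))
})

test_that("same seed gives bit-identical fields; packing failure errors", {
  g <- voxel_geometry(c(50L, 80L, 80L), c(2, 1, 1))
  f1 <- generate_nucleus_field(g, uniform_profile(5e-5), seed = 9)
  f2 <- generate_nucleus_field(g, uniform_profile(5e-5), seed = 9)
  expect_identical(f1, f2)
  expect_error(
    generate_nucleus_field(g, uniform_profile(1e-3),
                           min_separation_um = 30, seed = 1,
                           max_attempts_per_point = 20),
    "packing")
})

test_that("longitudinal preset: identity, exact hull scaling, cell loss", {
  g <- voxel_geometry(c(100L, 150L, 150L), c(2, 1, 1))
  f <- generate_nucleus_field(g, uniform_profile(4e-5), seed = 2)
  id <- apply_longitudinal_preset(f, longitudinal_preset(), seed = 5)
  expect_equal(id$field$nuclei, f$nuclei)
  expect_identical(id$correspondence$old_id, id$correspondence$new_id)

  # -5% preset, no noise: hull volume of corresponding fiducials scales by
  # exactly 0.95 (affine image of the hull)
  pre <- longitudinal_preset(volume_change_fraction = -0.05)
  lt <- apply_longitudinal_preset(f, pre, seed = 6)
  i0 <- match(f$fiducial_ids, f$nuclei$id)
  i1 <- match(f$fiducial_ids, lt$field$nuclei$id)
  h0 <- hull_volume(cbind(f$nuclei$x_um, f$nuclei$y_um, f$nuclei$z_um)[i0, ])
  h1 <- hull_volume(cbind(lt$field$nuclei$x_um, lt$field$nuclei$y_um,
                          lt$field$nuclei$z_um)[i1, ])
  expect_equal(h1$volume_um3 / h0$volume_um3, 0.95, tolerance = 1e-9)

  # Bernoulli cell loss: mean survivors over 200 seeds within 2 SE of 900
  # (fiducials are exempt, so use a field without them)
  gsm <- voxel_geometry(c(60L, 100L, 100L), c(2, 1, 1))
  fb <- generate_nucleus_field(gsm, uniform_profile(1e-3),
                               min_separation_um = 0, n_fiducials = 0,
                               seed = 7, n = 1000)
  loss <- longitudinal_preset(cell_loss_probability = 0.1)
  surv <- vapply(1:200, function(s)
    nrow(apply_longitudinal_preset(fb, loss, seed = s)$field$nuclei),
    numeric(1))
  se <- sqrt(1000 * 0.1 * 0.9 / 200)
  expect_lt(abs(mean(surv) - 900), 2 * se)
})

test_that("render_stack: background statistics, countability, vessels", {
  g <- voxel_geometry(c(30L, 40L, 40L), c(2, 1, 1))
  empty <- generate_nucleus_field(g, uniform_profile(0), seed = 1)
  st <- render_stack(empty, g, imaging_model(offset_adu = 100,
                                             noise_sd_adu = 2), seed = 3)
  nvox <- prod(g$shape)
  expect_lt(abs(mean(st$data) - 100), 3 * 2 / sqrt(nvox) + 0.5)  # + rounding

  # 10 well-separated nuclei, noise 0: thresholded component count = 10
  g2 <- voxel_geometry(c(60L, 120L, 120L), c(2, 1, 1))
  f10 <- generate_nucleus_field(g2, uniform_profile(10 / prod(g2$extent_um)),
                                min_separation_um = 40, seed = 8, n = 10,
                                margin_um = 15)
  st10 <- render_stack(f10, g2, imaging_model(attenuation_length_um = Inf,
                                              offset_adu = 100,
                                              noise_sd_adu = 0), seed = 1)
  mask <- st10$data > 100 + max(f10$nuclei$peak) / 2
  lab <- nucleomorph:::cpp_label_components(as.logical(mask), g2$shape)
  expect_identical(length(setdiff(unique(as.vector(lab)), 0L)), 10L)

  # vessel cylinder: offset-only inside
  ves <- imaging_model(attenuation_length_um = Inf, offset_adu = 100,
                       noise_sd_adu = 0,
                       vessels = list(list(point = c(60, 60, 0),
                                           direction = c(0, 0, 1),
                                           radius_um = 20)))
  stv <- render_stack(f10, g2, ves, seed = 1)
  xc <- voxel_centers(g2, 3); yc <- voxel_centers(g2, 2)
  inx <- which(abs(xc - 60) < 19.5); iny <- which(abs(yc - 60) < 19.5)
  sub <- stv$data[, iny, inx]
  d2 <- outer((yc[iny] - 60)^2, (xc[inx] - 60)^2, "+")
  inside <- sweep(array(FALSE, dim(sub)), c(2, 3), d2 < 20^2, "|")
  expect_true(all(sub[inside] == 100))
})

test_that("depth attenuation follows exp(-z/L)", {
  g <- voxel_geometry(c(100L, 40L, 40L), c(2, 1, 1))
  f <- generate_nucleus_field(g, uniform_profile(0), seed = 1)
  f$nuclei <- data.frame(id = 1:2, x_um = c(20, 20), y_um = c(20, 20),
                         z_um = c(50, 150), radius_x_um = 6,
                         radius_y_um = 6, radius_z_um = 6, peak = 1000,
                         class = "neuron", volume_um3 = 905)
  st <- render_stack(f, g, imaging_model(attenuation_length_um = 200,
                                         offset_adu = 0, noise_sd_adu = 0),
                     seed = 1)
  p1 <- max(st$data[1:50, , ]); p2 <- max(st$data[51:100, , ])
  expect_equal(p2 / p1, exp(-100 / 200), tolerance = 0.02)
})

test_that("MRI phantom: identity, affine field values, positive Jacobian", {
  ph0 <- generate_mri_phantom(NULL, noise_sd = 0, seed = 2)
  expect_equal(ph0$followup$data, ph0$baseline$data)
  expect_true(all(ph0$displacement$data == 0))

  A <- diag(3) * 0.99
  ph <- generate_mri_phantom(A, noise_sd = 0, seed = 2)
  geo <- ph$displacement$geometry
  ctr <- geo$extent_um / 2
  # displacement at voxel centers must reproduce x -> 0.99 x about center
  xc <- voxel_centers(geo, 3)
  ux <- ph$displacement$data[3, 5, , 3]
  expect_equal(ux, -0.01 * (xc - ctr[3]), tolerance = 1e-9)

  sm <- smooth_deformation(amplitude_um = 20, period_um = 1500, seed = 4)
  phs <- generate_mri_phantom(sm, noise_sd = 0, seed = 5)
  jf <- jacobian_determinant_field(phs$displacement)
  expect_true(all(jf$data > 0))
  expect_true(jf$all_positive)
})
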