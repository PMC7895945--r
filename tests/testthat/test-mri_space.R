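test_that("2D affine fit: identity, translation, exact recovery, errors", {
  src <- rbind(c(0, 0), c(700, 0), c(0, 700))
  tid <- fit_affine_xy(src, src)
  expect_equal(tid$A, diag(2), tolerance = 1e-12)
  expect_equal(tid$b, c(0, 0), tolerance = 1e-12)

  tt <- fit_affine_xy(src, sweep(src, 2, c(120, -40), "+"))
  expect_equal(tt$A, diag(2), tolerance = 1e-12)
  expect_equal(tt$b, c(120, -40), tolerance = 1e-12)

  A <- rbind(c(1.1, 0.2), c(-0.15, 0.95))
  b <- c(1000, 2000)
  tr <- fit_affine_xy(src, sweep(src %*% t(A), 2, b, "+"))
  expect_equal(tr$A, A, tolerance = 1e-9)
  expect_equal(tr$b, b, tolerance = 1e-9)
  # exactly-interpolating 3-point fit: zero residuals
  expect_equal(max(abs(tr$residuals)), 0, tolerance = 1e-9)

  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(fit_affine_xy(collinear, collinear), "collinear")
  expect_error(fit_affine_xy(src[1:2, ], src[1:2, ]), "at least 3")

  # least squares with > 3 noisy pairs still close
  set.seed(1)
  src2 <- matrix(runif(16, 0, 700), ncol = 2)
  dst2 <- sweep(src2 %*% t(A), 2, b, "+") + rnorm(16, 0, 1)
  tr2 <- fit_affine_xy(src2, dst2)
  expect_equal(tr2$A, A, tolerance = 0.05)
})

test_that("mask rasterization matches a brute-force center test", {
  geo <- voxel_geometry(c(24L, 48L, 48L), c(156, 78, 78))
  tr <- fit_affine_xy(rbind(c(0, 0), c(700, 0), c(0, 700)),
                      rbind(c(500, 700), c(1200, 700), c(500, 1400)))
  mk <- rasterize_stack_mask(tr, 700, geo, surface_plane = 2L)
  occ <- which(apply(mk$data, 1, any))
  expect_identical(occ, 2:4)                  # exactly 3 consecutive planes
  # brute-force in-plane oracle: centers inside the axis-aligned square
  xc <- voxel_centers(geo, 3); yc <- voxel_centers(geo, 2)
  inside <- outer(yc >= 700 & yc <= 1400, xc >= 500 & xc <= 1200, "&")
  expect_identical(unname(mk$data[2, , ]), unname(inside))
  # idempotent / deterministic
  mk2 <- rasterize_stack_mask(tr, 700, geo, surface_plane = 2L)
  expect_identical(mk$data, mk2$data)

  off <- fit_affine_xy(rbind(c(0, 0), c(700, 0), c(0, 700)),
                       rbind(c(9e5, 9e5), c(9e5 + 700, 9e5),
                             c(9e5, 9e5 + 700)))
  expect_error(rasterize_stack_mask(off, 700, geo), "empty mask")
  expect_error(rasterize_stack_mask(tr, 700, geo, surface_plane = 23L),
               "outside")
})

test_that("Jacobian determinant: identity, linear field, MC cross-check", {
  geo <- voxel_geometry(c(12L, 14L, 16L), c(156, 78, 78))
  zero <- deformation_field(array(0, c(geo$shape, 3)), geo)
  expect_true(all(jacobian_determinant_field(zero)$data == 1))

  ph <- generate_mri_phantom(diag(3) * 0.99, mri_geometry = geo,
                             noise_sd = 0, seed = 1)
  jf <- jacobian_determinant_field(ph$displacement)
  expect_equal(as.vector(jf$data), rep(0.99^3, prod(geo$shape)),
               tolerance = 1e-10)

  # smooth field: grid-based mean determinant vs an independent
  # finite-difference estimate at random points (interior only)
  u <- smooth_deformation(amplitude_um = 15, period_um = 2500, seed = 3)
  geo2 <- voxel_geometry(c(16L, 24L, 24L), c(156, 78, 78))
  ph2 <- generate_mri_phantom(u, mri_geometry = geo2, noise_sd = 0,
                              seed = 4)
  jf2 <- jacobian_determinant_field(ph2$displacement)
  interior <- jf2$data[3:14, 3:22, 3:22]
  set.seed(5)
  npt <- 4000
  lo <- c(2.5, 2.5, 2.5) * geo2$voxel_size
  hi <- geo2$extent_um - lo
  x <- runif(npt, lo[3], hi[3]); y <- runif(npt, lo[2], hi[2])
  z <- runif(npt, lo[1], hi[1])
  h <- 0.5
  det_mc <- vapply(seq_len(npt), function(i) {
    J <- matrix(0, 3, 3)
    for (ax in 1:3) {
      dp <- dm <- c(x[i], y[i], z[i])
      dp[ax] <- dp[ax] + h; dm[ax] <- dm[ax] - h
      up <- u(dp[1], dp[2], dp[3]); um <- u(dm[1], dm[2], dm[3])
      J[, ax] <- (up - um) / (2 * h)
    }
    det(diag(3) + J)
  }, numeric(1))
  expect_lt(abs(mean(interior) / mean(det_mc) - 1), 0.01)

  expect_error(deformation_field(array(NaN, c(geo$shape, 3)), geo),
               "finite")
})

test_that("GMV extraction in masks", {
  geo <- voxel_geometry(c(12L, 20L, 20L), c(156, 78, 78))
  tr <- fit_affine_xy(rbind(c(0, 0), c(700, 0), c(0, 700)),
                      rbind(c(300, 300), c(1000, 300), c(300, 1000)))
  mk <- rasterize_stack_mask(tr, 700, geo, surface_plane = 1L)

  zero <- deformation_field(array(0, c(geo$shape, 3)), geo)
  g0 <- gmv_change_in_mask(jacobian_determinant_field(zero), mk)
  expect_equal(g0$percent, 100)
  expect_identical(nrow(g0$profile), 3L)
  expect_equal(g0$profile$percent, rep(100, 3))

  # uniform determinant 0.95 via a linear field with per-axis scale
  s <- 0.95^(1 / 3)
  ph <- generate_mri_phantom(diag(3) * s, mri_geometry = geo, noise_sd = 0)
  g1 <- gmv_change_in_mask(jacobian_determinant_field(ph$displacement), mk)
  expect_equal(g1$percent, 95, tolerance = 1e-8)

  # affine deformation: percent equals 100 |det A| regardless of mask shape
  A <- diag(c(0.97, 1.01, 0.99))
  ph2 <- generate_mri_phantom(A, mri_geometry = geo, noise_sd = 0)
  jf2 <- jacobian_determinant_field(ph2$displacement)
  for (sp in c(1L, 5L)) {
    mks <- rasterize_stack_mask(tr, 700, geo, surface_plane = sp)
    expect_equal(gmv_change_in_mask(jf2, mks)$percent,
                 100 * abs(det(A)), tolerance = 1e-8)
  }
  empty <- mk; empty$data[] <- FALSE
  expect_error(gmv_change_in_mask(jf2, empty), "empty")
})

test_that("RARE acquisition arithmetic and the PSF polynomial", {
  acq <- acquisition_params()
  expect_equal(acq$tk_ms, 100)                    # 16 echoes x 6.25 ms
  expect_equal(round(psf_blurring_factor(acq), 3), 1.514)
  expect_equal(psf_blurring_factor(0, t2_ms = 45), 1.23)
  expect_equal(psf_blurring_factor(45, t2_ms = 45), 1.26)
  expect_error(psf_blurring_factor(100, t2_ms = -1), "positive")
  expect_error(acquisition_params(t2_ms = 0))
})
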