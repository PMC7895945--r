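# Shared fixture builders; everything is generated in code at test time.

# minimal nucleus table from coordinate vectors
make_table <- function(z, x = NULL, y = NULL, vol = 1000,
                       animal = "a1", pos = "p1", tp = 0) {
  n <- length(z)
  if (is.null(x)) x <- runif(n, 0, 700)
  if (is.null(y)) y <- runif(n, 0, 700)
  nucleus_table(data.frame(
    animal_id = rep_len(animal, n), position_id = rep_len(pos, n),
    timepoint = rep_len(tp, n),
    nucleus_id = seq_len(n), x_um = x, y_um = y, z_um = z,
    volume_voxels = rep_len(vol, n), volume_um3 = rep_len(vol, n),
    stringsAsFactors = FALSE))
}

# isotropic 3D Gaussian blob probability map
blob_prob <- function(dims, centers, sigma, amp = 0.9,
                      voxel_size = c(1, 1, 1)) {
  g <- voxel_geometry(dims, voxel_size)
  zc <- voxel_centers(g, 1); yc <- voxel_centers(g, 2)
  xc <- voxel_centers(g, 3)
  a <- array(0, dim = dims)
  centers <- matrix(centers, ncol = 3)      # rows of (x, y, z) um
  amp <- rep_len(amp, nrow(centers))
  sigma <- rep_len(sigma, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    gz <- exp(-((zc - centers[i, 3])^2) / (2 * sigma[i]^2))
    gy <- exp(-((yc - centers[i, 2])^2) / (2 * sigma[i]^2))
    gx <- exp(-((xc - centers[i, 1])^2) / (2 * sigma[i]^2))
    a <- a + amp[i] * outer(outer(gz, gy), gx)
  }
  probability_map(pmin(a, 1), g)
}

# fused twin-blob probability phantom: one seed at tolerance h, two at
# h * reseg factor (saddle drop engineered between the two)
fused_pair_prob <- function(sigma = 10.9, amp = 0.92, sep = NULL) {
  if (is.null(sep)) sep <- 2.433 * sigma    # saddle drop ~ 0.09 * amp/0.92
  nx <- as.integer(ceiling(2 * 33 + sep))
  dims <- c(66L, 66L, nx)
  blob_prob(dims, rbind(c(33, 33, 33), c(33 + sep, 33, 33)),
            sigma = sigma, amp = amp)
}

# mixed-model simulation used for coverage / type-I checks
simulate_long_table <- function(beta, seed, n_animal = 8, n_pos = 6,
                                sd_animal = 0.5, sd_res = 1) {
  set.seed(seed)
  d <- data.frame(animal_id = rep(seq_len(n_animal), each = n_pos),
                  x = rnorm(n_animal * n_pos))
  d$y <- 2 + beta * d$x + rep(rnorm(n_animal, 0, sd_animal), each = n_pos) +
    rnorm(nrow(d), 0, sd_res)
  d
}

fit_slope <- function(d) {
  m <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d, "y", "x")))
  m$coefficients[m$coefficients$term == "x", ]
}

# Monte-Carlo point-in-hull volume oracle (half-space test, chunked)
mc_hull_volume <- function(points, n_samples = 1e6, seed = 1) {
  set.seed(seed)
  h <- hull_volume(points)
  p <- h$points
  tets <- h$tets
  # boundary faces with outward normals (independent recomputation)
  faces <- NULL
  for (i in seq_len(nrow(tets))) {
    t <- tets[i, ]
    for (drop in 1:4) faces <- rbind(faces, sort(t[-drop]))
  }
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  bf <- faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
  bf <- unique(bf)
  g <- colMeans(p)
  normals <- matrix(0, nrow(bf), 3)
  offs <- numeric(nrow(bf))
  for (i in seq_len(nrow(bf))) {
    a <- p[bf[i, 1], ]; b <- p[bf[i, 2], ]; c <- p[bf[i, 3], ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    if (sum(nrm * (g - a)) < 0) nrm <- -nrm     # inward-pointing
    normals[i, ] <- nrm
    offs[i] <- sum(nrm * a)
  }
  lo <- apply(p, 2, min); hi <- apply(p, 2, max)
  box <- prod(hi - lo)
  inside <- 0
  chunk <- 1e5
  left <- n_samples
  while (left > 0) {
    m <- min(chunk, left)
    s <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
               runif(m, lo[3], hi[3]))
    ok <- (s %*% t(normals)) >= matrix(offs, m, length(offs), byrow = TRUE)
    inside <- inside + sum(rowSums(ok) == length(offs))
    left <- left - m
  }
  box * inside / n_samples
}
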