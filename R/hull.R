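#' @section Geometry backend:
#' The package carries its own 3D Delaunay triangulation (Bowyer-Watson
#' incremental insertion with an enclosing super-tetrahedron).  Point sets
#' here are small (tens to a few hundred fiducials), so an O(n * T) scan
#' per insertion is ample.  Degenerate configurations (co-spherical grids
#' and the like) are handled by a deterministic symbolic-style jitter that
#' is applied only to the copy of the coordinates used for the predicates;
#' all reported volumes are computed from the original coordinates.
#' @name hull-internals
#' @keywords internal
NULL

det3 <- function(a, b, c) {
  a[1] * (b[2] * c[3] - b[3] * c[2]) -
    a[2] * (b[1] * c[3] - b[3] * c[1]) +
    a[3] * (b[1] * c[2] - b[2] * c[1])
}

tet_signed_volume <- function(p, tet) {
  a <- p[tet[1], ]; b <- p[tet[2], ]; c <- p[tet[3], ]; d <- p[tet[4], ]
  det3(b - a, c - a, d - a) / 6
}

jitter_coords <- function(q, scale) {
  # deterministic, input-independent pseudo-jitter (does not touch the RNG)
  n <- nrow(q)
  i <- seq_len(n)
  j <- cbind(((i * 2654435761) %% 65536) / 65536,
             ((i * 40503 + 17) %% 65536) / 65536,
             ((i * 69069 + 101) %% 65536) / 65536)
  q + (j - 0.5) * scale
}

#' 3D Delaunay triangulation of a point set
#'
#' Incremental Bowyer-Watson triangulation using the lifted in-sphere
#' determinant predicate on per-axis-normalized, deterministically
#' jittered coordinates.  The result is validated (manifold face counts,
#' convex boundary, volume cross-check on the original coordinates); on
#' failure the jitter is escalated and the construction retried.
#'
#' @param points n x 3 numeric matrix (n >= 4, affinely independent).
#' @return list with `tets` (T x 4 matrix of row indices into `points`),
#'   `signed_volumes` (length T, original coordinates), `boundary_faces`
#'   (B x 3 vertex indices of the hull surface) and `direct_volume`
#'   (divergence-theorem volume over the outward-oriented boundary).
#' @export
delaunay_3d <- function(points) {
  p <- as.matrix(points)
  dimnames(p) <- NULL
  stopifnot(ncol(p) == 3)
  n <- nrow(p)
  check_affine_independence(p)
  lo <- apply(p, 2, min); hi <- apply(p, 2, max)
  q <- sweep(sweep(p, 2, lo), 2, pmax(hi - lo, 1e-300), "/")
  err <- "unknown"
  for (attempt in 1:6) {
    qj <- jitter_coords(q, 1e-10 * 10^(attempt - 1))
    res <- try(bowyer_watson(qj, n), silent = TRUE)
    if (inherits(res, "try-error")) {
      err <- attr(res, "condition")$message
      next
    }
    val <- validate_triangulation(p, res)
    if (is.null(val$error)) {
      return(list(tets = res, signed_volumes = val$signed_volumes,
                  boundary_faces = val$boundary_faces,
                  direct_volume = val$direct_volume))
    }
    err <- val$error
  }
  stop("Delaunay triangulation failed: ", err)
}

orient_positive <- function(q, tet) {
  v <- det3(q[tet[2], ] - q[tet[1], ], q[tet[3], ] - q[tet[1], ],
            q[tet[4], ] - q[tet[1], ])
  if (v < 0) tet[c(1, 2, 4, 3)] else tet
}

bowyer_watson <- function(q, n) {
  # Incremental Delaunay with an infinite vertex (index 0): hull faces are
  # carried as virtual tets (a, b, c, 0) whose base triangle is oriented
  # outward; their "circumsphere" contains p iff the face is visible.
  if (n < 4) stop("need at least 4 points")
  # greedy, well-conditioned initial tetrahedron
  i1 <- 1L
  d1 <- rowSums(sweep(q, 2, q[i1, ])^2)
  i2 <- which.max(d1)
  e1 <- q[i2, ] - q[i1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  ar <- apply(q, 1, function(x) sum(cr(e1, x - q[i1, ])^2))
  i3 <- which.max(ar)
  nrm <- cr(e1, q[i3, ] - q[i1, ])
  vol <- abs(as.numeric(sweep(q, 2, q[i1, ]) %*% nrm))
  i4 <- which.max(vol)
  first <- c(i1, i2, i3, i4)
  if (abs(vol[i4]) < 1e-300) stop("degenerate initial tetrahedron")
  order_ins <- c(first, setdiff(seq_len(n), first))

  t0 <- orient_positive(q, first)
  tets <- matrix(t0, nrow = 1)
  # virtual tets on each face, base oriented outward w.r.t. opposite vertex
  for (drop in 1:4) {
    f <- t0[-drop]
    v <- t0[drop]
    if (det3(q[f[2], ] - q[f[1], ], q[f[3], ] - q[f[1], ],
             q[v, ] - q[f[1], ]) > 0) f <- f[c(1, 3, 2)]
    tets <- rbind(tets, c(f, 0L))
  }
  alive <- rep(TRUE, nrow(tets))
  g <- colMeans(q[first, , drop = FALSE])
  n_in <- 4L
  for (ip in order_ins[-(1:4)]) {
    pt <- q[ip, ]
    live <- which(alive)
    isv <- tets[live, 4] == 0L
    bad <- integer(0)
    if (any(!isv)) {
      real <- live[!isv]
      ins <- cpp_insphere_batch(q, tets[real, , drop = FALSE], pt)
      bad <- real[ins]
    }
    if (any(isv)) {
      virt <- live[isv]
      a <- q[tets[virt, 1], , drop = FALSE]
      b <- q[tets[virt, 2], , drop = FALSE]
      cc <- q[tets[virt, 3], , drop = FALSE]
      u <- b - a; v <- cc - a
      nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
      ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
      nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
      w <- (pt[1] - a[, 1]) * nx + (pt[2] - a[, 2]) * ny +
        (pt[3] - a[, 3]) * nz
      bad <- c(bad, virt[w > 0])
    }
    if (!length(bad)) stop("insertion point belongs to no cavity")
    faces <- matrix(0L, nrow = 4 * length(bad), ncol = 3)
    k <- 0L
    for (bb in bad) {
      t <- tets[bb, ]
      for (drop in 1:4) {
        k <- k + 1L
        faces[k, ] <- sort(t[-drop])
      }
    }
    keyf <- paste(faces[, 1], faces[, 2], faces[, 3])
    cnt <- table(keyf)
    sel <- match(names(cnt)[cnt == 1], keyf)
    alive[bad] <- FALSE
    g <- (g * n_in + pt) / (n_in + 1)
    n_in <- n_in + 1L
    newt <- matrix(0L, length(sel), 4)
    for (j in seq_along(sel)) {
      f <- faces[sel[j], ]
      if (f[1] == 0L) {
        # horizon edge (0, a, b): new hull face (a, b, p), outward via g
        e <- f[2:3]
        tri <- c(e, ip)
        if (det3(q[tri[2], ] - q[tri[1], ], q[tri[3], ] - q[tri[1], ],
                 g - q[tri[1], ]) > 0) tri <- tri[c(1, 3, 2)]
        newt[j, ] <- c(tri, 0L)
      } else {
        newt[j, ] <- orient_positive(q, c(f, ip))
      }
    }
    tets <- rbind(tets, newt)
    alive <- c(alive, rep(TRUE, nrow(newt)))
  }
  keep <- alive & tets[, 4] != 0L
  out <- tets[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("triangulation produced no interior tetrahedra")
  dimnames(out) <- NULL
  out
}

validate_triangulation <- function(p, tets) {
  Tn <- nrow(tets)
  faces <- matrix(0L, 4 * Tn, 3)
  k <- 0L
  for (i in seq_len(Tn)) {
    t <- tets[i, ]
    for (drop in 1:4) {
      k <- k + 1L
      faces[k, ] <- sort(t[-drop])
    }
  }
  keyf <- paste(faces[, 1], faces[, 2], faces[, 3])
  cnt <- table(keyf)
  if (any(cnt > 2))
    return(list(error = "non-manifold face adjacency"))
  bsel <- which(keyf %in% names(cnt)[cnt == 1])
  bfaces <- faces[bsel, , drop = FALSE]
  scale <- max(apply(p, 2, function(x) diff(range(x))))
  g <- colMeans(p)
  direct <- 0
  for (s in seq_len(nrow(bfaces))) {
    a <- p[bfaces[s, 1], ]; b <- p[bfaces[s, 2], ]; c <- p[bfaces[s, 3], ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) {
      if (sum(nrm * (a - g)) < 0) nrm <- -nrm          # outward
      # convexity: no point may lie outside the supporting plane
      d <- (p %*% (nrm / nn)) - sum((nrm / nn) * a)
      if (max(d) > 1e-7 * scale)
        return(list(error = "boundary face is not a hull support plane"))
      if (sum(nrm * (a - g)) < 0) { tmp <- b; b <- c; c <- tmp }
    }
    # outward-oriented divergence contribution
    aa <- a; bb <- b; cc <- c
    nr2 <- c((bb - aa)[2] * (cc - aa)[3] - (bb - aa)[3] * (cc - aa)[2],
             (bb - aa)[3] * (cc - aa)[1] - (bb - aa)[1] * (cc - aa)[3],
             (bb - aa)[1] * (cc - aa)[2] - (bb - aa)[2] * (cc - aa)[1])
    if (sum(nr2 * (aa - g)) < 0) { tmp <- bb; bb <- cc; cc <- tmp }
    direct <- direct + det3(aa, bb, cc) / 6
  }
  vols <- apply(tets, 1, function(t) tet_signed_volume(p, t))
  total <- sum(abs(vols))
  if (abs(direct - total) > 1e-9 * max(total, .Machine$double.eps))
    return(list(error = "tetrahedra volumes do not sum to the hull volume"))
  list(error = NULL, signed_volumes = vols,
       boundary_faces = bfaces, direct_volume = direct)
}

check_affine_independence <- function(p) {
  n <- nrow(p)
  if (n < 4) stop("degenerate input: need at least 4 points")
  if (cpp_min_pairwise_distance(p) <
      1e-9 * max(1, max(apply(p, 2, function(x) diff(range(x))))))
    stop("degenerate input: duplicate points")
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))$d
  tol <- max(sv) * 1e-9
  rank <- sum(sv > tol)
  if (rank < 2) stop("degenerate input: points are collinear")
  if (rank < 3) stop("degenerate input: points are coplanar")
  invisible(TRUE)
}

#' Convex-hull volume via Delaunay triangulation
#'
#' Triangulates the point set, sums the absolute tetrahedron volumes
#' (the Delaunay route), and independently recomputes the hull volume by
#' the divergence theorem over the outward-oriented boundary faces of the
#' complex (the direct route).  Both values are stored; they agree to
#' within 1e-9 relative on valid triangulations and serve as an internal
#' cross-check.
#'
#' @param points n x 3 matrix of coordinates in um (n >= 4, affinely
#'   independent).
#' @return A `convex_hull_result`: `volume_um3` (Delaunay sum),
#'   `direct_volume_um3`, `tets`, `tet_volumes_um3`, `tet_centroids`
#'   (T x 3), `hull_vertices` (indices of points on the hull boundary) and
#'   `points`.
#' @export
hull_volume <- function(points) {
  p <- as.matrix(points)
  dimnames(p) <- NULL
  dt <- delaunay_3d(p)
  vols <- abs(dt$signed_volumes)
  tets <- dt$tets
  centroids <- t(apply(tets, 1, function(t) colMeans(p[t, , drop = FALSE])))
  structure(list(volume_um3 = sum(vols),
                 direct_volume_um3 = dt$direct_volume,
                 tets = tets,
                 tet_volumes_um3 = vols,
                 tet_centroids = centroids,
                 hull_vertices = sort(unique(as.vector(dt$boundary_faces))),
                 points = p),
            class = "convex_hull_result")
}

#' @export
print.convex_hull_result <- function(x, ...) {
  cat(sprintf("<convex_hull_result> %d points, %d tetrahedra, volume %.6g um^3 (direct %.6g)\n",
              nrow(x$points), nrow(x$tets), x$volume_um3,
              x$direct_volume_um3))
  invisible(x)
}

#' Layer-confined hull volumes
#'
#' Each Delaunay tetrahedron is assigned to exactly one depth bin by the z
#' coordinate of its centroid (mean of the four vertex z), and bin volumes
#' are the sums of member tetrahedron volumes.  Tetrahedra are not clipped
#' at bin boundaries, so individual layer volumes are approximate but their
#' sum equals the total hull volume exactly.
#'
#' @param result a `convex_hull_result` from [hull_volume()].
#' @param binning a [depth_binning()] covering all tetrahedron centroids.
#' @return named numeric vector of per-layer volumes (um^3).
#' @export
layer_volumes <- function(result, binning = depth_binning()) {
  stopifnot(inherits(result, "convex_hull_result"),
            inherits(binning, "depth_binning"))
  cz <- result$tet_centroids[, 3]
  idx <- depth_bin_index(cz, binning)
  if (any(is.na(idx)))
    stop("tetrahedron centroid(s) outside the binning range: ",
         paste(which(is.na(idx)), collapse = ", "))
  lab <- depth_bin_labels(binning)
  out <- vapply(seq_along(lab), function(b)
    sum(result$tet_volumes_um3[idx == b]), numeric(1))
  setNames(out, lab)
}

#' Hull-volume change series from a fiducial table
#'
#' Applies completeness filtering (only fiducial ids present at every
#' declared timepoint are used, identically at all timepoints), computes
#' the convex-hull volume per `(animal_id, position_id, timepoint)`, and
#' expresses each volume as percent of the baseline timepoint.
#'
#' @param fiducials data frame with columns `animal_id`, `position_id`,
#'   `timepoint`, `fiducial_id`, `x_um`, `y_um`, `z_um`.
#' @param baseline_timepoint baseline; default is the first declared
#'   timepoint (sorted order).
#' @param timepoints declared timepoint list; default: all timepoints
#'   present for the position.
#' @param binning optional [depth_binning()]; when given, per-layer volumes
#'   and percents are returned as well.
#' @param min_recommended warn below this fiducial count (default 30).
#' @return data frame with `animal_id`, `position_id`, `timepoint`,
#'   `n_fiducials`, `volume_um3`, `pct_of_baseline`; with `binning`, an
#'   attribute `"layers"` holds the long-format per-layer table.
#' @export
hull_change_series <- function(fiducials, baseline_timepoint = NULL,
                               timepoints = NULL, binning = NULL,
                               min_recommended = 30) {
  need <- c("animal_id", "position_id", "timepoint", "fiducial_id",
            "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(fiducials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  groups <- unique(fiducials[c("animal_id", "position_id")])
  out <- NULL
  layers_out <- NULL
  for (gi in seq_len(nrow(groups))) {
    g <- fiducials[fiducials$animal_id == groups$animal_id[gi] &
                     fiducials$position_id == groups$position_id[gi], ]
    tps <- if (is.null(timepoints)) sort(unique(g$timepoint)) else
      sort(timepoints)
    base_tp <- if (is.null(baseline_timepoint)) tps[1] else baseline_timepoint
    if (!base_tp %in% tps) stop("baseline timepoint not among declared timepoints")
    # completeness filtering: common id set across all declared timepoints
    ids <- Reduce(intersect,
                  lapply(tps, function(tp) g$fiducial_id[g$timepoint == tp]))
    if (length(ids) < 4)
      stop(sprintf("position %s/%s: fewer than 4 fiducials common to all timepoints",
                   groups$animal_id[gi], groups$position_id[gi]))
    if (length(ids) < min_recommended)
      warning(sprintf("position %s/%s: only %d common fiducials (>= %d recommended)",
                      groups$animal_id[gi], groups$position_id[gi],
                      length(ids), min_recommended))
    hulls <- lapply(tps, function(tp) {
      gg <- g[g$timepoint == tp & g$fiducial_id %in% ids, ]
      if (anyDuplicated(gg$fiducial_id))
        stop("duplicate fiducial ids within one timepoint")
      gg <- gg[order(gg$fiducial_id), ]
      hull_volume(cbind(gg$x_um, gg$y_um, gg$z_um))
    })
    vols <- vapply(hulls, function(h) h$volume_um3, numeric(1))
    vbase <- vols[match(base_tp, tps)]
    res <- data.frame(animal_id = groups$animal_id[gi],
                      position_id = groups$position_id[gi],
                      timepoint = tps, n_fiducials = length(ids),
                      volume_um3 = vols,
                      pct_of_baseline = relative_change(vols, vbase),
                      stringsAsFactors = FALSE)
    out <- rbind(out, res)
    if (!is.null(binning)) {
      lv <- lapply(hulls, layer_volumes, binning = binning)
      base_lv <- lv[[match(base_tp, tps)]]
      for (ti in seq_along(tps)) {
        layers_out <- rbind(layers_out, data.frame(
          animal_id = groups$animal_id[gi],
          position_id = groups$position_id[gi],
          timepoint = tps[ti], layer = names(lv[[ti]]),
          volume_um3 = as.numeric(lv[[ti]]),
          pct_of_baseline = ifelse(base_lv > 0,
                                   100 * lv[[ti]] / base_lv, NA_real_),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  if (!is.null(binning)) attr(out, "layers") <- layers_out
  out
}
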