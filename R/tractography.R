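# Fractional anisotropy, principal diffusion directions, and deterministic
# FACT (Fiber Assignment by Continuous Tracking) fiber tracking.
#
# Tensor volumes store the six unique components of the symmetric diffusion
# tensor per voxel in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
# Voxel indices are 1-based (R convention); world coordinates in mm come
# from the affine applied to voxel centers.

tensor_component_order <- c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz")

# Rebuild the 3x3 symmetric tensor from its six stored components.
tensor_matrix <- function(comp) {
  matrix(c(comp[1L], comp[2L], comp[4L],
           comp[2L], comp[3L], comp[5L],
           comp[4L], comp[5L], comp[6L]), 3L, 3L)
}

#' Tensor volume container
#'
#' @param data 4-D array `c(nx, ny, nz, 6)` of symmetric-tensor components
#'   in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), nominally in
#'   mm^2/s.
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @param origin World coordinate of the center of voxel (1, 1, 1).
#' @return A `tensor_volume` object with a 4 x 4 voxel-to-world affine.
#' @export
tensor_volume <- function(data, voxel_size = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 4L || dim(data)[4L] != 6L) {
    stopf("tensor data must be an array of dimension c(nx, ny, nz, 6)")
  }
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(voxel_size)
  affine[1:3, 4L] <- origin
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 affine = affine, dim = dim(data)[1:3]),
            class = "tensor_volume")
}

voxel_to_world <- function(vol, idx) {
  # idx: matrix of 1-based voxel indices (rows); centers map through affine
  idx0 <- sweep(as.matrix(idx), 2L, c(1, 1, 1))
  sweep(idx0 %*% t(vol$affine[1:3, 1:3]), 2L, vol$affine[1:3, 4L], "+")
}

fa_from_eigenvalues <- function(ev) {
  ev <- pmax(ev, 0)
  ss <- sum(ev^2)
  if (ss <= 0) return(0)
  m <- mean(ev)
  min(1, sqrt(3 / 2) * sqrt(sum((ev - m)^2)) / sqrt(ss))
}

#' Fractional anisotropy from a tensor volume
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`
#' on the tensor eigenvalues, clamped below at 0 before use; an all-zero
#' tensor has FA 0 by convention. FA lies in [0, 1]: 0 for isotropic
#' diffusion, approaching 1 when diffusion is confined to one axis.
#'
#' @param tensors A [tensor_volume()].
#' @return A `scalar_volume` list: `data` (FA array), `voxel_size`, `affine`.
#' @export
compute_fa <- function(tensors) {
  d <- tensors$data
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stopf("non-finite tensor component at voxel (%d, %d, %d)", bad[1L], bad[2L], bad[3L])
  }
  dm <- dim(d)[1:3]
  flat <- matrix(d, prod(dm), 6L)
  fa <- vapply(seq_len(nrow(flat)), function(i) {
    comp <- flat[i, ]
    if (all(comp == 0)) return(0)
    fa_from_eigenvalues(eigen(tensor_matrix(comp), symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  structure(list(data = array(fa, dm), voxel_size = tensors$voxel_size,
                 affine = tensors$affine, dim = dm),
            class = "scalar_volume")
}

#' Principal diffusion direction of one tensor
#'
#' Unit eigenvector of the largest eigenvalue, the direction FACT tracking
#' follows. The sign is chosen so the dot product with `reference` is
#' nonnegative (the incoming direction during tracking; +x at seeding).
#' A leading eigenvalue tied within `tol` is flagged degenerate and treated
#' as a termination point by the tracker.
#'
#' @param tensor Length-6 component vector or 3 x 3 symmetric matrix.
#' @param reference Sign-disambiguation direction.
#' @param tol Tie tolerance on the top two eigenvalues.
#' @return List with unit vector `direction` and logical `degenerate`.
#' @export
principal_direction <- function(tensor, reference = c(1, 0, 0), tol = 1e-9) {
  m <- if (is.matrix(tensor)) tensor else tensor_matrix(tensor)
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m)))) stopf("tensor must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  degenerate <- (e$values[1L] - e$values[2L]) <= tol * max(abs(e$values[1L]), 1e-300)
  v <- e$vectors[, 1L]
  if (sum(v * reference) < 0) v <- -v
  list(direction = v / sqrt(sum(v^2)), degenerate = degenerate)
}

#' Deterministic FACT fiber tracking
#'
#' Voxel-to-voxel propagation of the Fiber Assignment by Continuous
#' Tracking algorithm: from a seed at a voxel center, advance along the
#' current voxel's principal diffusion direction to the exit face, enter
#' the neighbor and adopt its (sign-aligned) principal direction.
#' Propagation terminates when the next voxel's FA falls below `fa_min`,
#' the angle between successive principal directions exceeds
#' `angle_max_deg`, the leading eigenvalue is degenerate, or the ray leaves
#' the volume. The two half-tracks grown from each seed in opposite
#' directions are concatenated; streamlines visiting fewer than
#' `min_points` voxels are discarded. Tracking is fully deterministic.
#'
#' @param tensors A [tensor_volume()].
#' @param fa Matching FA volume; computed with [compute_fa()] when `NULL`.
#' @param fa_min FA termination threshold (default 0.2).
#' @param angle_max_deg Turning-angle termination threshold in degrees
#'   (default 45).
#' @param seeds Optional matrix of 1-based seed voxel indices; default one
#'   seed at the center of every voxel with FA >= `fa_min`.
#' @param min_points Minimum visited-voxel count to keep a streamline.
#' @param max_steps Safety cap per half-track.
#' @return A `wm_streamlines` object: list `streamlines` (each with world-mm
#'   `points`, visited `voxels`, and per-voxel `fa` samples) plus the
#'   tracking parameters.
#' @export
fact_track <- function(tensors, fa = NULL, fa_min = 0.2, angle_max_deg = 45,
                       seeds = NULL, min_points = 3L, max_steps = 10000L) {
  if (is.null(fa)) fa <- compute_fa(tensors)
  if (!all(fa$dim == tensors$dim) || max(abs(fa$affine - tensors$affine)) > 1e-9) {
    stopf("FA and tensor volumes are on different grids")
  }
  dm <- tensors$dim
  fa_arr <- fa$data
  vs <- tensors$voxel_size
  cos_max <- cos(angle_max_deg * pi / 180)

  # cache principal directions and degeneracy flags for trackable voxels
  dir_cache <- array(NA_real_, c(dm, 3L))
  degen <- array(FALSE, dm)
  idx_track <- which(fa_arr >= fa_min, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_track))) {
    i <- idx_track[r, 1L]; j <- idx_track[r, 2L]; k <- idx_track[r, 3L]
    pd <- principal_direction(tensors$data[i, j, k, ], reference = c(1, 0, 0))
    dir_cache[i, j, k, ] <- pd$direction
    degen[i, j, k] <- pd$degenerate
  }

  if (is.null(seeds)) seeds <- idx_track
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) {
    warnf("no seed voxels with FA >= %g; empty streamline set", fa_min)
    return(structure(list(streamlines = list(),
                          tracking_params = list(fa_min = fa_min,
                                                 angle_max_deg = angle_max_deg,
                                                 min_points = min_points)),
                     class = "wm_streamlines"))
  }

  inside <- function(v) all(v >= 1L) && all(v <= dm)

  # Advance from world point p inside voxel v along unit world direction d
  # to the voxel's exit face; returns exit point and next voxel index.
  step_out <- function(p, v, d) {
    center <- (v - 1) * vs
    t_exit <- rep(Inf, 3L)
    for (ax in 1:3) {
      if (abs(d[ax]) > 1e-12) {
        bound <- center[ax] + sign(d[ax]) * vs[ax] / 2
        t_exit[ax] <- (bound - p[ax]) / d[ax]
      }
    }
    tmin <- min(t_exit)
    cross <- which(abs(t_exit - tmin) <= 1e-9)
    if (length(cross) > 1L) cross <- cross[which.max(abs(d[cross]))]  # edge/corner tie
    vn <- v
    vn[cross] <- vn[cross] + as.integer(sign(d[cross]))
    list(p = p + tmin * d, v_next = vn)
  }

  half_track <- function(v0, d0) {
    p <- (v0 - 1) * vs
    d <- d0
    v <- v0
    pts <- list(p)
    vox <- list(v0)
    zero_steps <- 0L
    for (s in seq_len(max_steps)) {
      st <- step_out(p, v, d)
      # near-zero advances occur when the ray passes a voxel edge/corner:
      # allow the handful needed to cross it, but stop a ray that is stuck
      if (sum(abs(st$p - p)) < 1e-9) {
        zero_steps <- zero_steps + 1L
        if (zero_steps > 3L) break
      } else {
        zero_steps <- 0L
      }
      pts[[length(pts) + 1L]] <- st$p
      vn <- st$v_next
      if (!inside(vn)) break
      if (fa_arr[vn[1L], vn[2L], vn[3L]] < fa_min) break
      if (degen[vn[1L], vn[2L], vn[3L]]) break
      dn <- dir_cache[vn[1L], vn[2L], vn[3L], ]
      if (sum(dn * d) < 0) dn <- -dn
      if (sum(dn * d) < cos_max) break
      p <- st$p
      v <- vn
      d <- dn
      vox[[length(vox) + 1L]] <- vn
    }
    list(points = do.call(rbind, pts), voxels = do.call(rbind, vox))
  }

  origin <- tensors$affine[1:3, 4L]
  streamlines <- vector("list", nrow(seeds))
  kept <- 0L
  for (r in seq_len(nrow(seeds))) {
    v0 <- as.integer(seeds[r, ])
    if (!inside(v0) || fa_arr[v0[1L], v0[2L], v0[3L]] < fa_min ||
        degen[v0[1L], v0[2L], v0[3L]]) next
    d0 <- dir_cache[v0[1L], v0[2L], v0[3L], ]
    fwd <- half_track(v0, d0)
    bwd <- half_track(v0, -d0)
    pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
                 fwd$points[-1L, , drop = FALSE])
    vox <- rbind(bwd$voxels[rev(seq_len(nrow(bwd$voxels))), , drop = FALSE],
                 fwd$voxels[-1L, , drop = FALSE])
    vox <- vox[!duplicated(vox), , drop = FALSE]
    if (nrow(vox) < min_points) next
    kept <- kept + 1L
    streamlines[[kept]] <- list(
      points = sweep(pts, 2L, origin, "+"),
      voxels = vox,
      fa = fa_arr[vox]
    )
  }
  structure(list(streamlines = streamlines[seq_len(kept)],
                 tracking_params = list(fa_min = fa_min, angle_max_deg = angle_max_deg,
                                        min_points = min_points)),
            class = "wm_streamlines")
}

#' Write streamlines to a plain-text table
#'
#' One row per polyline vertex: streamline id and world-mm x, y, z.
#'
#' @param tracks A `wm_streamlines` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(tracks, path) {
  rows <- lapply(seq_along(tracks$streamlines), function(i) {
    p <- tracks$streamlines[[i]]$points
    data.frame(streamline = i, x = p[, 1L], y = p[, 2L], z = p[, 3L])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(streamline = integer(), x = numeric(), y = numeric(), z = numeric())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a streamline set
#'
#' @param tracks A `wm_streamlines` object.
#' @return List with streamline count and length statistics (mm).
#' @export
streamline_summary <- function(tracks) {
  lens <- vapply(tracks$streamlines, function(sl) {
    p <- sl$points
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  list(n_streamlines = length(lens),
       length_mm = if (length(lens)) summary(lens) else summary(numeric()))
}
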