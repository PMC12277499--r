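#' Rigid transform between patient spaces
#'
#' Maps a point `p` in the fixed volume's patient space to the moving
#' volume's space as `R p + t` (the pull-back convention used when
#' resampling the moving volume onto the fixed grid).
#'
#' @param rotation 3x3 rotation matrix, determinant +1.
#' @param translation mm vector of length 3.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be a proper 3x3 rotation matrix", call. = FALSE)
  }
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stop("translation must be three finite mm values", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

# Euler XYZ rotation (radians), right-handed about the patient axes.
euler_rotation <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, pts) {
  pts <- rbind_coords(pts)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, `+`)
}

# Sample a volume at arbitrary patient-space points. Points outside the
# source extent (beyond half a voxel past the outermost centers for
# nearest; contributing corners outside the lattice for trilinear) read
# as `fill`.
sample_volume_at <- function(volume, pts, interpolation = "trilinear",
                             fill = 0) {
  idx <- patient_to_voxel(volume$grid, pts)
  d <- volume$grid$dims
  v <- volume$values
  n <- nrow(idx)
  if (interpolation == "nearest") {
    i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
      k >= 0 & k <= d[3] - 1
    out <- rep(fill, n)
    out[ok] <- v[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
    return(out)
  }
  i0 <- floor(idx[, 1]); j0 <- floor(idx[, 2]); k0 <- floor(idx[, 3])
  fx <- idx[, 1] - i0; fy <- idx[, 2] - j0; fz <- idx[, 3] - k0
  out <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 &
      kk >= 0 & kk <= d[3] - 1 & w > 0
    val <- rep(fill, n)
    val[ok] <- v[cbind(ii[ok] + 1, jj[ok] + 1, kk[ok] + 1)]
    out <- out + w * val
  }
  out
}

#' Resample a volume or mask onto another grid
#'
#' Evaluates the source volume at every target voxel center (optionally
#' through a rigid transform mapping target space into source space).
#' Voxels mapping outside the source extent get the fill value 0. Use
#' nearest-neighbor for masks/labels and trilinear for images.
#'
#' @param volume a [scalar_volume()] or [binary_mask()].
#' @param target target [volume_grid()].
#' @param interpolation `"trilinear"` or `"nearest"` (masks always use
#'   nearest).
#' @param transform optional [rigid_transform()] from target space to
#'   source space.
#' @return Object of the same class as `volume`, on `target`.
#' @export
resample <- function(volume, target,
                     interpolation = c("trilinear", "nearest"),
                     transform = NULL) {
  stopifnot(is_volume_grid(target))
  interpolation <- match.arg(interpolation)
  if (is_binary_mask(volume)) {
    src <- scalar_volume(array(as.numeric(volume$voxels), volume$grid$dims),
                         volume$grid, "CT")
    res <- resample(src, target, "nearest", transform)
    return(binary_mask(array(res$values > 0.5, target$dims), target,
                       volume$label))
  }
  stopifnot(is_scalar_volume(volume))
  if (is.null(transform) && grid_equal(volume$grid, target)) {
    return(scalar_volume(volume$values, target, volume$modality))
  }
  pts <- grid_voxel_centers(target)
  if (!is.null(transform)) pts <- transform_points(transform, pts)
  vals <- sample_volume_at(volume, pts, interpolation)
  scalar_volume(array(vals, target$dims), target, volume$modality)
}

#' Dice overlap coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`, in `[0, 1]`; defined as 1 when both masks
#' are empty. Masks must share a grid — resample one first otherwise.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  stopifnot(is_binary_mask(a), is_binary_mask(b))
  if (!grid_equal(a$grid, b$grid)) {
    stop("masks are on different grids; resample first", call. = FALSE)
  }
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Optimizer and metric settings for rigid registration
#'
#' The similarity is a 32-bin joint-histogram mutual information
#' evaluated over the full fixed grid (no random sampling, so the
#' optimization is deterministic). The optimizer is a regular-step
#' pattern search over scaled parameters: steps start at `radius` and
#' halve whenever no axis move improves the metric, stopping below
#' `epsilon` or at `max_iterations` sweeps. One scaled parameter unit
#' corresponds to `rotation_scale` radians or `translation_scale` mm.
#'
#' @param radius initial step in scaled parameter units.
#' @param epsilon convergence threshold on the step size.
#' @param max_iterations maximum optimizer sweeps.
#' @param bins histogram bins per axis for mutual information.
#' @param rotation_scale radians per parameter unit.
#' @param translation_scale mm per parameter unit.
#' @param rotations include the three rotation parameters (disable for a
#'   translation-only search).
#' @return A `register_config` list.
#' @export
register_config <- function(radius = 0.009, epsilon = 1.5e-4,
                            max_iterations = 1000, bins = 32,
                            rotation_scale = 5, translation_scale = 1000,
                            rotations = TRUE) {
  structure(list(radius = radius, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 bins = as.integer(bins),
                 rotation_scale = rotation_scale,
                 translation_scale = translation_scale,
                 rotations = isTRUE(rotations)),
            class = "register_config")
}

# Mutual information between the fixed volume and the moving volume
# pulled back through the transform, over all fixed voxels.
mutual_information <- function(fixed_vals, fixed_bin, moving, pts,
                               transform, bins, mov_range) {
  mpts <- transform_points(transform, pts)
  mv <- sample_volume_at(moving, mpts, "trilinear")
  mb <- pmin(pmax(floor((mv - mov_range[1]) / diff(mov_range) * bins), 0),
             bins - 1) + 1
  joint <- tabulate(fixed_bin + bins * (mb - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (px[row(pj)[nz]] * py[col(pj)[nz]])))
}

#' Rigid mutual-information registration
#'
#' Finds the rigid transform (pull-back: fixed space to moving space)
#' maximizing the mutual information between the fixed volume and the
#' transformed moving volume. Deterministic for fixed inputs and
#' configuration. If the step size never falls below `epsilon` within
#' `max_iterations` sweeps, the best transform so far is returned with
#' `converged = FALSE`.
#'
#' @param fixed,moving non-constant [scalar_volume()]s.
#' @param config a [register_config()].
#' @return List with `transform` ([rigid_transform()]), `converged`,
#'   `similarity` (final mutual information, nats), and `iterations`.
#' @export
register_rigid <- function(fixed, moving, config = register_config()) {
  stopifnot(is_scalar_volume(fixed), is_scalar_volume(moving))
  if (diff(range(fixed$values)) == 0 || diff(range(moving$values)) == 0) {
    stop("registration needs non-constant volumes", call. = FALSE)
  }
  bins <- config$bins
  pts <- grid_voxel_centers(fixed$grid)
  fr <- range(fixed$values)
  fb <- pmin(pmax(floor((fixed$values - fr[1]) / diff(fr) * bins), 0),
             bins - 1) + 1
  fb <- as.integer(fb)
  mr <- range(moving$values)
  if (diff(mr) == 0) mr <- mr + c(-0.5, 0.5)

  scales <- if (config$rotations) {
    c(rep(config$rotation_scale, 3), rep(config$translation_scale, 3))
  } else {
    rep(config$translation_scale, 3)
  }
  np <- length(scales)
  par_to_transform <- function(u) {
    if (config$rotations) {
      rigid_transform(euler_rotation(u[1] * scales[1], u[2] * scales[2],
                                     u[3] * scales[3]),
                      u[4:6] * scales[4:6])
    } else {
      rigid_transform(diag(3), u * scales)
    }
  }
  objective <- function(u) {
    mutual_information(fixed$values, fb, moving, pts, par_to_transform(u),
                       bins, mr)
  }

  u <- numeric(np)
  best <- objective(u)
  step <- config$radius
  it <- 0L
  converged <- FALSE
  while (it < config$max_iterations) {
    it <- it + 1L
    improved <- FALSE
    for (i in seq_len(np)) {
      for (s in c(1, -1)) {
        cand <- u
        cand[i] <- cand[i] + s * step
        val <- objective(cand)
        if (val > best + 1e-12) {
          u <- cand
          best <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      step <- step / 2
      if (step < config$epsilon) {
        converged <- TRUE
        break
      }
    }
  }
  list(transform = par_to_transform(u), converged = converged,
       similarity = best, iterations = it)
}
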