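#' Define a 3D voxel lattice in patient space
#'
#' A `volume_grid` fixes the geometry shared by volumes and masks: voxel
#' counts, spacing in mm, the patient-space position of the first voxel's
#' center, and the direction cosines of the three voxel axes. Patient
#' coordinates follow the LPS convention (left, posterior, superior), the
#' native DICOM frame. Voxel indices are 0-based in the coordinate maps.
#'
#' @param dims integer vector of length 3, voxel counts `(nx, ny, nz)`.
#' @param spacing numeric length 3, mm per voxel along each axis; all > 0.
#' @param origin numeric length 3, patient-space mm of the center of voxel
#'   `(0, 0, 0)`.
#' @param orientation 3x3 matrix whose columns are the direction cosines of
#'   the voxel axes; must be orthonormal. Defaults to the identity (axis-
#'   aligned LPS).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(10, 10, 5), spacing = c(2, 2, 3))
#' voxel_volume_ml(g)  # 2*2*3 mm^3 = 0.012 mL
#' @export
volume_grid <- function(dims, spacing, origin = c(0, 0, 0),
                        orientation = diag(3)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be three positive voxel counts", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive mm values", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite mm coordinates", call. = FALSE)
  }
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6) {
    stop("`orientation` must be a 3x3 orthonormal matrix", call. = FALSE)
  }
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, spacing %s mm, origin (%s)\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Compare two grids for geometric equality
#'
#' Grids are considered the same when dims match exactly and spacing,
#' origin and orientation agree within `tol` (metadata round-trips through
#' file formats can perturb the last few bits).
#'
#' @param a,b `volume_grid` objects.
#' @param tol numeric tolerance on spacing/origin/orientation entries.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-6) {
  stopifnot(is_volume_grid(a), is_volume_grid(b))
  identical(a$dims, b$dims) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}

#' Volume of one voxel in millilitres
#'
#' @param grid a `volume_grid`.
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(is_volume_grid(grid))
  prod(grid$spacing) / 1000
}

#' Map 0-based voxel indices to patient-space mm
#'
#' @param grid a `volume_grid`.
#' @param idx numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional), or a length-3 vector.
#' @return n x 3 matrix of LPS mm coordinates.
#' @export
voxel_to_patient <- function(grid, idx) {
  stopifnot(is_volume_grid(grid))
  idx <- rbind_coords(idx)
  sweep(idx %*% diag(grid$spacing) %*% t(grid$orientation), 2,
        grid$origin, `+`)
}

#' Map patient-space mm to continuous 0-based voxel indices
#'
#' Inverse of [voxel_to_patient()]; returns fractional indices, no rounding.
#'
#' @param grid a `volume_grid`.
#' @param pts numeric matrix (n x 3) of LPS mm, or a length-3 vector.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
patient_to_voxel <- function(grid, pts) {
  stopifnot(is_volume_grid(grid))
  pts <- rbind_coords(pts)
  sweep(pts, 2, grid$origin, `-`) %*% grid$orientation %*%
    diag(1 / grid$spacing)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  x
}

# Patient-space coordinates of every voxel center, in array (column-major)
# order: first axis fastest. Returns an (n_voxels x 3) matrix.
grid_voxel_centers <- function(grid) {
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  voxel_to_patient(grid, cbind(i, j, k))
}
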