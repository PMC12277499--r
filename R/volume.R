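#' Scalar volume on a grid
#'
#' Container for a 3D lattice of stored values together with its geometry
#' and modality. PET volumes carry raw scanner counts (to be rescaled and
#' converted to SUV), CT volumes carry Hounsfield units, and `"SUV"`
#' volumes hold converted uptake values.
#'
#' @param values 3D numeric array; `dim(values)` must equal `grid$dims`.
#' @param grid a [volume_grid()].
#' @param modality one of `"CT"`, `"PET"`, `"SUV"`.
#' @return A `scalar_volume` (additionally `suv_volume` when modality is
#'   `"SUV"`).
#' @export
scalar_volume <- function(values, grid, modality = c("PET", "CT", "SUV")) {
  modality <- match.arg(modality)
  stopifnot(is_volume_grid(grid))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$dims)) {
    stop("`values` shape does not match grid dims", call. = FALSE)
  }
  storage.mode(values) <- "double"
  cls <- if (modality == "SUV") c("suv_volume", "scalar_volume") else "scalar_volume"
  structure(list(values = values, grid = grid, modality = modality),
            class = cls)
}

is_scalar_volume <- function(x) inherits(x, "scalar_volume")

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("%s volume: %s voxels, values in [%.4g, %.4g]\n", x$modality,
              paste(x$grid$dims, collapse = " x "), rng[1], rng[2]))
  invisible(x)
}

#' Binary region mask on a grid
#'
#' @param voxels logical 3D array matching `grid$dims`; `TRUE` marks
#'   membership.
#' @param grid a [volume_grid()].
#' @param label organ or lesion name carried along for reporting.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(voxels, grid, label = "") {
  stopifnot(is_volume_grid(grid))
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || !all(dim(voxels) == grid$dims)) {
    stop("mask shape does not match grid dims", call. = FALSE)
  }
  storage.mode(voxels) <- "logical"
  voxels[is.na(voxels)] <- FALSE
  structure(list(voxels = voxels, grid = grid, label = as.character(label)),
            class = "binary_mask")
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.binary_mask <- function(x, ...) {
  n <- sum(x$voxels)
  cat(sprintf("binary_mask '%s': %d voxels (%.3f mL) on %s grid\n",
              x$label, n, n * voxel_volume_ml(x$grid),
              paste(x$grid$dims, collapse = " x ")))
  invisible(x)
}

#' Total mask volume in millilitres
#'
#' @param mask a [binary_mask()].
#' @return Volume in mL (member voxel count times voxel volume).
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$voxels) * voxel_volume_ml(mask$grid)
}
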