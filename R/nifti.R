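# NIfTI I/O through RNifti. Internally everything is LPS (the DICOM
# patient frame); NIfTI affines are RAS, so the first two world axes are
# negated on the way in and out.

lps_to_ras <- diag(c(-1, -1, 1))

grid_to_affine_ras <- function(grid) {
  A <- matrix(0, 4, 4)
  A[1:3, 1:3] <- lps_to_ras %*% grid$orientation %*% diag(grid$spacing)
  A[1:3, 4] <- lps_to_ras %*% grid$origin
  A[4, 4] <- 1
  A
}

affine_ras_to_grid <- function(A, dims) {
  M <- lps_to_ras %*% A[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  volume_grid(dims, spacing, as.numeric(lps_to_ras %*% A[1:3, 4]),
              M %*% diag(1 / spacing))
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [scalar_volume()] or [binary_mask()] (masks are written as
#'   0/1 integers).
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  if (is_binary_mask(x)) {
    vals <- array(as.integer(x$voxels), x$grid$dims)
    grid <- x$grid
  } else {
    stopifnot(is_scalar_volume(x))
    vals <- x$values
    grid <- x$grid
  }
  img <- RNifti::asNifti(vals)
  m <- structure(grid_to_affine_ras(grid), code = 2L)
  img <- RNifti::`sform<-`(img, m)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path `.nii`/`.nii.gz` file.
#' @param modality modality to stamp on the result.
#' @return A [scalar_volume()] with geometry taken from the sform/qform.
#' @export
read_volume_nifti <- function(path, modality = "PET") {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  grid <- affine_ras_to_grid(unclass(RNifti::xform(img)), dims)
  scalar_volume(array(as.numeric(img), dims), grid, modality)
}

#' Write a label volume of masks to NIfTI
#'
#' Masks are burned into one integer label volume in list order (later
#' masks overwrite earlier ones where they overlap).
#'
#' @param masks named list of [binary_mask()]s on one common grid.
#' @param path output path.
#' @param labels integer labels to use, default `seq_along(masks)`.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(masks, path, labels = seq_along(masks)) {
  stopifnot(length(masks) >= 1L, length(labels) == length(masks))
  grid <- masks[[1]]$grid
  lab <- array(0L, grid$dims)
  for (i in seq_along(masks)) {
    stopifnot(grid_equal(grid, masks[[i]]$grid))
    lab[masks[[i]]$voxels] <- as.integer(labels[i])
  }
  img <- RNifti::asNifti(lab)
  m <- structure(grid_to_affine_ras(grid), code = 2L)
  img <- RNifti::`sform<-`(img, m)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume as one mask per label
#'
#' @param path NIfTI label volume (nonnegative integers; 0 is
#'   background).
#' @param grid optional [volume_grid()] the labels must live on; if the
#'   file geometry differs the labels are resampled to it
#'   (nearest-neighbor).
#' @return Named list of [binary_mask()]s, one per nonzero label, named
#'   `label_<k>`.
#' @export
read_mask <- function(path, grid = NULL) {
  vol <- read_volume_nifti(path, modality = "CT")
  vals <- vol$values
  if (max(abs(vals - round(vals))) > 1e-6 || any(vals < 0)) {
    stop("label volume must contain nonnegative integers", call. = FALSE)
  }
  vals <- round(vals)
  if (!is.null(grid) && !grid_equal(vol$grid, grid)) {
    lv <- scalar_volume(vals, vol$grid, "CT")
    vals <- resample(lv, grid, "nearest")$values
    vol$grid <- grid
  }
  labs <- sort(setdiff(unique(as.vector(vals)), 0))
  if (!length(labs)) return(structure(list(), names = character(0)))
  out <- lapply(labs, function(l) {
    binary_mask(vals == l, vol$grid, paste0("label_", l))
  })
  names(out) <- paste0("label_", labs)
  out
}
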