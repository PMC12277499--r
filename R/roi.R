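#' Centroid of a mask in patient space
#'
#' Unweighted mean of the member-voxel center coordinates. For concave
#' regions the centroid may fall outside the mask; it is reported as-is
#' (sphere placement does not snap back inside).
#'
#' @param mask a non-empty [binary_mask()].
#' @return Length-3 numeric, LPS mm.
#' @export
mask_centroid <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sel <- which(mask$voxels)
  if (!length(sel)) stop("mask is empty", call. = FALSE)
  idx <- arrayInd(sel, dim(mask$voxels)) - 1L
  colMeans(voxel_to_patient(mask$grid, idx))
}

#' Fixed-radius spherical VOI
#'
#' The 1.2 cm-radius sphere used for single-VOI SUVmean readings,
#' centered at an organ centroid by convention.
#'
#' @param center patient-space mm.
#' @param radius mm, > 0; default 12 (1.2 cm).
#' @return A `spherical_voi`.
#' @export
spherical_voi <- function(center, radius = 12) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be three finite mm coordinates", call. = FALSE)
  }
  if (!is.finite(radius) || radius <= 0) {
    stop("`radius` must be > 0", call. = FALSE)
  }
  structure(list(center = center, radius = as.numeric(radius)),
            class = "spherical_voi")
}

#' Rasterize a spherical VOI onto a grid
#'
#' A voxel is included iff its center lies within `radius` of the sphere
#' center (no partial volumes, so counts are deterministic).
#'
#' @param grid a [volume_grid()].
#' @param voi a [spherical_voi()].
#' @return A [binary_mask()].
#' @export
sphere_voi_mask <- function(grid, voi) {
  stopifnot(is_volume_grid(grid), inherits(voi, "spherical_voi"))
  idx <- patient_to_voxel(grid, voi$center)
  if (any(idx < -0.5) || any(idx > grid$dims - 0.5)) {
    stop("sphere center lies outside the grid extent", call. = FALSE)
  }
  ctr <- grid_voxel_centers(grid)
  d2 <- rowSums(sweep(ctr, 2, voi$center, `-`)^2)
  m <- binary_mask(array(d2 <= voi$radius^2, grid$dims), grid, "sphere_voi")
  if (!any(m$voxels)) {
    stop("sphere contains no voxel centers on this grid", call. = FALSE)
  }
  m
}

#' SUV statistics over a region
#'
#' SUVmax (ties broken by the lowest linear voxel index, location
#' reported), SUVmean (arithmetic mean), voxel count and volume over the
#' member voxels of a mask sharing the SUV volume's grid.
#'
#' @param suv an SUV [scalar_volume()] (see [convert_to_suv()]).
#' @param mask a non-empty [binary_mask()] on the same grid.
#' @return A `roi_statistics` list: `suv_max`, `suv_mean`,
#'   `max_voxel` (1-based array index), `max_location_mm`,
#'   `voxel_count`, `volume_ml`.
#' @export
roi_statistics <- function(suv, mask) {
  stopifnot(is_scalar_volume(suv), is_binary_mask(mask))
  if (!grid_equal(suv$grid, mask$grid)) {
    stop("SUV volume and mask are on different grids", call. = FALSE)
  }
  sel <- which(mask$voxels)
  if (!length(sel)) stop("mask is empty", call. = FALSE)
  vals <- suv$values[sel]
  imax <- sel[which.max(vals)]  # which.max: first (lowest linear index) tie
  idx <- arrayInd(imax, dim(suv$values))
  structure(list(
    suv_max = max(vals),
    suv_mean = mean(vals),
    max_voxel = as.integer(idx),
    max_location_mm = as.numeric(voxel_to_patient(suv$grid, idx - 1L)),
    voxel_count = length(sel),
    volume_ml = length(sel) * voxel_volume_ml(suv$grid)),
    class = "roi_statistics")
}

#' @export
print.roi_statistics <- function(x, ...) {
  cat(sprintf("ROI: SUVmax %.4g at (%s) mm, SUVmean %.4g, %d voxels (%.3f mL)\n",
              x$suv_max, paste(sprintf("%.1f", x$max_location_mm), collapse = ", "),
              x$suv_mean, x$voxel_count, x$volume_ml))
  invisible(x)
}

#' Organ-level SUV report: whole contour vs single spherical VOI
#'
#' For each labelled organ mask, computes SUVmax and SUVmean over the
#' whole-organ contour and SUVmean over a fixed-radius spherical VOI at
#' the organ centroid — the two measurement routes whose disagreement
#' the package quantifies.
#'
#' @param suv an SUV [scalar_volume()].
#' @param masks named list of [binary_mask()]s on the SUV grid.
#' @param voi_radius sphere radius in mm (default 12).
#' @return data.frame: `organ`, `suv_max`, `suv_mean_contour`,
#'   `suv_mean_voi`, `volume_ml`.
#' @export
organ_suv_report <- function(suv, masks, voi_radius = 12) {
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    st <- roi_statistics(suv, m)
    sph <- sphere_voi_mask(suv$grid, spherical_voi(mask_centroid(m), voi_radius))
    data.frame(organ = nm, suv_max = st$suv_max,
               suv_mean_contour = st$suv_mean,
               suv_mean_voi = roi_statistics(suv, sph)$suv_mean,
               volume_ml = st$volume_ml)
  })
  do.call(rbind, rows)
}
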