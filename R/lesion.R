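#' Delineate a lesion at a fraction of SUVmax
#'
#' Classic fractional-SUVmax thresholding: the reference is the SUVmax
#' over the organ mask, and the lesion is every organ voxel with SUV
#' greater than or equal to `fraction` times that reference (inclusive,
#' so the maximum voxel always belongs to the lesion). Clinically used
#' fractions are 0.4 and 0.5. By default all supra-threshold voxels form
#' the lesion; `largest_component = TRUE` keeps only the largest
#' 6-connected component.
#'
#' @param suv an SUV [scalar_volume()].
#' @param organ non-empty [binary_mask()] on the same grid.
#' @param fraction threshold fraction in (0, 1).
#' @param largest_component keep only the largest connected component.
#' @return A `lesion_segmentation`: `fraction`, `reference_suv_max`,
#'   `mask`, `voxel_count`, `volume_ml`, `suv_mean`, `tlg`,
#'   `bounding_box` (1-based index ranges) and `voxel_coords_mm`.
#' @export
delineate_by_fraction <- function(suv, organ, fraction,
                                  largest_component = FALSE) {
  stopifnot(is_scalar_volume(suv), is_binary_mask(organ))
  if (!grid_equal(suv$grid, organ$grid)) {
    stop("SUV volume and organ mask are on different grids", call. = FALSE)
  }
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  ref <- roi_statistics(suv, organ)$suv_max
  if (ref <= 0) {
    stop("organ SUVmax is not positive; cannot threshold", call. = FALSE)
  }
  inside <- organ$voxels & (suv$values >= fraction * ref)
  mask <- binary_mask(inside, suv$grid,
                      paste0(organ$label, "_lesion", fraction))
  if (largest_component && any(inside)) {
    mask <- largest_connected_component(mask)
  }
  sel <- which(mask$voxels)
  vv <- voxel_volume_ml(suv$grid)
  idx <- arrayInd(sel, dim(mask$voxels))
  structure(list(
    fraction = fraction,
    reference_suv_max = ref,
    mask = mask,
    voxel_count = length(sel),
    volume_ml = length(sel) * vv,
    suv_mean = mean(suv$values[sel]),
    tlg = sum(suv$values[sel]) * vv,
    bounding_box = if (length(sel)) apply(idx, 2, range) else NULL,
    voxel_coords_mm = voxel_to_patient(suv$grid, idx - 1L)),
    class = "lesion_segmentation")
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  cat(sprintf(paste0("lesion at %.0f%% of SUVmax %.4g: %d voxels, ",
                     "%.3f mL, SUVmean %.4g, TLG %.4g\n"),
              100 * x$fraction, x$reference_suv_max, x$voxel_count,
              x$volume_ml, x$suv_mean, x$tlg))
  invisible(x)
}

# Largest 6-connected component of a mask (flood fill).
largest_connected_component <- function(mask) {
  d <- dim(mask$voxels)
  lab <- array(0L, d)
  cur <- 0L
  todo <- which(mask$voxels & lab == 0L)
  offsets <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                   c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    while (length(queue)) {
      idx <- arrayInd(queue, d)
      nxt <- integer(0)
      for (o in seq_len(6)) {
        nb <- sweep(idx, 2, offsets[o, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        lin <- nb[ok, , drop = FALSE]
        lin <- lin[, 1] + d[1] * (lin[, 2] - 1L) + d[1] * d[2] * (lin[, 3] - 1L)
        lin <- lin[mask$voxels[lin] & lab[lin] == 0L]
        lab[lin] <- cur
        nxt <- c(nxt, lin)
      }
      queue <- unique(nxt)
    }
    todo <- which(mask$voxels & lab == 0L)
  }
  counts <- tabulate(lab[lab > 0L], nbins = cur)
  keep <- which.max(counts)
  binary_mask(lab == keep, mask$grid, mask$label)
}

#' Total lesion glycolysis
#'
#' TLG integrates uptake over the lesion: the per-voxel sum of SUV times
#' voxel volume (mL), identically equal to SUVmean times lesion volume.
#' Units are SUV·mL.
#'
#' @param lesion a `lesion_segmentation` from [delineate_by_fraction()].
#' @return TLG (SUV·mL); 0 with a warning for an empty lesion.
#' @export
total_lesion_glycolysis <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_segmentation"))
  if (lesion$voxel_count == 0L) {
    warning("empty lesion; TLG is 0")
    return(0)
  }
  lesion$tlg
}

#' Cumulative SUV histogram
#'
#' For each threshold `t`, the fraction of the region's volume with SUV
#' at or above `t`. Thresholds span `[0, SUVmax]` of the region, either
#' as absolute SUV or as percent of SUVmax (0–100%). The curve is
#' non-increasing and starts at 1 when all SUVs are nonnegative; its
#' shape separates hot lesions (convex downward, mass retained at high
#' thresholds) from healthy tissue (convex upward).
#'
#' @param suv an SUV [scalar_volume()].
#' @param mask non-empty [binary_mask()] on the same grid.
#' @param mode `"percent_of_max"` (default) or `"absolute"`.
#' @param n_bins number of thresholds (>= 2); default 101 (0–100% in 1%
#'   steps).
#' @return A `cumulative_suv_histogram` data.frame with columns
#'   `threshold` (SUV or percent) and `fraction`.
#' @export
cumulative_suv_histogram <- function(suv, mask,
                                     mode = c("percent_of_max", "absolute"),
                                     n_bins = 101) {
  mode <- match.arg(mode)
  stopifnot(is_scalar_volume(suv), is_binary_mask(mask))
  if (!grid_equal(suv$grid, mask$grid)) {
    stop("SUV volume and mask are on different grids", call. = FALSE)
  }
  sel <- which(mask$voxels)
  if (!length(sel)) stop("mask is empty", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  vals <- suv$values[sel]
  smax <- max(vals)
  abs_thr <- seq(0, max(smax, 0), length.out = n_bins)
  fraction <- vapply(abs_thr, function(t) mean(vals >= t), 0)
  thr <- if (mode == "percent_of_max") {
    seq(0, 100, length.out = n_bins)
  } else {
    abs_thr
  }
  structure(data.frame(threshold = thr, fraction = fraction),
            class = c("cumulative_suv_histogram", "data.frame"),
            mode = mode, suv_max = smax)
}
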