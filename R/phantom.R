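#' Describe one ellipsoidal organ of a phantom
#'
#' Organs are axis-aligned ellipsoids with a CT attenuation value and a
#' target uptake, standing in for the contoured structures of a breast
#' FDG-PET study (breasts, liver, spleen, bone marrow) without any claim
#' to anatomical realism.
#'
#' @param name unique label string.
#' @param center patient-space mm, ellipsoid center.
#' @param semi_axes mm, the three semi-axes; all > 0.
#' @param ct_value attenuation in Hounsfield units painted into the CT.
#' @param suv target body-weight SUV painted into the PET (the raw stored
#'   values are synthesized so that SUV conversion recovers this value).
#' @return An `organ_spec`.
#' @export
organ_spec <- function(name, center, semi_axes, ct_value, suv) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("`semi_axes` must be three positive mm values", call. = FALSE)
  }
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be three finite mm coordinates", call. = FALSE)
  }
  structure(list(name = as.character(name), center = center,
                 semi_axes = semi_axes, ct_value = as.numeric(ct_value),
                 suv = as.numeric(suv)),
            class = "organ_spec")
}

#' Full specification of a dual-grid PET/CT phantom
#'
#' The CT and PET lattices deliberately differ (finer CT, coarser PET)
#' so grid transfer is exercised the way clinical series demand it. A
#' `tumor` is an extra ellipsoid with elevated uptake allowed to sit
#' inside a host organ; ordinary organs must not overlap.
#'
#' @param ct_grid,pet_grid [volume_grid()]s covering a common extent.
#' @param organs list of [organ_spec()]s with unique names.
#' @param tumor optional [organ_spec()] with elevated uptake; may overlap
#'   organs (its uptake overrides theirs).
#' @param noise_sd standard deviation of additive Gaussian noise applied
#'   to raw PET stored values (clipped at zero); >= 0.
#' @param suv_params [suv_parameters()] used both to synthesize raw
#'   values and, downstream, to convert them back.
#' @param background_ct CT value outside all organs (HU), default -1000
#'   (air).
#' @param seed integer seed making noise reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(ct_grid, pet_grid, organs, tumor = NULL,
                         noise_sd = 0, suv_params = default_suv_params(),
                         background_ct = -1000, seed = 1L) {
  stopifnot(is_volume_grid(ct_grid), is_volume_grid(pet_grid),
            is_suv_parameters(suv_params))
  if (!is.list(organs) || !all(vapply(organs, inherits, TRUE, "organ_spec"))) {
    stop("`organs` must be a list of organ_spec objects", call. = FALSE)
  }
  nms <- vapply(organs, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("organ labels must be unique: ", nms[duplicated(nms)][1], call. = FALSE)
  }
  if (!is.null(tumor) && !inherits(tumor, "organ_spec")) {
    stop("`tumor` must be an organ_spec or NULL", call. = FALSE)
  }
  noise_sd <- as.numeric(noise_sd)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(ct_grid = ct_grid, pet_grid = pet_grid, organs = organs,
                 tumor = tumor, noise_sd = noise_sd, suv_params = suv_params,
                 background_ct = as.numeric(background_ct),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Typical acquisition metadata for a phantom
#'
#' 70 kg patient, 370 MBq injected dose (a routine 5.18 MBq/kg FDG
#' activity at that weight), 60 min uptake, F-18 half-life.
#'
#' @param rescale_slope stored-value scaling; the default keeps raw
#'   values in a 16-bit-friendly range.
#' @return An [suv_parameters()] object.
#' @export
default_suv_params <- function(rescale_slope = 0.5) {
  suv_parameters(patient_weight = 70, total_dose = 3.7e8,
                 radiopharmaceutical_start_time = 9 * 3600,
                 series_time = 10 * 3600,
                 half_life = fdg_half_life_s(),
                 rescale_slope = rescale_slope)
}

#' Rasterize an ellipsoid onto a grid
#'
#' A voxel belongs to the ellipsoid iff its center lies inside it — no
#' fractional occupancy — so masks are exactly reproducible.
#'
#' @param grid target [volume_grid()].
#' @param organ an [organ_spec()] (only center/semi-axes are used).
#' @return A [binary_mask()] labelled with the organ name.
#' @export
rasterize_ellipsoid <- function(grid, organ) {
  ctr <- grid_voxel_centers(grid)
  u <- sweep(ctr, 2, organ$center, `-`)
  u <- sweep(u, 2, organ$semi_axes, `/`)
  inside <- rowSums(u * u) <= 1
  binary_mask(array(inside, grid$dims), grid, organ$name)
}

#' Generate a paired CT/PET phantom with known truth
#'
#' Paints each organ's HU into the CT grid and synthesizes raw PET stored
#' values by inverting the SUV formula, so that [convert_to_suv()] on the
#' noise-free phantom returns each organ's target SUV exactly. The tumor,
#' when present, overrides host-organ uptake inside its own extent.
#' Masks are exact center-in-ellipsoid rasterizations on both grids.
#' Optional Gaussian noise (sd `spec$noise_sd`, clipped at zero) is added
#' to the raw PET values; the result is deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `ct` (CT `scalar_volume`), `pet_raw`
#'   (PET `scalar_volume` of stored values), `masks_ct` and `masks_pet`
#'   (named lists of [binary_mask()]s per organ, tumor included), and
#'   `truth` (named numeric vector of target SUVs).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  all_regions <- spec$organs
  if (!is.null(spec$tumor)) all_regions <- c(all_regions, list(spec$tumor))

  masks_ct <- lapply(all_regions, function(o) rasterize_ellipsoid(spec$ct_grid, o))
  masks_pet <- lapply(all_regions, function(o) rasterize_ellipsoid(spec$pet_grid, o))
  names(masks_ct) <- names(masks_pet) <-
    vapply(all_regions, `[[`, "", "name")

  n_org <- length(spec$organs)
  if (n_org > 1L) {
    for (i in seq_len(n_org - 1L)) {
      for (j in seq(i + 1L, n_org)) {
        if (any(masks_ct[[i]]$voxels & masks_ct[[j]]$voxels) ||
            any(masks_pet[[i]]$voxels & masks_pet[[j]]$voxels)) {
          stop(sprintf("organs '%s' and '%s' overlap",
                       names(masks_ct)[i], names(masks_ct)[j]),
               call. = FALSE)
        }
      }
    }
  }

  ct_vals <- array(spec$background_ct, spec$ct_grid$dims)
  pet_vals <- array(suv_to_stored_value(0, spec$suv_params),
                    spec$pet_grid$dims)
  for (i in seq_len(n_org)) {
    o <- spec$organs[[i]]
    ct_vals[masks_ct[[i]]$voxels] <- o$ct_value
    pet_vals[masks_pet[[i]]$voxels] <- suv_to_stored_value(o$suv, spec$suv_params)
  }
  if (!is.null(spec$tumor)) {
    tm_ct <- masks_ct[[n_org + 1L]]
    tm_pet <- masks_pet[[n_org + 1L]]
    ct_vals[tm_ct$voxels] <- spec$tumor$ct_value
    pet_vals[tm_pet$voxels] <- suv_to_stored_value(spec$tumor$suv, spec$suv_params)
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    pet_vals <- pet_vals + stats::rnorm(length(pet_vals), sd = spec$noise_sd)
    pet_vals[pet_vals < 0] <- 0
  }

  truth <- vapply(all_regions, `[[`, 0, "suv")
  names(truth) <- names(masks_ct)

  list(ct = scalar_volume(ct_vals, spec$ct_grid, "CT"),
       pet_raw = scalar_volume(pet_vals, spec$pet_grid, "PET"),
       masks_ct = masks_ct,
       masks_pet = masks_pet,
       truth = truth)
}

#' A ready-made small phantom specification
#'
#' Convenience builder for a torso-like field of view holding five
#' non-overlapping organs with typical FDG uptake (liver SUVmean near 2,
#' spleen and marrow below it, low breast background) and, optionally, a
#' hot breast tumor. The dual-grid geometry follows the acquisition
#' pattern of whole-body FDG PET/CT — CT finer in-plane than PET — scaled
#' to a desk-size extent; `scale = "study"` instead reproduces the full
#' 512x512 CT / 200x200 PET in-plane matrices at 3 mm slices.
#'
#' @param scale `"desk"` (default, 48 mm cube extent class grids) or
#'   `"study"` (full clinical matrix sizes; large).
#' @param tumor_suv target SUV of the tumor, or `NULL` for no tumor.
#' @param noise_sd,seed passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
example_phantom_spec <- function(scale = c("desk", "study"), tumor_suv = 8,
                                 noise_sd = 0, seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    ct_grid <- volume_grid(c(48, 48, 24), spacing = c(1.5, 1.5, 3))
    pet_grid <- volume_grid(c(24, 24, 24), spacing = c(3, 3, 3))
  } else {
    ct_grid <- volume_grid(c(512, 512, 284), spacing = c(1.0, 1.0, 3))
    pet_grid <- volume_grid(c(200, 200, 283), spacing = c(2.6, 2.6, 3))
  }
  extent <- (ct_grid$dims - 1) * ct_grid$spacing
  cx <- extent / 2
  s <- min(extent) / 48  # organ sizes scale with the field of view
  organs <- list(
    organ_spec("breast_right", cx + c(-14, -10, 0) * s, c(9, 8, 8) * s,
               ct_value = -60, suv = 0.8),
    organ_spec("breast_left", cx + c(14, -10, 0) * s, c(9, 8, 8) * s,
               ct_value = -60, suv = 0.8),
    organ_spec("liver", cx + c(-8, 10, 8) * s, c(11, 8, 7) * s,
               ct_value = 60, suv = 2.0),
    organ_spec("spleen", cx + c(13, 10, 8) * s, c(6, 6, 6) * s,
               ct_value = 50, suv = 1.6),
    organ_spec("bone_marrow", cx + c(0, 10, -10) * s, c(16, 4, 4) * s,
               ct_value = 200, suv = 1.2))
  tumor <- NULL
  if (!is.null(tumor_suv)) {
    tumor <- organ_spec("tumor", cx + c(-14, -10, 0) * s, c(3.5, 3, 3) * s,
                        ct_value = 40, suv = tumor_suv)
  }
  phantom_spec(ct_grid, pet_grid, organs, tumor = tumor,
               noise_sd = noise_sd, seed = seed)
}
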