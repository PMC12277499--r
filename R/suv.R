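#' Acquisition parameters for body-weight SUV conversion
#'
#' Bundles every quantity the SUV formula needs: stored PET values are
#' first mapped to activity concentration (Bq/mL) through the DICOM
#' rescale factor, then normalized by the decay-corrected injected dose
#' per gram of body weight.
#'
#' @param patient_weight body weight in kg (> 0).
#' @param total_dose injected radionuclide dose in Bq (> 0).
#' @param radiopharmaceutical_start_time injection clock time, seconds
#'   since midnight.
#' @param series_time scan initiation clock time, seconds since midnight.
#'   If earlier than the start time the scan is assumed to have crossed
#'   midnight and 24 h are added when computing the uptake interval.
#' @param half_life radionuclide half-life in seconds (> 0); defaults to
#'   F-18 (`fdg_half_life_s()`).
#' @param rescale_slope,rescale_intercept DICOM real-world value mapping
#'   applied to stored values before conversion; slope must be nonzero.
#' @return A `suv_parameters` object.
#' @seealso [convert_to_suv()], [decay_factor()]
#' @export
suv_parameters <- function(patient_weight, total_dose,
                           radiopharmaceutical_start_time, series_time,
                           half_life = fdg_half_life_s(),
                           rescale_slope = 1, rescale_intercept = 0) {
  p <- list(patient_weight = as.numeric(patient_weight),
            total_dose = as.numeric(total_dose),
            radiopharmaceutical_start_time =
              as.numeric(radiopharmaceutical_start_time),
            series_time = as.numeric(series_time),
            half_life = as.numeric(half_life),
            rescale_slope = as.numeric(rescale_slope),
            rescale_intercept = as.numeric(rescale_intercept))
  for (nm in names(p)) {
    if (length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (p$patient_weight <= 0) stop("patient_weight must be > 0", call. = FALSE)
  if (p$total_dose <= 0) stop("total_dose must be > 0", call. = FALSE)
  if (p$half_life <= 0) stop("half_life must be > 0", call. = FALSE)
  if (p$rescale_slope == 0) stop("rescale_slope must be nonzero", call. = FALSE)
  structure(p, class = "suv_parameters")
}

is_suv_parameters <- function(x) inherits(x, "suv_parameters")

#' F-18 physical half-life in seconds
#'
#' Default used when a PET series carries no radionuclide half-life tag.
#'
#' @return 6586.2 seconds (109.77 min).
#' @export
fdg_half_life_s <- function() 6586.2

#' Radioactive decay factor
#'
#' Fraction of activity remaining after `delta_t` seconds:
#' `2^(-delta_t / half_life)`. Lies in (0, 1] for nonnegative `delta_t`.
#'
#' @param delta_t elapsed time in seconds (may be a vector).
#' @param half_life half-life in seconds, > 0.
#' @return Numeric decay factor(s).
#' @examples
#' decay_factor(0, 6586.2)       # 1
#' decay_factor(6586.2, 6586.2)  # 0.5
#' @export
decay_factor <- function(delta_t, half_life) {
  half_life <- as.numeric(half_life)
  if (length(half_life) != 1L || !is.finite(half_life) || half_life <= 0) {
    stop("half_life must be a single positive number", call. = FALSE)
  }
  2^(-as.numeric(delta_t) / half_life)
}

# Uptake interval in seconds, adding 24 h when the series time has wrapped
# past midnight relative to the injection time.
uptake_interval_s <- function(params) {
  dt <- params$series_time - params$radiopharmaceutical_start_time
  if (dt < 0) dt <- dt + 86400
  dt
}

#' Convert a raw PET volume to body-weight SUV
#'
#' Applies, voxel-wise,
#' \deqn{SUV = \frac{(value \cdot slope + intercept) \cdot W_g}
#'                  {D \cdot 2^{-\Delta t / T_{1/2}}}}
#' where \eqn{W_g} is the patient weight in grams, \eqn{D} the injected
#' dose in Bq and \eqn{\Delta t} the series-minus-injection interval.
#' With concentrations in Bq/mL this yields the conventional
#' dimensionless (g/mL) body-weight SUV. Negative rescaled values are
#' passed through unchanged; clipping is a display concern.
#'
#' @param volume a PET [scalar_volume()].
#' @param params an [suv_parameters()] object.
#' @return An `suv_volume` on the same grid.
#' @examples
#' g <- volume_grid(c(2, 2, 1), c(4, 4, 4))
#' v <- scalar_volume(array(100, c(2, 2, 1)), g, "PET")
#' p <- suv_parameters(70, 3.5e8, 0, 0, rescale_slope = 1)
#' convert_to_suv(v, p)$values[1]  # 100 * 70000 / 3.5e8 = 0.02
#' @export
convert_to_suv <- function(volume, params) {
  stopifnot(is_scalar_volume(volume), is_suv_parameters(params))
  if (volume$modality != "PET") {
    stop("convert_to_suv expects a PET volume", call. = FALSE)
  }
  dt <- uptake_interval_s(params)
  decay <- decay_factor(dt, params$half_life)
  conc <- volume$values * params$rescale_slope + params$rescale_intercept
  suv <- conc * (params$patient_weight * 1000) / (params$total_dose * decay)
  scalar_volume(suv, volume$grid, "SUV")
}

# Inverse of convert_to_suv for a scalar target: the stored value whose
# conversion under `params` gives `suv`. Used by the phantom generator so
# the conversion path is exercised against known truth.
suv_to_stored_value <- function(suv, params) {
  dt <- uptake_interval_s(params)
  decay <- decay_factor(dt, params$half_life)
  conc <- suv * params$total_dose * decay / (params$patient_weight * 1000)
  (conc - params$rescale_intercept) / params$rescale_slope
}
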