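# Minimal DICOM codec: explicit VR little endian, one frame per file,
# defined-length sequences. Covers exactly the attributes the SUV
# formula and slice geometry require; anything else (compressed transfer
# syntaxes, multi-frame enhanced objects, RTSTRUCT) is out of scope.

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UN", "UT")

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(bytes, pad = as.raw(0L)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_string_value <- function(x, ui = FALSE) {
  dcm_pad(charToRaw(paste(x, collapse = "\\")),
          pad = if (ui) as.raw(0L) else charToRaw(" "))
}

# DS values are limited to 16 bytes each.
dcm_ds_value <- function(x) {
  dcm_string_value(vapply(x, function(v) {
    s <- format(v, digits = 10, scientific = FALSE, trim = TRUE)
    if (nchar(s) > 16) s <- formatC(v, digits = 9, format = "g")
    s
  }, ""))
}

dcm_element <- function(group, elem, vr, value) {
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% dcm_long_vrs) {
    c(hdr, as.raw(c(0L, 0L)), u32le(length(value)), value)
  } else {
    if (length(value) > 65534) stop("value too long for short VR")
    c(hdr, u16le(length(value)), value)
  }
}

dcm_sequence_item <- function(elements) {
  body <- do.call(c, elements)
  c(u16le(0xFFFE), u16le(0xE000), u32le(length(body)), body)
}

dcm_uid <- function(...) {
  # Deterministic study-free UIDs under a test root.
  paste("1.2.826.0.1.3680043.9999", ..., sep = ".")
}

#' Write one DICOM slice file
#'
#' Emits a minimal single-frame explicit-VR-little-endian file. Pixel
#' data are 16-bit unsigned, row-major (row direction = second grid
#' axis).
#'
#' @param path output file.
#' @param pixels integer matrix (nx columns direction x first index) of
#'   stored values, 0..65535.
#' @param meta named list with entries: `modality`, `rows`, `cols`,
#'   `pixel_spacing` (row, col mm), `slice_thickness`,
#'   `image_position` (LPS mm), `image_orientation` (6 direction
#'   cosines), `series_uid`, `instance` (number), `series_time`,
#'   `acquisition_time`, `rescale_slope`, `rescale_intercept`,
#'   `patient_weight` (kg, or NULL to omit), `total_dose` (Bq or NULL),
#'   `start_time` (or NULL), `half_life` (s or NULL).
#' @return `path`, invisibly.
#' @keywords internal
write_dicom_slice <- function(path, pixels, meta) {
  stopifnot(is.matrix(pixels))
  pix <- as.integer(round(pixels))
  if (any(pix < 0L) || any(pix > 65535L)) {
    stop("stored values must fit unsigned 16-bit; adjust rescale_slope",
         call. = FALSE)
  }
  pix_raw <- writeBin(pix, raw(), size = 2, endian = "little")

  sop_class <- if (identical(meta$modality, "CT")) {
    "1.2.840.10008.5.1.4.1.1.2"
  } else {
    "1.2.840.10008.5.1.4.1.1.128"
  }
  sop_uid <- dcm_uid(meta$series_root %||% "1", meta$instance)

  els <- list()
  add <- function(g, e, vr, val) els[[length(els) + 1L]] <<- dcm_element(g, e, vr, val)

  add(0x0008, 0x0016, "UI", dcm_string_value(sop_class, ui = TRUE))
  add(0x0008, 0x0018, "UI", dcm_string_value(sop_uid, ui = TRUE))
  if (!is.null(meta$series_time)) {
    add(0x0008, 0x0031, "TM", dcm_string_value(meta$series_time))
  }
  if (!is.null(meta$acquisition_time)) {
    add(0x0008, 0x0032, "TM", dcm_string_value(meta$acquisition_time))
  }
  add(0x0008, 0x0060, "CS", dcm_string_value(meta$modality))
  if (!is.null(meta$patient_weight)) {
    add(0x0010, 0x1030, "DS", dcm_ds_value(meta$patient_weight))
  }
  add(0x0018, 0x0050, "DS", dcm_ds_value(meta$slice_thickness))
  add(0x0020, 0x000D, "UI", dcm_string_value(dcm_uid("study"), ui = TRUE))
  add(0x0020, 0x000E, "UI", dcm_string_value(meta$series_uid, ui = TRUE))
  add(0x0020, 0x0013, "IS", dcm_string_value(as.character(meta$instance)))
  add(0x0020, 0x0032, "DS", dcm_ds_value(meta$image_position))
  add(0x0020, 0x0037, "DS", dcm_ds_value(meta$image_orientation))
  add(0x0028, 0x0002, "US", u16le(1))
  add(0x0028, 0x0004, "CS", dcm_string_value("MONOCHROME2"))
  add(0x0028, 0x0010, "US", u16le(meta$rows))
  add(0x0028, 0x0011, "US", u16le(meta$cols))
  add(0x0028, 0x0030, "DS", dcm_ds_value(meta$pixel_spacing))
  add(0x0028, 0x0100, "US", u16le(16))
  add(0x0028, 0x0101, "US", u16le(16))
  add(0x0028, 0x0102, "US", u16le(15))
  add(0x0028, 0x0103, "US", u16le(0))
  add(0x0028, 0x1052, "DS", dcm_ds_value(meta$rescale_intercept %||% 0))
  add(0x0028, 0x1053, "DS", dcm_ds_value(meta$rescale_slope %||% 1))
  if (!is.null(meta$total_dose) || !is.null(meta$start_time) ||
      !is.null(meta$half_life)) {
    item <- list()
    if (!is.null(meta$start_time)) {
      item[[length(item) + 1L]] <-
        dcm_element(0x0018, 0x1072, "TM", dcm_string_value(meta$start_time))
    }
    if (!is.null(meta$total_dose)) {
      item[[length(item) + 1L]] <-
        dcm_element(0x0018, 0x1074, "DS", dcm_ds_value(meta$total_dose))
    }
    if (!is.null(meta$half_life)) {
      item[[length(item) + 1L]] <-
        dcm_element(0x0018, 0x1075, "DS", dcm_ds_value(meta$half_life))
    }
    add(0x0054, 0x0016, "SQ", dcm_sequence_item(item))
  }
  add(0x7FE0, 0x0010, "OW", pix_raw)

  body <- do.call(c, els)

  meta_els <- c(
    dcm_element(0x0002, 0x0002, "UI", dcm_string_value(sop_class, ui = TRUE)),
    dcm_element(0x0002, 0x0003, "UI", dcm_string_value(sop_uid, ui = TRUE)),
    dcm_element(0x0002, 0x0010, "UI",
                dcm_string_value("1.2.840.10008.1.2.1", ui = TRUE)))
  header <- c(raw(128), charToRaw("DICM"),
              dcm_element(0x0002, 0x0000, "UL", u32le(length(meta_els))),
              meta_els)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reading ----------------------------------------------------------

dcm_read_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_read_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

dcm_parse_value <- function(vr, bytes) {
  switch(vr,
    DS = as.numeric(strsplit(rawToChar(bytes), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(rawToChar(bytes), "\\", fixed = TRUE)[[1]]),
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    OW = ,
    OB = bytes,
    {
      s <- rawToChar(bytes[bytes != as.raw(0L)])
      trimws(s)
    })
}

# Parses a dataset between pos and end (1-based raw indices); returns
# list(elements = named list keyed "GGGGEEEE", pos = next position).
dcm_parse_dataset <- function(raw, pos, end) {
  out <- list()
  while (pos + 7L <= end + 1L && pos < end) {
    group <- dcm_read_u16(raw, pos)
    elem <- dcm_read_u16(raw, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {  # item delimiters inside sequences
      len <- dcm_read_u32(raw, pos)
      pos <- pos + 4L
      if (elem == 0xE000) {
        # shouldn't occur at dataset level; skip into it
        next
      }
      next
    }
    vr <- rawToChar(raw[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% dcm_long_vrs) {
      len <- dcm_read_u32(raw, pos + 2L)
      pos <- pos + 6L
    } else {
      len <- dcm_read_u16(raw, pos)
      pos <- pos + 2L
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      if (len == 4294967295) {  # undefined length: scan to delimiter
        items <- list()
        repeat {
          g2 <- dcm_read_u16(raw, pos); e2 <- dcm_read_u16(raw, pos + 2L)
          l2 <- dcm_read_u32(raw, pos + 4L)
          pos <- pos + 8L
          if (g2 == 0xFFFE && e2 == 0xE0DD) break
          if (g2 == 0xFFFE && e2 == 0xE000) {
            parsed <- dcm_parse_dataset(raw, pos, pos + l2 - 1L)
            items[[length(items) + 1L]] <- parsed$elements
            pos <- pos + l2
          } else stop("malformed sequence", call. = FALSE)
        }
        out[[key]] <- items
      } else {
        sq_end <- pos + len - 1L
        items <- list()
        while (pos < sq_end) {
          g2 <- dcm_read_u16(raw, pos); e2 <- dcm_read_u16(raw, pos + 2L)
          l2 <- dcm_read_u32(raw, pos + 4L)
          pos <- pos + 8L
          if (g2 != 0xFFFE || e2 != 0xE000) stop("malformed sequence item",
                                                call. = FALSE)
          parsed <- dcm_parse_dataset(raw, pos, pos + l2 - 1L)
          items[[length(items) + 1L]] <- parsed$elements
          pos <- pos + l2
        }
        out[[key]] <- items
      }
    } else {
      bytes <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
      out[[key]] <- dcm_parse_value(vr, bytes)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos)
}

#' Read one DICOM file
#'
#' Supports explicit VR little endian only (the transfer syntax this
#' package writes); other transfer syntaxes raise an error.
#'
#' @param path DICOM file.
#' @return Named list of parsed elements keyed `"GGGGEEEE"`.
#' @keywords internal
read_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140 ||
      rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  parsed <- dcm_parse_dataset(bytes, 133L, length(bytes))
  ts <- parsed$elements[["00020010"]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
    stop("unsupported transfer syntax ", ts, call. = FALSE)
  }
  parsed$elements
}

#' Parse a DICOM time string
#'
#' Accepts `HHMMSS` or `HHMMSS.FFFFFF`; fractional seconds are
#' preserved.
#'
#' @param time_string character scalar.
#' @return Seconds since midnight (numeric).
#' @examples
#' parse_dicom_time("130512.5")  # 47112.5
#' @export
parse_dicom_time <- function(time_string) {
  if (length(time_string) != 1L || is.na(time_string)) {
    stop("time string must be a single value", call. = FALSE)
  }
  s <- trimws(as.character(time_string))
  if (!grepl("^[0-9]{6}(\\.[0-9]+)?$", s)) {
    stop("malformed DICOM time: '", s, "' (expect HHMMSS[.FFFFFF])",
         call. = FALSE)
  }
  hh <- as.numeric(substr(s, 1, 2))
  mm <- as.numeric(substr(s, 3, 4))
  ss <- as.numeric(substr(s, 5, nchar(s)))
  if (hh >= 24 || mm >= 60 || ss >= 60) {
    stop("invalid DICOM time: '", s, "'", call. = FALSE)
  }
  hh * 3600 + mm * 60 + ss
}

seconds_to_dicom_time <- function(sec) {
  hh <- floor(sec / 3600)
  mm <- floor((sec - hh * 3600) / 60)
  ss <- sec - hh * 3600 - mm * 60
  sprintf("%02d%02d%09.6f", hh, mm, ss)
}

dcm_require <- function(value, name) {
  if (is.null(value) || !length(value)) {
    stop(name, " absent from DICOM series", call. = FALSE)
  }
  value
}

#' Read a PET (or CT) series and its SUV parameters
#'
#' Reads every file in a directory, checks they belong to one series,
#' sorts the slices along the slice normal regardless of on-disk order,
#' and assembles the stored-value volume plus the acquisition metadata
#' needed for SUV conversion. Weight is in kg and dose in Bq, as DICOM
#' stores them.
#'
#' @param path directory containing one single-frame-per-file series.
#' @param time_source `"series"` (default; the time the SUV formula
#'   names) or `"acquisition"`.
#' @return List with `volume` (a [scalar_volume()]) and `params` (an
#'   [suv_parameters()]; `NULL` for CT series without dose metadata).
#' @export
read_pet_series <- function(path, time_source = c("series", "acquisition")) {
  time_source <- match.arg(time_source)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in ", path, call. = FALSE)
  slices <- lapply(files, read_dicom_file)

  uids <- vapply(slices, function(s) s[["0020000E"]] %||% "", "")
  if (length(unique(uids)) != 1L) {
    stop("mixed series UIDs in ", path, call. = FALSE)
  }

  first <- slices[[1]]
  iop <- dcm_require(first[["00200037"]], "image_orientation")
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  pos <- vapply(slices, function(s) {
    sum(dcm_require(s[["00200032"]], "image_position") * normal)
  }, 0)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]

  rows <- first[["00280010"]]; cols <- first[["00280011"]]
  nz <- length(slices)
  vals <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    pix <- slices[[k]][["7FE00010"]]
    ints <- readBin(pix, "integer", n = length(pix) / 2, size = 2,
                    signed = FALSE, endian = "little")
    vals[, , k] <- array(ints, c(cols, rows))
  }

  ps <- dcm_require(first[["00280030"]], "pixel_spacing")
  dz <- if (nz > 1) mean(diff(pos)) else
    (first[["00180050"]] %||% 1)
  grid <- volume_grid(c(cols, rows, nz), c(ps[2], ps[1], dz),
                      origin = dcm_require(slices[[1]][["00200032"]],
                                           "image_position"),
                      orientation = cbind(rowdir, coldir, normal))

  modality <- first[["00080060"]] %||% "OT"
  volume <- scalar_volume(vals, grid, if (modality == "CT") "CT" else "PET")

  rph <- first[["00540016"]]
  rph <- if (is.null(rph)) list() else rph[[1]]
  params <- NULL
  if (modality != "CT") {
    weight <- dcm_require(first[["00101030"]], "patient_weight")
    dose <- dcm_require(rph[["00181074"]], "total_dose")
    start_raw <- dcm_require(rph[["00181072"]], "radiopharmaceutical_start_time")
    scan_raw <- if (time_source == "series") {
      dcm_require(first[["00080031"]], "series_time")
    } else {
      dcm_require(first[["00080032"]], "acquisition_time")
    }
    params <- suv_parameters(
      patient_weight = weight,
      total_dose = dose,
      radiopharmaceutical_start_time = parse_dicom_time(start_raw),
      series_time = parse_dicom_time(scan_raw),
      half_life = rph[["00181075"]] %||% fdg_half_life_s(),
      rescale_slope = first[["00281053"]] %||% 1,
      rescale_intercept = first[["00281052"]] %||% 0)
  }
  list(volume = volume, params = params)
}

#' Write a volume as a DICOM series
#'
#' One file per slice, explicit VR little endian, 16-bit unsigned stored
#' values. For PET volumes the SUV parameters are embedded (weight,
#' dose, times, half-life, rescale factors) so [read_pet_series()]
#' recovers them.
#'
#' @param volume a [scalar_volume()]; values must round into 0..65535.
#' @param dir output directory (created if needed).
#' @param params [suv_parameters()] for PET; ignored for CT.
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(volume, dir, params = NULL) {
  stopifnot(is_scalar_volume(volume))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- volume$grid
  series_uid <- dcm_uid(if (volume$modality == "CT") "11" else "12",
                        format(g$dims[3]))
  iop <- c(g$orientation[, 1], g$orientation[, 2])
  for (k in seq_len(g$dims[3])) {
    ipp <- as.numeric(voxel_to_patient(g, c(0, 0, k - 1)))
    meta <- list(
      modality = if (volume$modality == "CT") "CT" else "PT",
      rows = g$dims[2], cols = g$dims[1],
      pixel_spacing = c(g$spacing[2], g$spacing[1]),
      slice_thickness = g$spacing[3],
      image_position = ipp,
      image_orientation = iop,
      series_uid = series_uid,
      series_root = if (volume$modality == "CT") "11" else "12",
      instance = k)
    if (!is.null(params) && volume$modality != "CT") {
      meta$series_time <- seconds_to_dicom_time(params$series_time)
      meta$acquisition_time <- seconds_to_dicom_time(params$series_time)
      meta$start_time <-
        seconds_to_dicom_time(params$radiopharmaceutical_start_time)
      meta$patient_weight <- params$patient_weight
      meta$total_dose <- params$total_dose
      meta$half_life <- params$half_life
      meta$rescale_slope <- params$rescale_slope
      meta$rescale_intercept <- params$rescale_intercept
    }
    write_dicom_slice(file.path(dir, sprintf("slice_%04d.dcm", k)),
                      volume$values[, , k], meta)
  }
  invisible(dir)
}
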