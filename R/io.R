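# On-disk dialects
# - imaging: multi-page 32-bit-float TIFF, page order wavelength-major /
#   channel-minor (w1 green, w1 red, w2 green, ...), pixel values divided by
#   a power-of-two intensity_scale recorded in the JSON sidecar
#   {wavelengths_nm, channels, pixel_size_um, intensity_scale}; ground truth
#   as CSV. Pixel coordinates are 0-based, x right, y down.
# - LFP: <prefix>.csv single `value` column + <prefix>.json metadata
#   {sample_rate_hz, mode, annotations, ...}.
# - locomotion: CSV (time_s, displacement_cm) + JSON light schedule.

.INTENSITY_SCALE <- 2^16
.INTENSITY_OFFSET <- 2^14  # keeps noisy (negative) pixels inside [0, 1]

#' Write / read a multi-wavelength image stack
#'
#' `write_imaging_field()` stores a simulated (or assembled) field as a
#' multi-page float TIFF with a JSON metadata sidecar and a ground-truth CSV
#' (when present). `read_image_stack()` loads it back, validating the page
#' count against the sidecar.
#'
#' @param field A `clop_field` (or a list with `stack` and optionally
#'   `cells`).
#' @param prefix Path prefix; writes `<prefix>.tif`, `<prefix>.json` and
#'   `<prefix>_truth.csv`.
#' @return `write_imaging_field()`: the prefix, invisibly.
#'   `read_image_stack()`: a list with `stack` (the
#'   `[ny, nx, channel, wavelength]` array), `metadata`, and `cells` (truth
#'   tibble or `NULL`).
#' @export
write_imaging_field <- function(field, prefix) {
  arr <- field$stack
  wl <- dimnames(arr)[[4]]
  pages <- list()
  for (k in seq_along(wl)) for (ch in c("green", "red")) {
    pages[[length(pages) + 1]] <- (arr[, , ch, k] + .INTENSITY_OFFSET) / .INTENSITY_SCALE
  }
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(wavelengths_nm = as.numeric(wl), channels = c("green", "red"),
               pixel_size_um = field$pixel_size_um %||% NA,
               intensity_scale = .INTENSITY_SCALE,
               intensity_offset = .INTENSITY_OFFSET,
               page_order = "wavelength-major, channel-minor",
               coordinates = "0-based, x right, y down")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(field$cells)) {
    readr::write_csv(field$cells, paste0(prefix, "_truth.csv"))
  }
  invisible(prefix)
}

#' @param prefix Path prefix used at write time.
#' @rdname write_imaging_field
#' @export
read_image_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  wl <- meta$wavelengths_nm
  expected <- length(wl) * length(meta$channels)
  if (length(pages) != expected) {
    abort(sprintf("sidecar lists %d wavelengths x %d channels = %d pages but TIFF has %d",
                  length(wl), length(meta$channels), expected, length(pages)))
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], 2, length(wl)),
               dimnames = list(NULL, NULL, meta$channels, wl))
  p <- 1
  for (k in seq_along(wl)) for (ch in meta$channels) {
    arr[, , ch, k] <- pages[[p]] * meta$intensity_scale -
      (meta$intensity_offset %||% 0)
    p <- p + 1
  }
  truth_path <- paste0(prefix, "_truth.csv")
  cells <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  }
  list(stack = arr, metadata = meta, cells = cells)
}

#' Write / read an LFP session (CSV + JSON metadata dialect)
#'
#' The trace is stored as a single-column CSV; sample rate, mode and the
#' annotation table live in a JSON sidecar.
#'
#' @param lfp A `clop_lfp`.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `write_lfp()`: the prefix, invisibly. `read_lfp()`: a
#'   `clop_lfp`.
#' @export
write_lfp <- function(lfp, prefix) {
  readr::write_csv(tibble(value = lfp$trace), paste0(prefix, ".csv"))
  meta <- list(sample_rate_hz = lfp$fs, mode = lfp$mode,
               annotations = lfp$annotations)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (is.null(meta$sample_rate_hz)) abort("metadata missing sample_rate_hz")
  trace <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE)$value
  ann <- as_tibble(meta$annotations)
  if (nrow(ann) > 1 && is.unsorted(ann$onset_s)) {
    abort("annotations are not monotone in onset_s")
  }
  .new_lfp(trace, meta$sample_rate_hz, meta$mode %||% "unknown", ann,
           truth = NULL)
}

#' Write / read a locomotion trace (CSV + JSON schedule)
#'
#' @param trace A `clop_locomotion`.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `write_locomotion()`: the prefix, invisibly.
#'   `read_locomotion()`: a `clop_locomotion` tibble with schedule attrs.
#' @export
write_locomotion <- function(trace, prefix) {
  readr::write_csv(as_tibble(trace)[, c("time_s", "displacement_cm")],
                   paste0(prefix, ".csv"))
  sch <- attr(trace, "schedule")
  meta <- list(lights_on = sch$lights_on, lights_off = sch$lights_off,
               extend_dark_until_zt = sch$extend_dark_until_zt,
               frame_dt_s = attr(trace, "frame_dt_s"),
               days = attr(trace, "days"))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_locomotion
#' @export
read_locomotion <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tr <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE)
  sch <- light_schedule(meta$lights_on, meta$lights_off,
                        meta$extend_dark_until_zt)
  structure(tr, class = c("clop_locomotion", class(tr)),
            schedule = sch, frame_dt_s = meta$frame_dt_s, days = meta$days)
}
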