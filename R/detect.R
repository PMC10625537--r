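#' Detect cell somata on the red reference channel
#'
#' Runs difference-of-Gaussians band-pass filtering at the soma scale on the
#' wavelength-summed red channel (the red reference is chloride- and
#' pH-independent, so detection is not biased by quench-dependent green
#' intensity), finds local maxima above an adaptive threshold
#' (median + `threshold_k` * MAD of the DoG image), suppresses overlapping
#' detections by descending peak value, and refines centroids to sub-pixel
#' precision by parabolic interpolation. Ordering is deterministic:
#' peak value descending, then y, then x.
#'
#' @param stack A `clop_field` or a bare `[ny, nx, channel, wavelength]`
#'   array with a `"red"` channel.
#' @param soma_radius_px Expected soma radius (px); sets the DoG scales
#'   (sigma `r/2` and `r`), the assigned ROI radius and the default minimum
#'   separation.
#' @param threshold_k Adaptive-threshold multiplier on the MAD.
#' @param min_separation_px Minimum centre distance between kept ROIs;
#'   default `1.5 * soma_radius_px`.
#' @return A tibble of ROIs: `cell_id`, `x`, `y` (0-based px), `radius_px`,
#'   `peak` (quality score). Empty or constant images yield zero rows.
#' @export
detect_somata <- function(stack, soma_radius_px = 5.5, threshold_k = 8,
                          min_separation_px = NULL) {
  arr <- if (inherits(stack, "clop_field")) stack$stack else stack
  if (soma_radius_px <= 0) abort("soma_radius_px must be > 0")
  min_sep <- min_separation_px %||% (1.5 * soma_radius_px)
  red <- apply(arr[, , "red", , drop = FALSE], c(1, 2), sum)
  empty <- tibble(cell_id = integer(0), x = numeric(0), y = numeric(0),
                  radius_px = numeric(0), peak = numeric(0))
  if (max(red) - min(red) < 1e-12) return(empty)
  s1 <- soma_radius_px / 2
  if (min(dim(red)) < 8 * soma_radius_px + 1) return(empty)  # field smaller than filter
  dog <- EBImage::gblur(red, sigma = s1) - EBImage::gblur(red, sigma = 2 * s1)
  thr <- median(dog) + threshold_k * mad(dog)
  ny <- nrow(dog); nx <- ncol(dog)
  inner <- dog[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (inner >= dog[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  ri <- idx[, 1] + 1; ci <- idx[, 2] + 1
  pk <- dog[cbind(ri, ci)]
  # deterministic order: peak desc, then y, then x
  o <- order(-pk, ri, ci)
  ri <- ri[o]; ci <- ci[o]; pk <- pk[o]
  keep_r <- keep_c <- integer(0); keep_p <- numeric(0)
  for (i in seq_along(pk)) {
    if (length(keep_r) == 0 ||
        all((keep_r - ri[i])^2 + (keep_c - ci[i])^2 >= min_sep^2)) {
      keep_r <- c(keep_r, ri[i]); keep_c <- c(keep_c, ci[i])
      keep_p <- c(keep_p, pk[i])
    }
  }
  # sub-pixel refinement: 1-d parabola through the DoG along each axis
  refine <- function(v0, vm, vp) {
    den <- vm - 2 * v0 + vp
    if (abs(den) < 1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  dy <- dx <- numeric(length(keep_r))
  for (i in seq_along(keep_r)) {
    r <- keep_r[i]; c <- keep_c[i]
    if (r > 1 && r < ny) dy[i] <- refine(dog[r, c], dog[r - 1, c], dog[r + 1, c])
    if (c > 1 && c < nx) dx[i] <- refine(dog[r, c], dog[r, c - 1], dog[r, c + 1])
  }
  tibble(cell_id = seq_along(keep_r),
         x = keep_c - 1 + dx, y = keep_r - 1 + dy,
         radius_px = soma_radius_px, peak = keep_p)
}

#' Extract background-subtracted ROI intensities per wavelength
#'
#' For each ROI and each (wavelength, channel) page, averages the pixels
#' within a disk of the ROI radius after subtracting a per-page background
#' level estimated as a low percentile of the pixels outside all (dilated)
#' ROIs — robust to labelled-pixel contamination and invariant to uniform
#' additive offsets. Negative background-subtracted means are floored at 0
#' and flagged; ROIs touching the field edge average in-bounds pixels only
#' and are flagged `"edge"`; ROIs containing saturated pixels are flagged
#' `"saturated"`.
#'
#' @inheritParams detect_somata
#' @param rois ROI tibble (`cell_id`, `x`, `y`, `radius_px`), e.g. from
#'   [detect_somata()] or a ground-truth table.
#' @param background_percentile Percentile (0-1) of outside-ROI pixels used
#'   as the background level. Default 0.1.
#' @param saturation_level Intensity at or above which a pixel counts as
#'   saturated (`Inf` disables).
#' @return A tibble with one row per (cell, wavelength): `cell_id`,
#'   `wavelength_nm`, `green`, `red`, `flag`.
#' @export
extract_cell_ratios <- function(stack, rois, background_percentile = 0.1,
                                saturation_level = Inf) {
  arr <- if (inherits(stack, "clop_field")) stack$stack else stack
  ny <- dim(arr)[1]; nx <- dim(arr)[2]
  wl <- as.numeric(dimnames(arr)[[4]])
  if (nrow(rois) == 0) {
    return(tibble(cell_id = integer(0), wavelength_nm = numeric(0),
                  green = numeric(0), red = numeric(0), flag = character(0)))
  }
  if (any(rois$x < 0 | rois$x > nx - 1 | rois$y < 0 | rois$y > ny - 1)) {
    abort("ROI centroids must lie within image bounds")
  }
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  inside_any <- matrix(FALSE, ny, nx)
  masks <- vector("list", nrow(rois))
  edge_flag <- logical(nrow(rois))
  for (i in seq_len(nrow(rois))) {
    d2 <- (xg - rois$x[i])^2 + (yg - rois$y[i])^2
    masks[[i]] <- d2 <= rois$radius_px[i]^2
    inside_any <- inside_any | (d2 <= (rois$radius_px[i] + 2)^2)
    edge_flag[i] <- rois$x[i] < rois$radius_px[i] ||
      rois$y[i] < rois$radius_px[i] ||
      rois$x[i] > nx - 1 - rois$radius_px[i] ||
      rois$y[i] > ny - 1 - rois$radius_px[i]
  }
  outside <- !inside_any
  if (!any(outside)) abort("no background pixels outside ROIs")
  out <- vector("list", length(wl))
  # low-percentile background, corrected for the quantile's noise offset:
  # q_p sits qnorm(p)*sigma below the true level for symmetric noise, so add
  # back qnorm(1-p)*MAD. Robust to bright contamination (upper tail) yet
  # unbiased under noise; exact on noise-free images (MAD = 0).
  bg_level <- function(px) {
    quantile(px, background_percentile, names = FALSE) +
      stats::qnorm(1 - background_percentile) * mad(px)
  }
  for (k in seq_along(wl)) {
    g_pg <- arr[, , "green", k]; r_pg <- arr[, , "red", k]
    g_bg <- bg_level(g_pg[outside])
    r_bg <- bg_level(r_pg[outside])
    g <- r <- numeric(nrow(rois)); fl <- character(nrow(rois))
    for (i in seq_len(nrow(rois))) {
      m <- masks[[i]]
      gm <- mean(g_pg[m]) - g_bg
      rm <- mean(r_pg[m]) - r_bg
      flags <- character(0)
      if (edge_flag[i]) flags <- c(flags, "edge")
      if (is.finite(saturation_level) &&
          (any(g_pg[m] >= saturation_level) || any(r_pg[m] >= saturation_level))) {
        flags <- c(flags, "saturated")
      }
      if (gm < 0 || rm < 0) flags <- c(flags, "negative_after_background")
      g[i] <- max(gm, 0); r[i] <- max(rm, 0)
      fl[i] <- if (length(flags)) paste(flags, collapse = ",") else NA_character_
    }
    out[[k]] <- tibble(cell_id = rois$cell_id, wavelength_nm = wl[k],
                       green = g, red = r, flag = fl)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$cell_id, .data$wavelength_nm)
}

#' Quantify a field: per-cell pH and chloride from extracted ratios
#'
#' Applies [estimate_ph()] then [estimate_chloride()] to each cell's
#' wavelength-intensity table and assembles a cell-measurement table.
#' Extraction flags are propagated; cells whose pH ratio falls outside the
#' titration range are flagged rather than dropped silently. A warning is
#' emitted when no cell could be quantified.
#'
#' @param ratios Output of [extract_cell_ratios()].
#' @param calib A [sensor_calibration()].
#' @param rois Optional ROI tibble; adds `x`, `y` columns.
#' @param animal_id,field_id,condition Labels stamped onto every row.
#' @return A `CellMeasurementTable` tibble: `animal_id`, `field_id`,
#'   `condition`, `cell_id`, `x`, `y`, `ph`, `cl_mM`, `flag`.
#' @export
quantify_field <- function(ratios, calib = sensor_calibration(), rois = NULL,
                           animal_id = "animal", field_id = 1L,
                           condition = NA_character_) {
  cells <- split(ratios, ratios$cell_id)
  rows <- purrr::map_dfr(cells, function(w) {
    prior <- unique(w$flag[!is.na(w$flag)])
    ep <- estimate_ph(w, calib)
    ec <- estimate_chloride(w, ep$ph, calib)
    fl <- c(prior, ep$flag[!is.na(ep$flag)], ec$flag[!is.na(ec$flag)])
    tibble(cell_id = w$cell_id[1], ph = ep$ph, cl_mM = ec$cl_mM,
           flag = if (length(fl)) paste(unique(fl), collapse = ",") else NA_character_)
  })
  if (nrow(rows) > 0 && all(is.na(rows$cl_mM))) {
    warn("no cell could be quantified (all flagged)")
  }
  if (!is.null(rois)) {
    rows <- dplyr::left_join(rows, rois[, c("cell_id", "x", "y")], by = "cell_id")
  } else {
    rows$x <- NA_real_; rows$y <- NA_real_
  }
  dplyr::mutate(rows, animal_id = animal_id, field_id = field_id,
                condition = condition, .before = 1) |>
    dplyr::select("animal_id", "field_id", "condition", "cell_id",
                  "x", "y", "ph", "cl_mM", "flag")
}
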