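test_that("blank and constant fields yield no ROIs", {
  blank <- array(0, dim = c(128, 128, 2, 1),
                 dimnames = list(NULL, NULL, c("green", "red"), "860"))
  expect_equal(nrow(detect_somata(blank)), 0)
  blank[] <- 7
  expect_equal(nrow(detect_somata(blank)), 0)
})

test_that("well-separated somata are recovered with sub-pixel accuracy", {
  fld <- sim_imaging_field(n_cells = 50, field_size = c(320, 320), seed = 17)
  rois <- detect_somata(fld)
  m <- match_pre_post(fld$cells, rois, tolerance_px = 5.5)
  recall <- nrow(m$matched) / nrow(fld$cells)
  precision <- nrow(m$matched) / nrow(rois)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  expect_lte(max(m$matched$distance_px), 1.5)
})

test_that("non-overlap suppression keeps the stronger of two close peaks", {
  # construct a red image with two Gaussian blobs closer than min separation
  ny <- nx <- 96
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  blob <- function(x0, y0, amp) amp * exp(-((xg - x0)^2 + (yg - y0)^2) / (2 * 3^2))
  img <- blob(40, 48, 100) + blob(44, 48, 60) + blob(70, 20, 90)
  arr <- array(0, dim = c(ny, nx, 2, 1),
               dimnames = list(NULL, NULL, c("green", "red"), "860"))
  arr[, , "red", 1] <- img
  rois <- detect_somata(arr, soma_radius_px = 4, min_separation_px = 8)
  expect_equal(nrow(rois), 2)
  # the kept peak near (40,48) is the brighter one; ordering is peak-descending
  expect_lt(abs(rois$x[1] - 40), 2)
  expect_true(all(diff(rois$peak) <= 0))
})

test_that("detection is deterministic", {
  fld <- sim_imaging_field(n_cells = 25, field_size = c(256, 256), seed = 31)
  expect_identical(detect_somata(fld), detect_somata(fld))
})

test_that("extraction is invariant to uniform additive offsets", {
  fld <- sim_imaging_field(n_cells = 5, field_size = c(128, 128),
                           noise = list(gaussian_sd = 0, poisson_gain = 0),
                           seed = 3)
  rois <- fld$cells[, c("cell_id", "x", "y", "radius_px")]
  r1 <- extract_cell_ratios(fld, rois)
  fld$stack <- fld$stack + 55
  r2 <- extract_cell_ratios(fld, rois)
  expect_equal(r2$green, r1$green, tolerance = 1e-9)
  expect_equal(r2$red, r1$red, tolerance = 1e-9)
})

test_that("edge ROIs average in-bounds pixels and are flagged", {
  fld <- sim_imaging_field(n_cells = 3, field_size = c(128, 128), seed = 6)
  rois <- fld$cells[, c("cell_id", "x", "y", "radius_px")]
  rois$x[1] <- 1; rois$y[1] <- 1   # push one ROI onto the corner
  r <- extract_cell_ratios(fld, rois)
  expect_true(all(grepl("edge", r$flag[r$cell_id == 1])))
  expect_true(all(is.finite(r$green) & is.finite(r$red)))
})

test_that("quantification closes the loop on a noisy synthetic field", {
  res <- quantify_synthetic_field(n_cells = 80, field_size = c(448, 448),
                                  cl_median = 8.9, seed = 23)
  med_est <- median(res$cells$cl_mM[is.na(res$cells$flag)])
  med_true <- median(res$field$cells$cl_mM)
  expect_equal(med_est, med_true, tolerance = 0.10)
})

test_that("noise-free quantification is exact to numerical precision", {
  fld <- sim_imaging_field(n_cells = 10, field_size = c(256, 256),
                           background = 0,
                           noise = list(gaussian_sd = 0, poisson_gain = 0),
                           seed = 41)
  rois <- fld$cells[, c("cell_id", "x", "y", "radius_px")]
  cells <- quantify_field(extract_cell_ratios(fld, rois), fld$calib, rois)
  ord <- match(cells$cell_id, fld$cells$cell_id)
  expect_lt(max(abs(cells$cl_mM - fld$cells$cl_mM[ord])), 1e-6)
  expect_lt(max(abs(cells$ph - fld$cells$ph[ord])), 1e-9)
})

test_that("cells outside the titration range are flagged, not dropped silently", {
  calib <- sensor_calibration()
  w <- tibble::tibble(cell_id = 1,
                      wavelength_nm = calib$wavelengths_nm,
                      green = rep(1, 5), red = rep(1, 5),
                      flag = NA_character_)
  # make the pH ratio sit beyond the base asymptote
  w$green[w$wavelength_nm == calib$ph_pair[1]] <- 10
  expect_warning(cells <- quantify_field(w, calib), "quantified")
  expect_true(grepl("ph_out_of_range", cells$flag))
})

test_that("group summaries use the animal as the statistical unit", {
  cells <- tibble::tibble(
    animal_id = c("m1", "m1", "m1", "m2", "m2"),
    condition = "ZT5",
    cl_mM = c(5, 10, 15, 18, 18),
    flag = NA_character_)
  gs <- summarize_group(cells)
  expect_equal(gs$animals$median, c(10, 18))
  expect_equal(gs$groups$median_of_medians, 14)
  expect_equal(gs$groups$mean_of_medians, 14)
  # duplicating every cell within an animal changes nothing at group level
  gs_dup <- summarize_group(dplyr::bind_rows(cells, cells))
  expect_equal(gs_dup$groups, gs$groups)
  # cumulative distributions are monotone in [0, 1] and reach 1
  for (aid in unique(gs$ecdf$animal_id)) {
    Fv <- gs$ecdf$F[gs$ecdf$animal_id == aid]
    expect_true(all(diff(Fv) >= 0))
    expect_equal(max(Fv), 1)
    expect_gte(min(Fv), 0)
  }
})

test_that("day/night group contrast reaches significance at realistic group sizes", {
  # 9 ZT5-like vs 8 ZT17-like animals; animal medians are the test unit
  reps <- 40
  pvals <- vapply(seq_len(reps), function(r) {
    d5 <- sim_cell_table(9, cl_median = 8.9, condition = "ZT5",
                         seed = 5000 + r)
    d17 <- sim_cell_table(8, cl_median = 18.4, condition = "ZT17",
                          seed = 6000 + r)
    gs <- summarize_group(list(d5, d17))
    rank_tests(gs$animals$median[gs$animals$condition == "ZT5"],
               gs$animals$median[gs$animals$condition == "ZT17"])$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.01), 0.95)
})

test_that("pre/post matching pairs cells and differences chloride", {
  pre <- tibble::tibble(cell_id = 1:4, x = c(10, 30, 50, 70),
                        y = c(10, 30, 50, 70), cl_mM = c(20, 18, 16, 22))
  # identical sets match fully with zero delta
  self <- match_pre_post(pre, pre)
  expect_equal(nrow(self$matched), 4)
  expect_true(all(self$matched$delta_cl_mM == 0))
  # translation within tolerance preserves the matching
  post <- dplyr::mutate(pre, x = x + 2, cl_mM = cl_mM - 8.7)
  m <- match_pre_post(pre, post, tolerance_px = 3)
  expect_equal(nrow(m$matched), 4)
  expect_equal(m$matched$pre_id, m$matched$post_id)
  expect_equal(median(m$matched$delta_cl_mM), -8.7)
  # beyond tolerance nothing matches
  far <- dplyr::mutate(pre, x = x + 10)
  expect_equal(nrow(match_pre_post(pre, far, tolerance_px = 3)$matched), 0)
})

test_that("night-time bumetanide-like effect is recovered from paired fields", {
  # same cells, chloride drawn at the ZT17 median pre and reduced post
  set.seed(77)
  pre_fld <- sim_imaging_field(n_cells = 60, field_size = c(384, 384),
                               cl_median = 18.4, seed = 52)
  post_cells <- pre_fld$cells
  post_cells$cl_mM <- post_cells$cl_mM * (9.7 / 18.4)
  m <- match_pre_post(pre_fld$cells, post_cells, tolerance_px = 3)
  expect_equal(nrow(m$matched), 60)
  expect_equal(median(m$matched$delta_cl_mM), -8.7, tolerance = 0.15)
})
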