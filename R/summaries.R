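#' Group summaries with the animal as the statistical unit
#'
#' Flagged cells are excluded, animal-level medians and IQRs are computed
#' first, and group statistics are taken over animal medians — the animal,
#' not the cell, is the unit of analysis, so duplicating every cell within
#' an animal leaves the group summary unchanged. Per-animal empirical
#' cumulative distributions are evaluated on a common per-group grid
#' together with their group mean distribution.
#'
#' @param cells A cell-measurement table (rows `animal_id`, `condition`,
#'   `cl_mM`/`ph`, `flag`), or a list of such tables which are row-bound.
#' @param value Column to summarize (default `cl_mM`).
#' @param ecdf_points Number of grid points for the cumulative
#'   distributions.
#' @return A `clop_group_summary` list: `animals` (median, IQR, n_cells per
#'   animal), `groups` (median and mean of animal medians, n per group),
#'   `ecdf` (long tibble: condition, animal_id with `".group_mean"` for the
#'   mean curve, value grid, F).
#' @export
summarize_group <- function(cells, value = "cl_mM", ecdf_points = 200) {
  if (is.list(cells) && !is.data.frame(cells)) cells <- dplyr::bind_rows(cells)
  cells <- dplyr::filter(cells, is.na(.data$flag), !is.na(.data[[value]]))
  if (nrow(cells) == 0) abort("no unflagged cells to summarize")
  animals <- cells |>
    dplyr::group_by(.data$condition, .data$animal_id) |>
    dplyr::summarise(median = median(.data[[value]]),
                     q1 = quantile(.data[[value]], 0.25, names = FALSE),
                     q3 = quantile(.data[[value]], 0.75, names = FALSE),
                     n_cells = dplyr::n(), .groups = "drop")
  groups <- animals |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(median_of_medians = median(.data$median),
                     mean_of_medians = mean(.data$median),
                     n_animals = dplyr::n(), .groups = "drop")
  ecdf_tbl <- cells |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      grid <- seq(min(d[[value]]), max(d[[value]]), length.out = ecdf_points)
      per <- d |>
        dplyr::group_by(.data$animal_id) |>
        dplyr::group_modify(function(a, k2) {
          Fv <- stats::ecdf(a[[value]])(grid)
          tibble(value = grid, F = Fv)
        }) |>
        dplyr::ungroup()
      mean_curve <- per |>
        dplyr::group_by(.data$value) |>
        dplyr::summarise(F = mean(.data$F), .groups = "drop") |>
        dplyr::mutate(animal_id = ".group_mean")
      dplyr::bind_rows(per, mean_curve)
    }) |>
    dplyr::ungroup()
  structure(list(animals = animals, groups = groups, ecdf = ecdf_tbl,
                 value = value),
            class = "clop_group_summary")
}

#' @export
print.clop_group_summary <- function(x, ...) {
  cat("<clop_group_summary> of", x$value, "\n")
  print(x$groups)
  invisible(x)
}

#' Match cells across paired pre/post fields and compute per-cell deltas
#'
#' Greedy nearest-centroid matching under a distance tolerance: candidate
#' pairs are sorted by distance (ties broken by pre then post `cell_id`) and
#' assigned greedily, each cell used at most once. Both fields must share a
#' coordinate frame; small rigid shifts within the tolerance are matched
#' through. When both tables carry the value column, the per-cell change
#' `post - pre` is returned.
#'
#' @param pre,post Cell tables with `cell_id`, `x`, `y` and optionally the
#'   value column.
#' @param tolerance_px Maximum centre distance for a match (default 3 px).
#' @param value Column to difference (default `cl_mM`).
#' @return A list: `matched` (pre_id, post_id, distance_px, and
#'   `delta_<value>` when available), `unmatched_pre`, `unmatched_post`.
#' @export
match_pre_post <- function(pre, post, tolerance_px = 3, value = "cl_mM") {
  dx <- outer(pre$x, post$x, "-"); dy <- outer(pre$y, post$y, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= tolerance_px, arr.ind = TRUE)
  ord <- order(d[cand], pre$cell_id[cand[, 1]], post$cell_id[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  used_pre <- logical(nrow(pre)); used_post <- logical(nrow(post))
  ii <- jj <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_pre[i] && !used_post[j]) {
      used_pre[i] <- TRUE; used_post[j] <- TRUE
      ii <- c(ii, i); jj <- c(jj, j)
    }
  }
  matched <- tibble(pre_id = pre$cell_id[ii], post_id = post$cell_id[jj],
                    distance_px = d[cbind(ii, jj)])
  if (value %in% names(pre) && value %in% names(post)) {
    matched[[paste0("delta_", value)]] <- post[[value]][jj] - pre[[value]][ii]
  }
  list(matched = matched,
       unmatched_pre = pre[!used_pre, , drop = FALSE],
       unmatched_post = post[!used_post, , drop = FALSE])
}
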