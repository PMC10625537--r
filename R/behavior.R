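#' Bin a locomotion trace into an actogram
#'
#' Sums per-frame displacement into left-closed, right-open time bins
#' aligned to the trace start (for traces produced by [sim_locomotion()] the
#' start is ZT0, so bins are zeitgeber-aligned). A partial final bin is kept
#' and flagged.
#'
#' @param trace A tibble with `time_s` and `displacement_cm` columns (e.g.
#'   from [sim_locomotion()]).
#' @param bin_s Bin duration in seconds (default 600 = 10 min).
#' @return A `clop_actogram` tibble: `bin_start_s`, `zt_h`, `distance_cm`,
#'   `n_frames`, `partial`.
#' @export
bin_actogram <- function(trace, bin_s = 600) {
  if (bin_s <= 0) abort("bin_s must be > 0")
  if (nrow(trace) == 0) abort("empty trace")
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("timestamps must be strictly increasing")
  }
  dt <- if (nrow(trace) > 1) trace$time_s[2] - trace$time_s[1] else bin_s
  bin <- floor((trace$time_s - trace$time_s[1]) / bin_s)
  out <- trace |>
    as_tibble() |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(distance_cm = sum(.data$displacement_cm),
                     n_frames = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_start_s = trace$time_s[1] + .data$bin * bin_s,
                  zt_h = .data$bin_start_s / 3600,
                  partial = .data$n_frames < floor(bin_s / dt)) |>
    dplyr::select("bin_start_s", "zt_h", "distance_cm", "n_frames", "partial")
  structure(out, class = c("clop_actogram", class(out)),
            bin_s = bin_s, schedule = attr(trace, "schedule"))
}

#' Total time spent in complete immobility
#'
#' Frames whose speed (displacement / frame interval) is below
#' `speed_threshold` are grouped into runs; only runs lasting at least
#' `min_bout_s` count as immobility. Returns total immobile seconds.
#'
#' @inheritParams bin_actogram
#' @param speed_threshold Speed below which a frame is still (cm/s).
#' @param min_bout_s Minimum sustained stillness to count (s).
#' @return Immobile time in seconds (scalar).
#' @export
immobility_time <- function(trace, speed_threshold = 0.1, min_bout_s = 40) {
  if (speed_threshold <= 0 || min_bout_s <= 0) abort("thresholds must be > 0")
  n <- nrow(trace)
  if (n == 0) return(0)
  dt <- attr(trace, "frame_dt_s") %||%
    (if (n > 1) trace$time_s[2] - trace$time_s[1] else 1)
  still <- trace$displacement_cm / dt < speed_threshold
  r <- rle(still)
  sum(r$lengths[r$values & r$lengths * dt >= min_bout_s]) * dt
}

#' Cumulative distance travelled over an interval
#'
#' @inheritParams bin_actogram
#' @param interval `c(start_s, end_s)` (left-closed, right-open), or `NULL`
#'   for the whole trace.
#' @return Distance in cm (scalar).
#' @export
cumulative_distance <- function(trace, interval = NULL) {
  if (is.null(interval)) return(sum(trace$displacement_cm))
  sel <- trace$time_s >= interval[1] & trace$time_s < interval[2]
  sum(trace$displacement_cm[sel])
}

#' Nonparametric and paired group comparisons
#'
#' Thin reporting wrappers around the group statistics used throughout:
#' two-sided Mann-Whitney U for unpaired samples (exact enumeration when
#' `n1 + n2 <= 12` and there are no ties, tie-corrected normal approximation
#' otherwise), two-sided Wilcoxon signed-rank for paired samples (zero
#' differences dropped), and the paired t-test for behavioral contrasts.
#'
#' @param a,b Numeric samples; equal length when `paired = TRUE`.
#' @param paired Paired comparison?
#' @param type `"rank"` (Mann-Whitney / signed-rank) or `"t"` (paired t).
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `n1`, `n2`,
#'   `flag`. All-zero paired differences give `p_value = 1` with flag
#'   `"all_differences_zero"`.
#' @examples
#' rank_tests(c(1, 2, 3), c(4, 5, 6))
#' @export
rank_tests <- function(a, b, paired = FALSE, type = c("rank", "t")) {
  type <- match.arg(type)
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired && length(a) != length(b)) abort("paired samples must have equal length")
  if (length(a) == 0 || length(b) == 0) abort("samples must be non-empty")
  flag <- NA_character_
  if (type == "t") {
    ht <- t.test(a, b, paired = paired)
    return(tibble(method = if (paired) "paired t" else "t",
                  statistic = unname(ht$statistic), p_value = ht$p.value,
                  n1 = length(a), n2 = length(b), flag = flag))
  }
  if (paired) {
    d <- a - b
    if (all(d == 0)) {
      return(tibble(method = "wilcoxon signed-rank", statistic = NA_real_,
                    p_value = 1, n1 = length(a), n2 = length(b),
                    flag = "all_differences_zero"))
    }
    d <- d[d != 0]
    exact <- !any(duplicated(abs(d))) && length(d) <= 50
    ht <- suppressWarnings(
      wilcox.test(d, exact = exact, correct = TRUE))
    return(tibble(method = "wilcoxon signed-rank",
                  statistic = unname(ht$statistic), p_value = ht$p.value,
                  n1 = length(a), n2 = length(b), flag = flag))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble(method = if (exact) "mann-whitney (exact)" else "mann-whitney (normal approx.)",
         statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
         n1 = length(a), n2 = length(b), flag = flag)
}

#' Immunoblot densitometry ratio arithmetic
#'
#' Computes, per sample, the phospho/total cotransporter ratio
#' `(phospho_dimer + phospho_monomer) / (total_dimer + total_monomer)` and
#' the loading-normalized expression `(total_dimer + total_monomer)/tubulin`,
#' then group means with SEM and (for exactly two groups) the percent change
#' of the second group relative to the first.
#'
#' @param band_table Tibble with columns `sample_id`, `group`,
#'   `phospho_dimer`, `phospho_monomer`, `total_dimer`, `total_monomer`,
#'   `tubulin` (intensities, a.u.).
#' @return A list with `samples` (per-sample ratios, zero-denominator rows
#'   flagged), `groups` (mean, SEM, n per group) and `contrast` (percent
#'   change, two-group case only, else `NULL`).
#' @export
densitometry_ratios <- function(band_table) {
  needed <- c("sample_id", "group", "phospho_dimer", "phospho_monomer",
              "total_dimer", "total_monomer", "tubulin")
  if (!all(needed %in% names(band_table))) {
    abort(paste("band_table must have columns:", paste(needed, collapse = ", ")))
  }
  samples <- band_table |>
    as_tibble() |>
    dplyr::mutate(
      total = .data$total_dimer + .data$total_monomer,
      phospho_total = dplyr::if_else(.data$total > 0,
                                     (.data$phospho_dimer + .data$phospho_monomer) / .data$total,
                                     NA_real_),
      total_tubulin = dplyr::if_else(.data$tubulin > 0,
                                     .data$total / .data$tubulin, NA_real_),
      flag = dplyr::if_else(.data$total > 0 & .data$tubulin > 0,
                            NA_character_, "zero_denominator"))
  sem <- function(x) sd(x) / sqrt(length(x))
  groups <- samples |>
    dplyr::filter(is.na(.data$flag)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(c("phospho_total", "total_tubulin"),
                                   list(mean = mean, sem = sem)),
                     n = dplyr::n(), .groups = "drop")
  contrast <- NULL
  if (nrow(groups) == 2) {
    g <- groups[match(unique(band_table$group), groups$group), ]
    contrast <- tibble(
      reference = g$group[1], comparison = g$group[2],
      phospho_total_change_pct =
        100 * (g$phospho_total_mean[2] / g$phospho_total_mean[1] - 1),
      total_tubulin_change_pct =
        100 * (g$total_tubulin_mean[2] / g$total_tubulin_mean[1] - 1))
  }
  list(samples = samples, groups = groups, contrast = contrast)
}

#' Simulate an immunoblot band-intensity table
#'
#' Generates per-sample band intensities whose expected phospho/total and
#' total/tubulin ratios equal the configured group values, with log-normal
#' multiplicative measurement noise — a synthetic stand-in for densitometry
#' of Western blots.
#'
#' @param n_per_group Samples per group.
#' @param groups Group labels (order defines the contrast reference).
#' @param phospho_total Named expected phospho/total ratio per group.
#' @param total_tubulin Named expected total/tubulin ratio per group.
#' @param cv Multiplicative coefficient of variation of each band.
#' @param seed Integer seed (mandatory).
#' @return A band table suitable for [densitometry_ratios()].
#' @export
sim_band_table <- function(n_per_group = 4, groups = c("ZT5", "ZT17"),
                           phospho_total = c(ZT5 = 0.4, ZT17 = 0.6),
                           total_tubulin = c(ZT5 = 1.2, ZT17 = 1.2),
                           cv = 0.08, seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  sdl <- sqrt(log(1 + cv^2))
  noisy <- function(mu, n) rlnorm(n, log(mu) - sdl^2 / 2, sdl)
  purrr::map_dfr(groups, function(g) {
    n <- n_per_group
    tubulin <- noisy(1, n)
    total <- total_tubulin[[g]] * tubulin * noisy(1, n)
    dim_frac <- 0.6
    phospho <- phospho_total[[g]] * total * noisy(1, n)
    tibble(sample_id = sprintf("%s_s%02d", g, seq_len(n)), group = g,
           phospho_dimer = phospho * dim_frac,
           phospho_monomer = phospho * (1 - dim_frac),
           total_dimer = total * dim_frac,
           total_monomer = total * (1 - dim_frac),
           tubulin = tubulin)
  })
}
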