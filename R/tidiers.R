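# broom-style tidy()/glance() methods

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an aperiodic fit
#'
#' @param x A `clop_aperiodic_fit`.
#' @param ... Unused.
#' @return One row per model term (`offset_db`, `exponent_db_per_decade`).
#' @method tidy clop_aperiodic_fit
#' @export
tidy.clop_aperiodic_fit <- function(x, ...) {
  tibble(term = c("offset_db", "exponent_db_per_decade"),
         estimate = c(x$offset, x$exponent))
}

#' @rdname tidy.clop_aperiodic_fit
#' @return `glance()`: a one-row model summary.
#' @method glance clop_aperiodic_fit
#' @export
glance.clop_aperiodic_fit <- function(x, ...) {
  tibble(residual_rms_db = x$residual_rms, n_bins = x$n_bins,
         bands = paste(vapply(x$bands, function(b) paste(b, collapse = "-"),
                              character(1)), collapse = " & "))
}

#' Tidy a group summary into per-animal rows
#'
#' @param x A `clop_group_summary`.
#' @param ... Unused.
#' @return The per-animal median table.
#' @method tidy clop_group_summary
#' @export
tidy.clop_group_summary <- function(x, ...) x$animals

#' @rdname tidy.clop_group_summary
#' @return `glance()`: per-group medians of animal medians.
#' @method glance clop_group_summary
#' @export
glance.clop_group_summary <- function(x, ...) x$groups

#' Tidy a z-score map into long form
#'
#' @param x A `clop_zscore_map`.
#' @param ... Unused.
#' @return A long tibble (`time_s`, `frequency_hz`, `z`).
#' @method tidy clop_zscore_map
#' @export
tidy.clop_zscore_map <- function(x, ...) {
  tibble(time_s = rep(x$times, each = length(x$frequencies)),
         frequency_hz = rep(x$frequencies, length(x$times)),
         z = as.vector(x$z))
}

#' Tidy a seizure report
#'
#' @param x A `clop_seizure_report`.
#' @param ... Unused.
#' @return The event table with a `seizure` logical column.
#' @method tidy clop_seizure_report
#' @export
tidy.clop_seizure_report <- function(x, ...) {
  ev <- x$events
  ev$seizure <- ev$start_s %in% x$seizures$start_s
  ev
}

#' @rdname tidy.clop_seizure_report
#' @return `glance()`: one-row session summary (counts, latency, total
#'   cumulative activity).
#' @method glance clop_seizure_report
#' @export
glance.clop_seizure_report <- function(x, ...) {
  tibble(n_events = nrow(x$events), n_seizures = nrow(x$seizures),
         latency_min = x$latency$latency_min,
         latency_censored = x$latency$censored,
         cumulative_total = attr(x$cumulative, "total"))
}
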