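#' Light schedule descriptor
#'
#' Describes a 12:12 light/dark entrainment cycle by the clock times of
#' lights-on and lights-off, plus an optional extended-darkness override in
#' which the lights stay off past the scheduled ZT0 (zeitgeber time 0 =
#' lights-on) of the final simulated night, up to the given ZT hour.
#'
#' @param lights_on,lights_off Clock times, `"HH:MM"`. Defaults 7:00 / 19:00.
#' @param extend_dark_until_zt Optional ZT hour (> 24) until which the last
#'   dark period is prolonged (e.g. 29 keeps the lights off from ZT12 of the
#'   last day until ZT29, i.e. 5 h into the following day).
#' @return A `clop_light_schedule` list.
#' @export
light_schedule <- function(lights_on = "07:00", lights_off = "19:00",
                           extend_dark_until_zt = NULL) {
  parse_clock <- function(s) {
    p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(p) != 2 || anyNA(p) || p[1] < 0 || p[1] > 23 || p[2] < 0 || p[2] > 59) {
      abort(sprintf("invalid clock time '%s'", s))
    }
    p[1] + p[2] / 60
  }
  on_h <- parse_clock(lights_on); off_h <- parse_clock(lights_off)
  if (length(extend_dark_until_zt) == 0 || is.na(extend_dark_until_zt)) {
    extend_dark_until_zt <- NULL
  }
  if (!is.null(extend_dark_until_zt) && extend_dark_until_zt <= 24) {
    abort("extend_dark_until_zt must exceed 24 (ZT0 of the following day)")
  }
  structure(list(lights_on = lights_on, lights_off = lights_off,
                 on_h = on_h, off_h = off_h,
                 dark_zt = (off_h - on_h) %% 24,
                 extend_dark_until_zt = extend_dark_until_zt),
            class = "clop_light_schedule")
}

# TRUE where the animal is in darkness; zt_h = hours since first lights-on,
# n_days = number of simulated 24 h cycles (extension applies after the last)
.in_dark <- function(zt_h, schedule, n_days) {
  zt_mod <- zt_h %% 24
  dark <- zt_mod >= schedule$dark_zt
  ext <- schedule$extend_dark_until_zt
  if (!is.null(ext)) {
    t0 <- (n_days - 1) * 24 + schedule$dark_zt   # last scheduled dark onset
    dark <- dark | (zt_h >= t0 & zt_h < (n_days - 1) * 24 + ext)
  }
  dark
}

#' Simulate an entrained locomotion trace with known activity structure
#'
#' Produces a per-frame displacement trace over `days` light/dark cycles.
#' Each phase (light/dark) has a configured mean displacement rate; a
#' dark-onset surge multiplies the dark rate for the first `surge_min`
#' minutes after each lights-off (mice show a peak of activity in the hour
#' after the lights go out). Immobility bouts (complete stillness, as during
#' sleep) arrive as a Poisson process with exponential durations,
#' phase-specific; mobile-frame displacements are gamma-distributed and
#' rescaled so that the *realized* expected rate of each phase equals the
#' configured rate regardless of the immobility settings.
#'
#' @param days Number of 24 h cycles.
#' @param schedule A [light_schedule()].
#' @param light_rate,dark_rate Mean displacement rates (cm/min) in light and
#'   dark (>= 0).
#' @param surge_factor,surge_min Dark-onset surge multiplier and duration
#'   (minutes).
#' @param immobility Named list of `light`/`dark` elements, each
#'   `c(bouts_per_hour =, mean_s =)`.
#' @param frame_dt_s Frame interval (s).
#' @param seed Integer seed (mandatory).
#' @return A `clop_locomotion` tibble (`time_s`, `displacement_cm`) with the
#'   schedule, frame interval and per-frame truth (`dark`, `immobile`) stored
#'   as attributes. Time 0 is ZT0 (lights-on) of day 1.
#' @examples
#' tr <- sim_locomotion(days = 1, frame_dt_s = 5, seed = 1)
#' @export
sim_locomotion <- function(days = 3,
                           schedule = light_schedule(),
                           light_rate = 5, dark_rate = 25,
                           surge_factor = 2.5, surge_min = 60,
                           immobility = list(light = c(bouts_per_hour = 9, mean_s = 300),
                                             dark = c(bouts_per_hour = 12, mean_s = 60)),
                           frame_dt_s = 1,
                           seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (light_rate < 0 || dark_rate < 0) abort("rates must be >= 0")
  set.seed(seed)
  ext <- schedule$extend_dark_until_zt
  total_h <- days * 24 + if (!is.null(ext)) ext - 24 else 0
  n <- floor(total_h * 3600 / frame_dt_s)
  time_s <- (seq_len(n) - 1) * frame_dt_s
  zt_h <- time_s / 3600
  dark <- .in_dark(zt_h, schedule, days)

  # immobility gate, phase-specific Poisson bouts
  immobile <- rep(FALSE, n)
  frac <- c(light = 0, dark = 0)
  for (phase in c("light", "dark")) {
    pars <- immobility[[phase]]
    lambda <- pars[["bouts_per_hour"]] / 3600       # bouts per second
    # stationary covered fraction of an M/G/inf bout process (bouts overlap)
    frac[phase] <- min(0.95, 1 - exp(-lambda * pars[["mean_s"]]))
    sel <- if (phase == "dark") dark else !dark
    t_cur <- 0
    while (t_cur < total_h * 3600) {
      t_cur <- t_cur + rexp(1, lambda)
      dur <- rexp(1, 1 / pars[["mean_s"]])
      i0 <- floor(t_cur / frame_dt_s) + 1
      i1 <- min(n, floor((t_cur + dur) / frame_dt_s) + 1)
      if (i0 > n) break
      idx <- i0:i1
      immobile[idx] <- immobile[idx] | sel[idx]
    }
  }

  # expected rate compensation: mobile-frame rate = phase rate / P(mobile)
  rate_cm_min <- ifelse(dark, dark_rate, light_rate)
  # dark-onset surge after every lights-off (including the extension onset)
  dark_on <- which(dark & !c(FALSE, dark[-n]))
  for (i0 in dark_on) {
    idx <- i0:min(n, i0 + ceiling(surge_min * 60 / frame_dt_s) - 1)
    rate_cm_min[idx] <- rate_cm_min[idx] * surge_factor
  }
  p_mobile <- ifelse(dark, 1 - frac[["dark"]], 1 - frac[["light"]])
  mean_step <- rate_cm_min / 60 * frame_dt_s / p_mobile
  disp <- ifelse(immobile | mean_step == 0, 0,
                 rgamma(n, shape = 2, scale = mean_step / 2))
  out <- tibble(time_s = time_s, displacement_cm = disp)
  structure(out,
            class = c("clop_locomotion", class(out)),
            schedule = schedule, frame_dt_s = frame_dt_s, days = days,
            truth = list(dark = dark, immobile = immobile,
                         light_rate = light_rate, dark_rate = dark_rate,
                         surge_factor = surge_factor, surge_min = surge_min),
            seed = seed)
}
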