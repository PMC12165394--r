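tug_event_names <- c("stand_init", "stand_end", "gait_init_end", "turn_begin",
                     "turn_end", "walk2_end", "sit_begin", "sit_end")

tug_phase_names <- c("sit_to_stand", "gait_initiation", "walk1", "turn",
                     "walk2", "slow_down_turn", "sit_down")

# first time y crosses above (dir = 1) or below (dir = -1) `thr` strictly
# after time `after`, with linear sub-frame interpolation between the
# bracketing frames; the unrounded time is returned so chained searches are
# not derailed by frame rounding (reported times are rounded downstream)
first_crossing <- function(t, y, thr, after, dir = 1, rate_hz = 120) {
  ok <- which(t >= after)
  if (!length(ok)) return(NA_real_)
  yy <- dir * (y[ok] - thr)
  hit <- which(yy > 0)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1) {
    t[ok[1]]
  } else {
    j0 <- ok[i - 1]; j1 <- ok[i]
    f <- (0 - dir * (y[j0] - thr)) / (dir * (y[j1] - thr) - dir * (y[j0] - thr))
    t[j0] + f * (t[j1] - t[j0])
  }
}

# first local maximum with prominence >= prom at or after `after`
first_local_max <- function(t, y, after, prom, rate_hz = 120) {
  ok <- which(t >= after)
  if (length(ok) < 3) return(NA_real_)
  yy <- y[ok]
  for (i in 2:(length(yy) - 1)) {
    if (yy[i] >= yy[i - 1] && yy[i] > yy[i + 1]) {
      left_min <- min(yy[1:i])
      right <- yy[(i + 1):length(yy)]
      below <- which(right < yy[i] - prom)
      right_min <- if (length(below)) min(right[1:below[1]]) else min(right)
      if (yy[i] - max(left_min, right_min) >= prom) {
        return(t[ok[i]])
      }
    }
  }
  NA_real_
}

#' Detect the eight TUG event markers from COM coordinates
#'
#' Applies the coordinate rules for the Timed Up and Go test to the filtered
#' center-of-mass trajectory: stand initiation when COM height first exceeds
#' its seated baseline (plus a noise tolerance), stand end at the first
#' prominent height peak, gait-initiation end and turn begin/end at the 1 m
#' and 3 m forward-excursion crossings, walk-2 end back through 1 m, sit
#' begin when COM height drops below 95% of standing height, and sit end
#' when the forward excursion returns to the start.
#'
#' @param trial A [trial_recording()] with `condition == "TUG"`.
#' @param config An [analysis_config()].
#'
#' @return A `tug_events` object: a list with a `times` tibble
#'   (`event`, `time`), the reference scalars `start_x`, `start_z`,
#'   `standing_z`, and a `fallback` flag for the sit-end rule.
#' @export
detect_tug_events <- function(trial, config = analysis_config()) {
  if (trial$condition != "TUG") {
    abort("`detect_tug_events()` requires a TUG trial.",
          class = "pdgait_precondition_error")
  }
  rate <- trial$rate_hz
  dat <- filter_trial_positions(trial, config)
  t <- dat$t
  x <- dat$com_x
  z <- dat$com_z

  start_x <- baseline_stat(x, config$baseline_window_s, rate)
  start_z <- baseline_stat(z, config$baseline_window_s, rate)
  tol <- config$z_noise_tolerance_m

  # seated precondition: a sustained excursion (>= 50 ms) above the baseline
  # inside the opening window means the rise already started; isolated noisy
  # samples are tolerated
  n0 <- round(config$baseline_window_s * rate)
  above <- rle(z[seq_len(n0)] > start_z + tol)
  if (any(above$values & above$lengths >= max(2L, round(0.05 * rate)))) {
    abort(paste0("Trial does not begin seated: COM height exceeds its ",
                 "baseline within the opening window."),
          class = "pdgait_precondition_error")
  }

  miss <- function(event, detail) {
    abort(sprintf("%s not reached: %s", event, detail),
          class = "pdgait_detection_error")
  }

  # the rise cannot legitimately start inside the seated baseline window, so
  # the search starts at its end (also clear of filter edge transients)
  e <- c(stand_init = NA_real_)
  e["stand_init"] <- first_crossing(t, z, start_z + tol,
                                    t[1] + config$baseline_window_s, 1, rate)
  if (is.na(e["stand_init"]))
    miss("stand_init", sprintf("COM z never exceeds baseline %.3f m + %.0f mm",
                               start_z, tol * 1000))
  e["stand_end"] <- first_local_max(t, z, e["stand_init"], tol, rate)
  if (is.na(e["stand_end"]))
    miss("stand_end", "no prominent COM z peak after stand initiation")
  standing_z <- z[which.min(abs(t - e["stand_end"]))]

  xr <- x - start_x
  e["gait_init_end"] <- first_crossing(t, xr, config$gait_init_distance_m,
                                       e["stand_end"], 1, rate)
  if (is.na(e["gait_init_end"]))
    miss("gait_init_end", sprintf("max excursion %.1f m", max(xr)))
  e["turn_begin"] <- first_crossing(t, xr, config$turn_distance_m,
                                    e["gait_init_end"], 1, rate)
  if (is.na(e["turn_begin"]))
    miss("turn_begin", sprintf("max excursion %.1f m", max(xr)))
  e["turn_end"] <- first_crossing(t, xr, config$turn_distance_m,
                                  e["turn_begin"], -1, rate)
  if (is.na(e["turn_end"]))
    miss("turn_end", "COM x never returns below the turn distance")
  e["walk2_end"] <- first_crossing(t, xr, config$gait_init_distance_m,
                                   e["turn_end"], -1, rate)
  if (is.na(e["walk2_end"]))
    miss("walk2_end", "COM x never returns below the gait-initiation distance")
  e["sit_begin"] <- first_crossing(t, z, config$sit_z_fraction * standing_z,
                                   e["walk2_end"], -1, rate)
  if (is.na(e["sit_begin"]))
    miss("sit_begin", sprintf("COM z never drops below %.0f%% of standing height",
                              100 * config$sit_z_fraction))
  fallback <- FALSE
  e["sit_end"] <- first_crossing(t, xr, 0, e["sit_begin"], -1, rate)
  if (is.na(e["sit_end"])) {
    # real sitting placement can end slightly forward of the start; fall back
    # to the time of minimum forward excursion after sit begin
    idx <- which(t > e["sit_begin"])
    e["sit_end"] <- round(t[idx[which.min(xr[idx])]] * rate) / rate
    fallback <- TRUE
    inform("sit_end rule never fired; using minimum COM x after sit begin.",
           class = "pdgait_log")
  }

  if (any(diff(e[tug_event_names]) <= 0)) {
    abort("Detected TUG events are not strictly increasing.",
          class = "pdgait_detection_error")
  }
  # times keep sub-frame interpolation precision; `frame` gives the nearest
  # capture frame for 120 Hz reporting
  structure(
    list(
      times = tibble::tibble(event = tug_event_names,
                             time = unname(e[tug_event_names]),
                             frame = as.integer(round(unname(e[tug_event_names]) * rate))),
      start_x = start_x, start_z = start_z, standing_z = standing_z,
      fallback_sit_end = fallback
    ),
    class = "tug_events"
  )
}

#' @export
#' @method print tug_events
print.tug_events <- function(x, ...) {
  cat("<tug_events>\n")
  print(x$times, n = Inf)
  invisible(x)
}

#' Derive the seven TUG phase durations from detected events
#'
#' The eight event markers partition the trial into seven phases:
#' sit-to-stand, gait initiation, walk 1, turn, walk 2, slow down & turn,
#' and sit down. Durations telescope, so they sum to the total time between
#' stand initiation and sit end.
#'
#' @param events A `tug_events` object from [detect_tug_events()], or a
#'   numeric vector of the eight event times in order.
#'
#' @return A `tug_phases` tibble with columns `phase` and `duration` (s).
#' @export
#' @examples
#' compute_phase_times(c(0.5, 1.63, 2.22, 3.95, 6.93, 8.82, 10.14, 11.47))
compute_phase_times <- function(events) {
  times <- if (inherits(events, "tug_events")) events$times$time else as.numeric(events)
  if (length(times) != 8) {
    abort("Expected eight event times.", class = "pdgait_format_error")
  }
  if (any(diff(times) <= 0)) {
    abort("Event times must be strictly increasing (no zero-length phase).",
          class = "pdgait_detection_error")
  }
  out <- tibble::tibble(
    phase = factor(tug_phase_names, levels = tug_phase_names),
    duration = diff(times)
  )
  class(out) <- c("tug_phases", class(out))
  out
}

#' Average phase durations across repeated TUG trials
#'
#' @param results A list of `tug_phases` tibbles (one per trial).
#'
#' @return A single `tug_phases` tibble of element-wise mean durations.
#' @export
average_tug_trials <- function(results) {
  if (inherits(results, "tug_phases")) results <- list(results)
  if (!length(results)) {
    abort("Need at least one phase result to average.",
          class = "pdgait_precondition_error")
  }
  durs <- vapply(results, function(r) r$duration, numeric(7))
  out <- tibble::tibble(
    phase = factor(tug_phase_names, levels = tug_phase_names),
    duration = rowMeans(matrix(durs, nrow = 7))
  )
  class(out) <- c("tug_phases", class(out))
  out
}
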