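# local extrema of y with minimum prominence and minimum time separation;
# returns times at frame resolution
find_extrema <- function(t, y, min_sep_s, prominence, maxima = TRUE) {
  if (!maxima) y <- -y
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    left <- y[1:i]
    higher_l <- which(left > y[i])
    lmin <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > y[i])
    rmin <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (!length(keep)) return(numeric(0))
  # greedy separation enforcement, highest peak first
  ord <- keep[order(y[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(t[i] - t[sel]) >= min_sep_s)) sel <- c(sel, i)
  }
  sort(t[sel])
}

#' Detect foot-strike and foot-off events from heel/toe position relative to
#' the COM
#'
#' The coordinate-based rule: foot strikes occur at local maxima of
#' `heel_x - com_x` (foot maximally ahead of the body) and foot offs at local
#' minima of `toe_x - com_x` (foot maximally behind), per side, on the
#' filtered series. Extrema must be separated by at least the configured
#' minimum (default 0.6 s) and exceed a 1 cm prominence guard.
#'
#' @param trial A walking [trial_recording()] with heel, toe and COM series.
#' @param config An [analysis_config()].
#'
#' @return A `gait_events` object: a tibble with columns `side` ("L"/"R"),
#'   `event` ("strike"/"off") and `time` (s), trimmed per side to the span
#'   between the first and last strike.
#' @export
detect_gait_events <- function(trial, config = analysis_config()) {
  for (s in c("heel_L", "heel_R", "toe_L", "toe_R")) {
    if (!has_series(trial, s)) {
      abort(sprintf("Gait event detection requires marker series '%s'.", s),
            class = "pdgait_precondition_error")
    }
  }
  dat <- filter_trial_positions(trial, config)
  t <- dat$t
  rows <- list()
  for (side in c("L", "R")) {
    rel_heel <- dat[[paste0("heel_", side, "_x")]] - dat$com_x
    rel_toe <- dat[[paste0("toe_", side, "_x")]] - dat$com_x
    strikes <- find_extrema(t, rel_heel, config$min_peak_separation_s,
                            config$peak_prominence_m, maxima = TRUE)
    offs <- find_extrema(t, rel_toe, config$min_peak_separation_s,
                         config$peak_prominence_m, maxima = FALSE)
    if (length(strikes) < 2) {
      abort(sprintf("insufficient strides: %d strike(s) detected on side %s",
                    length(strikes), side),
            class = "pdgait_detection_error")
    }
    offs <- offs[offs > min(strikes) & offs < max(strikes)]
    # alternation: exactly one off inside each strike-to-strike stride
    counts <- vapply(seq_len(length(strikes) - 1), function(i) {
      sum(offs > strikes[i] & offs < strikes[i + 1])
    }, integer(1))
    if (any(counts != 1L)) {
      abort(sprintf("foot-strike/foot-off alternation violated on side %s", side),
            class = "pdgait_detection_error")
    }
    rows[[side]] <- dplyr::bind_rows(
      tibble::tibble(side = side, event = "strike", time = strikes),
      tibble::tibble(side = side, event = "off", time = offs)
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$time)
  class(out) <- c("gait_events", class(out))
  out
}

events_of <- function(events, side_, event_) {
  sort(events$time[events$side == side_ & events$event == event_])
}

#' Walking velocity across the central capture zone
#'
#' Velocity is the capture-zone length divided by the time the COM takes to
#' traverse it, with sub-frame interpolated crossing times. The zone is
#' centered on the midpoint of the COM excursion (a proxy for the calibrated
#' volume midpoint) unless `zone_center` is given.
#'
#' @param trial A walking [trial_recording()].
#' @param config An [analysis_config()].
#' @param zone_center Optional zone center (m, lab x).
#'
#' @return Velocity in m/s.
#' @export
capture_zone_velocity <- function(trial, config = analysis_config(),
                                  zone_center = NULL) {
  dat <- filter_trial_positions(trial, config)
  t <- dat$t
  x <- dat$com_x
  center <- zone_center %||% ((min(x) + max(x)) / 2)
  lo <- center - config$capture_zone_m / 2
  hi <- center + config$capture_zone_m / 2
  if (max(x) < hi || min(x) > lo) {
    abort(sprintf("capture zone not fully traversed: COM spans [%.2f, %.2f] m, zone [%.2f, %.2f] m",
                  min(x), max(x), lo, hi),
          class = "pdgait_detection_error")
  }
  t_enter <- interp_crossing(t, x, lo)
  t_exit <- interp_crossing(t, x, hi)
  inside <- t >= t_enter & t <= t_exit
  if (any(diff(x[inside]) < 0)) {
    abort("COM reverses direction inside the capture zone.",
          class = "pdgait_detection_error")
  }
  if (config$velocity_mode == "zone") {
    config$capture_zone_m / (t_exit - t_enter)
  } else {
    (approx(t, x, t_exit)$y - approx(t, x, t_enter)$y) / (t_exit - t_enter)
  }
}

interp_crossing <- function(t, y, thr) {
  above <- which(y > thr)
  if (!length(above) || above[1] == 1) {
    abort("Series starts beyond the crossing threshold.",
          class = "pdgait_detection_error")
  }
  i <- above[1]
  t[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Mean stride length
#'
#' Anterior heel displacement between consecutive same-side foot strikes,
#' averaged over all strides of both sides.
#'
#' @param events A `gait_events` object.
#' @param trial The matching [trial_recording()].
#' @param config An [analysis_config()].
#'
#' @return Mean stride length (m).
#' @export
stride_length <- function(events, trial, config = analysis_config()) {
  dat <- filter_trial_positions(trial, config)
  strides <- unlist(lapply(c("L", "R"), function(side) {
    st <- events_of(events, side, "strike")
    if (length(st) < 2) return(numeric(0))
    hx <- approx(dat$t, dat[[paste0("heel_", side, "_x")]], st)$y
    abs(diff(hx))
  }))
  if (!length(strides)) {
    abort("insufficient strides: need two same-side strikes.",
          class = "pdgait_precondition_error")
  }
  mean(strides)
}

#' Mean double-support time
#'
#' For each stride (ipsilateral strike to the next ipsilateral strike) the
#' double-support time is the sum of the two double-limb intervals: the lag
#' from each foot strike in the stride to the opposite foot's off. Averaged
#' across strides of both sides.
#'
#' @param events A `gait_events` object.
#' @param per_interval Return the individual double-limb intervals instead of
#'   the per-stride mean sum.
#'
#' @return Mean double-support time (s), or a tibble of intervals.
#' @export
double_support_time <- function(events, per_interval = FALSE) {
  # lag from a foot strike to the opposite foot's off, which must occur
  # before the opposite foot's own next strike (i.e., within this double-
  # support episode)
  ds_interval <- function(strike_time, contra_offs, before) {
    nxt <- contra_offs[contra_offs >= strike_time & contra_offs < before]
    if (!length(nxt)) NA_real_ else nxt[1] - strike_time
  }
  intervals <- list()
  ds_per_stride <- numeric(0)
  n_strides <- 0L
  for (side in c("L", "R")) {
    contra <- if (side == "L") "R" else "L"
    st <- events_of(events, side, "strike")
    contra_st <- events_of(events, contra, "strike")
    contra_off <- events_of(events, contra, "off")
    own_off <- events_of(events, side, "off")
    for (i in seq_len(max(0, length(st) - 1))) {
      n_strides <- n_strides + 1L
      mid <- contra_st[contra_st > st[i] & contra_st < st[i + 1]]
      if (length(mid) != 1) next
      d1 <- ds_interval(st[i], contra_off, before = mid[1])
      d2 <- ds_interval(mid[1], own_off, before = st[i + 1])
      # strides truncated at the trial boundary lack one episode; skip them
      if (is.na(d1) || is.na(d2)) next
      ds_per_stride <- c(ds_per_stride, d1 + d2)
      intervals[[length(intervals) + 1]] <-
        tibble::tibble(side = side, stride = i, initial = d1, terminal = d2)
    }
  }
  if (!length(ds_per_stride)) {
    abort("unmatched contralateral events: no stride yields a double-support estimate.",
          class = "pdgait_detection_error")
  }
  if (per_interval) return(dplyr::bind_rows(intervals))
  mean(ds_per_stride)
}

#' Minimum toe clearance during swing
#'
#' Per swing (foot off to the next same-side foot strike), the minimum of the
#' toe height above the floor reference within the middle 80% of the swing
#' (trim fraction configurable); averaged across swings per side. The default
#' floor reference is the per-side median stance-phase toe height, which is
#' unbiased under measurement noise; per-side trial minimum or a fixed
#' constant are selectable.
#'
#' @param trial A walking [trial_recording()].
#' @param events A `gait_events` object.
#' @param config An [analysis_config()].
#'
#' @return Named numeric `c(L = , R = )` of mean minimum toe clearance (m),
#'   with per-swing detail in attribute `"swings"`.
#' @export
min_toe_clearance <- function(trial, events, config = analysis_config()) {
  dat <- filter_trial_positions(trial, config)
  t <- dat$t
  out <- c(L = NA_real_, R = NA_real_)
  detail <- list()
  for (side in c("L", "R")) {
    tz <- dat[[paste0("toe_", side, "_z")]]
    st <- events_of(events, side, "strike")
    off <- events_of(events, side, "off")
    floor_ref <- toe_floor_reference(t, tz, st, off, config)
    mins <- numeric(0)
    for (o in off) {
      nxt <- st[st > o]
      if (!length(nxt)) next
      sw <- nxt[1] - o
      w0 <- o + config$swing_trim_fraction * sw
      w1 <- nxt[1] - config$swing_trim_fraction * sw
      idx <- which(t >= w0 & t <= w1)
      if (length(idx) < 3) next
      imin <- idx[which.min(tz[idx])]
      if (imin == idx[1] || imin == idx[length(idx)]) {
        inform(sprintf("toe clearance minimum at swing-window edge (side %s).",
                       side),
               class = "pdgait_log")
      }
      mins <- c(mins, tz[imin] - floor_ref)
      detail[[length(detail) + 1]] <-
        tibble::tibble(side = side, off = o, strike = nxt[1],
                       clearance = tz[imin] - floor_ref)
    }
    if (!length(mins)) {
      abort(sprintf("no complete swing on side %s.", side),
            class = "pdgait_detection_error")
    }
    out[side] <- mean(mins)
  }
  attr(out, "swings") <- dplyr::bind_rows(detail)
  out
}

toe_floor_reference <- function(t, tz, strikes, offs, config) {
  ref <- config$toe_floor_reference
  if (is.numeric(ref)) return(ref)
  if (ref == "trial_min") return(min(tz))
  # stance frames: strike to the next same-side off
  stance <- rep(FALSE, length(t))
  for (s in strikes) {
    nxt <- offs[offs > s]
    if (length(nxt)) stance[t >= s & t <= nxt[1]] <- TRUE
  }
  if (!any(stance)) return(min(tz))
  median(tz[stance])
}

#' Joint range of motion over gait cycles
#'
#' Max minus min of the flexion-extension angle within each same-side gait
#' cycle (strike to next strike), averaged across cycles.
#'
#' @param angle Flexion-extension angle series (degrees), aligned with `t`.
#' @param t Time vector of the series (s).
#' @param events A `gait_events` object.
#' @param side `"L"` or `"R"`.
#'
#' @return Mean ROM (degrees).
#' @export
joint_rom <- function(angle, t, events, side) {
  st <- events_of(events, side, "strike")
  if (length(st) < 2) {
    abort("no complete gait cycle for ROM.", class = "pdgait_precondition_error")
  }
  roms <- vapply(seq_len(length(st) - 1), function(i) {
    idx <- which(t >= st[i] & t < st[i + 1])
    diff(range(angle[idx]))
  }, numeric(1))
  if (all(roms < 1e-9)) {
    warn("degenerate ROM: angle is constant over all cycles.",
         class = "pdgait_degenerate_warning")
  }
  mean(roms)
}

#' Full walking metric panel for one trial
#'
#' Composes event detection, capture-zone velocity, stride length, double
#' support, minimum toe clearance, hip and shoulder flexion-extension ROM and
#' the shoulder symmetry angle into a one-row metric panel. Side-specific
#' metrics are resolved with the impaired-side rule. Trials missing rotation
#' series yield NA for the affected joint metrics; failures in required
#' marker-based metrics are errors annotated with the metric name.
#'
#' @param trial A walking [trial_recording()].
#' @param config An [analysis_config()].
#'
#' @return A one-row `gait_metrics` tibble.
#' @export
summarize_walking_trial <- function(trial, config = analysis_config()) {
  trial <- prefilter_trial(trial, config)
  events <- detect_gait_events(trial, config)
  with_metric <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("metric '%s': %s", name, conditionMessage(e)),
            class = "pdgait_metric_error", parent = e)
    })
  }
  velocity <- with_metric("velocity", capture_zone_velocity(trial, config))
  sl <- with_metric("stride_length", stride_length(events, trial, config))
  ds <- with_metric("double_support", double_support_time(events))
  tc <- with_metric("toe_clearance", min_toe_clearance(trial, events, config))

  rom_of <- function(series, side) {
    if (!has_series(trial, series)) return(NA_real_)
    ang <- cardan_xyz_angles(series_matrix(trial, series))
    joint_rom(ang$alpha, trial$data$t, events, side)
  }
  hip_L <- rom_of("hip_rot_L", "L"); hip_R <- rom_of("hip_rot_R", "R")
  sh_L <- rom_of("shoulder_rot_L", "L"); sh_R <- rom_of("shoulder_rot_R", "R")
  if (any(is.na(c(hip_L, hip_R)))) {
    inform("hip rotation series missing: hip ROM flagged NA.",
           class = "pdgait_log")
  }
  if (any(is.na(c(sh_L, sh_R)))) {
    inform("shoulder rotation series missing: shoulder metrics flagged NA.",
           class = "pdgait_log")
  }
  sa_signed <- if (any(is.na(c(sh_L, sh_R)))) NA_real_ else
    symmetry_angle(sh_L, sh_R, signed = TRUE)

  out <- tibble::tibble(
    trial_id = trial$trial_id,
    condition = trial$condition,
    velocity = velocity,
    stride_length = sl,
    double_support = ds,
    toe_clearance_L = unname(tc["L"]),
    toe_clearance_R = unname(tc["R"]),
    toe_clearance = unname(impaired_side_value(tc["L"], tc["R"],
                                               trial$impaired_side)),
    hip_rom_L = hip_L,
    hip_rom_R = hip_R,
    hip_rom = if (any(is.na(c(hip_L, hip_R)))) NA_real_ else
      impaired_side_value(hip_L, hip_R, trial$impaired_side),
    shoulder_rom_L = sh_L,
    shoulder_rom_R = sh_R,
    shoulder_symmetry_signed = sa_signed,
    shoulder_symmetry = abs(sa_signed)
  )
  class(out) <- c("gait_metrics", class(out))
  out
}

#' Average metric panels across repeated trials
#'
#' Element-wise mean across trials of one condition; a metric missing in one
#' trial falls back to the other trials' values, with a log message.
#'
#' @param panels A list of `gait_metrics` tibbles.
#' @return A one-row `gait_metrics` tibble.
#' @export
average_walking_trials <- function(panels) {
  if (inherits(panels, "gait_metrics")) panels <- list(panels)
  if (!length(panels)) {
    abort("Need at least one panel to average.",
          class = "pdgait_precondition_error")
  }
  all <- dplyr::bind_rows(panels)
  num <- dplyr::select(all, dplyr::where(is.numeric))
  if (anyNA(num)) {
    inform("some metrics missing in one or more trials; averaging available values.",
           class = "pdgait_log")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(trial_id = paste(all$trial_id, collapse = "+"),
                   condition = all$condition[1]),
    dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                        ~ mean(.x, na.rm = TRUE)))
  )
  out[sapply(out, is.nan)] <- NA_real_
  class(out) <- c("gait_metrics", class(out))
  out
}
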