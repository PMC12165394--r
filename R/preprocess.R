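#' Low-pass filter specification
#'
#' @param cutoff_hz Cutoff frequency (Hz); must satisfy
#'   `0 < cutoff_hz < rate_hz / 2`.
#' @param rate_hz Sampling rate (Hz).
#' @param method `"butterworth"` for a zero-phase 4th-order Butterworth
#'   applied forward-backward (the reproducible standard in gait analysis
#'   once a fixed cutoff is pinned), or `"spline"` for a generalized
#'   cross-validated smoothing spline.
#'
#' @return A list with class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 12, rate_hz = 120,
                        method = c("butterworth", "spline")) {
  method <- match.arg(method)
  if (!(cutoff_hz > 0 && cutoff_hz < rate_hz / 2)) {
    abort("`cutoff_hz` must lie in (0, rate_hz / 2).",
          class = "pdgait_config_error")
  }
  structure(list(cutoff_hz = cutoff_hz, rate_hz = rate_hz, method = method),
            class = "filter_spec")
}

#' Zero-phase low-pass smoothing of a kinematic series
#'
#' Applies the configured smoother with reflective padding of one cutoff
#' period at each end to suppress endpoint transients. The forward-backward
#' Butterworth application makes the filter zero-phase: event times computed
#' on the smoothed series are not lagged. Short interior NaN runs (up to
#' `max_nan_gap_s`) are linearly interpolated before filtering.
#'
#' @param x Numeric series (length >= 10).
#' @param spec A [filter_spec()].
#' @param max_nan_gap_s Longest NaN run bridged by interpolation (s).
#'
#' @return Smoothed series of the same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 120)
#' x <- sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 50 * t)
#' y <- lowpass_series(x, filter_spec(12, 120))
lowpass_series <- function(x, spec = filter_spec(), max_nan_gap_s = 0.1) {
  if (length(x) < 10) {
    abort("Series must have at least 10 samples.", class = "pdgait_format_error")
  }
  x <- bridge_nan(x, max_gap = max(1L, round(max_nan_gap_s * spec$rate_hz)))
  # the forward-backward IIR starts from zero state, so pad long enough for
  # the start-up transient to decay below numerical noise before the data
  pad <- max(24L, ceiling(12 * spec$rate_hz / spec$cutoff_hz))
  pad <- min(pad, length(x) - 1L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),
          x,
          2 * x[length(x)] - rev(x[(length(x) - pad):(length(x) - 1)]))
  if (spec$method == "butterworth") {
    bf <- signal::butter(4, spec$cutoff_hz / (spec$rate_hz / 2), type = "low")
    yp <- signal::filtfilt(bf, xp)
  } else {
    tt <- seq_along(xp)
    yp <- smooth.spline(tt, xp, cv = FALSE)$y
  }
  yp[(pad + 1):(pad + length(x))]
}

bridge_nan <- function(x, max_gap) {
  if (!anyNA(x)) return(x)
  runs <- rle(is.na(x))
  if (any(runs$values & runs$lengths > max_gap)) {
    abort(sprintf("NaN run longer than %d samples cannot be bridged.", max_gap),
          class = "pdgait_format_error")
  }
  if (is.na(x[1]) || is.na(x[length(x)])) {
    abort("Series must not start or end with NaN.", class = "pdgait_format_error")
  }
  idx <- which(!is.na(x))
  out <- approx(idx, x[idx], xout = seq_along(x))$y
  inform(sprintf("Bridged %d NaN sample(s) by linear interpolation.",
                 sum(is.na(x))), class = "pdgait_log")
  out
}

#' Baseline statistic of the opening window of a series
#'
#' The mean over the first `window_s` seconds; used as the seated "starting"
#' center-of-mass position against which the TUG event thresholds are
#' referenced.
#'
#' @param x Numeric series.
#' @param window_s Window length (s); must be positive and no longer than the
#'   series.
#' @param rate_hz Sampling rate (Hz).
#'
#' @return Scalar mean of the opening window.
#' @export
baseline_stat <- function(x, window_s, rate_hz) {
  if (window_s <= 0) {
    abort("`window_s` must be positive.", class = "pdgait_config_error")
  }
  n <- round(window_s * rate_hz)
  if (n < 1 || n > length(x)) {
    abort("Baseline window is empty or exceeds the series duration.",
          class = "pdgait_config_error")
  }
  mean(x[seq_len(n)])
}

# filter every positional column of a trial, returning the smoothed data
# frame; rotation components are left untouched (angles are computed from
# the matrices, which must stay on SO(3))
filter_trial_positions <- function(trial, config = analysis_config()) {
  if (isTRUE(attr(trial, "prefiltered"))) return(trial$data)
  spec <- filter_spec(config$filter_cutoff_hz, trial$rate_hz)
  dat <- trial$data
  pos_cols <- setdiff(names(dat)[!grepl("_r[1-3][1-3]$", names(dat))], "t")
  for (col in pos_cols) {
    dat[[col]] <- lowpass_series(dat[[col]], spec,
                                 max_nan_gap_s = config$max_nan_gap_s)
  }
  dat
}

# one-shot smoothing: returns the trial with positional series replaced by
# their filtered versions and marked so downstream steps skip re-filtering
prefilter_trial <- function(trial, config = analysis_config()) {
  trial$data <- filter_trial_positions(trial, config)
  attr(trial, "prefiltered") <- TRUE
  trial
}
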