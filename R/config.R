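#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline: the low-pass filter cutoff,
#' the central capture-zone length used for walking velocity, the TUG
#' event-rule thresholds (1 m gait-initiation distance, 3 m turn distance,
#' 95% sit threshold), the seated-baseline window, event-detector guards and
#' the significance level for the statistical battery.
#'
#' @param filter_cutoff_hz Low-pass cutoff applied to kinematic series (Hz).
#' @param capture_zone_m Length of the central velocity capture zone (m).
#' @param gait_init_distance_m COM forward excursion ending gait initiation (m).
#' @param turn_distance_m COM forward excursion marking the turn (m).
#' @param sit_z_fraction Fraction of standing COM height below which sitting
#'   begins (dimensionless, in (0, 1)).
#' @param baseline_window_s Window over which the seated "starting" COM
#'   position is averaged (s).
#' @param min_peak_separation_s Minimum spacing between detected gait-event
#'   extrema (s).
#' @param z_noise_tolerance_m Vertical noise guard for the stand-initiation
#'   threshold and for peak prominence (m).
#' @param peak_prominence_m Minimum prominence of heel/toe extrema relative to
#'   the COM (m).
#' @param toe_floor_reference Floor reference for toe clearance: the per-side
#'   median stance-phase toe height (`"stance_median"`), the per-side trial
#'   minimum (`"trial_min"`), or a fixed numeric height in m.
#' @param swing_trim_fraction Fraction of each swing trimmed at both ends
#'   before locating the toe-clearance minimum.
#' @param velocity_mode `"zone"` divides the zone length by the crossing time;
#'   `"com"` divides the COM displacement across the zone by the same time.
#' @param alpha Significance level of the battery.
#' @param max_nan_gap_s Longest NaN run the filter will bridge by linear
#'   interpolation (s).
#' @param seed Optional integer seed recorded in reports.
#'
#' @return A list with class `pdgait_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$filter_cutoff_hz
analysis_config <- function(filter_cutoff_hz = 12,
                            capture_zone_m = 3.3,
                            gait_init_distance_m = 1,
                            turn_distance_m = 3,
                            sit_z_fraction = 0.95,
                            baseline_window_s = 0.5,
                            min_peak_separation_s = 0.6,
                            z_noise_tolerance_m = 0.005,
                            peak_prominence_m = 0.01,
                            toe_floor_reference = "stance_median",
                            swing_trim_fraction = 0.1,
                            velocity_mode = c("zone", "com"),
                            alpha = 0.05,
                            max_nan_gap_s = 0.1,
                            seed = NULL) {
  velocity_mode <- match.arg(velocity_mode)
  stopifnot(
    filter_cutoff_hz > 0, capture_zone_m > 0, gait_init_distance_m > 0,
    turn_distance_m > 0, baseline_window_s > 0, min_peak_separation_s > 0,
    z_noise_tolerance_m > 0, peak_prominence_m > 0,
    swing_trim_fraction >= 0, swing_trim_fraction < 0.5,
    alpha > 0, alpha < 1
  )
  if (!(is.numeric(sit_z_fraction) && sit_z_fraction > 0 && sit_z_fraction < 1)) {
    abort("`sit_z_fraction` must lie strictly between 0 and 1.",
          class = "pdgait_config_error")
  }
  if (is.character(toe_floor_reference)) {
    toe_floor_reference <- match.arg(toe_floor_reference,
                                     c("stance_median", "trial_min"))
  } else if (!is.numeric(toe_floor_reference)) {
    abort("`toe_floor_reference` must be a mode name or a numeric height.",
          class = "pdgait_config_error")
  }
  structure(
    list(
      filter_cutoff_hz = filter_cutoff_hz,
      capture_zone_m = capture_zone_m,
      gait_init_distance_m = gait_init_distance_m,
      turn_distance_m = turn_distance_m,
      sit_z_fraction = sit_z_fraction,
      baseline_window_s = baseline_window_s,
      min_peak_separation_s = min_peak_separation_s,
      z_noise_tolerance_m = z_noise_tolerance_m,
      peak_prominence_m = peak_prominence_m,
      toe_floor_reference = toe_floor_reference,
      swing_trim_fraction = swing_trim_fraction,
      velocity_mode = velocity_mode,
      alpha = alpha,
      max_nan_gap_s = max_nan_gap_s,
      seed = seed
    ),
    class = "pdgait_config"
  )
}

#' @export
#' @method print pdgait_config
print.pdgait_config <- function(x, ...) {
  cat("<pdgait analysis configuration>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = " ")))
  }
  invisible(x)
}
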