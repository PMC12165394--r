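marker_series <- c("heel_L", "heel_R", "toe_L", "toe_R")
rotation_series <- c("hip_rot_L", "hip_rot_R", "shoulder_rot_L", "shoulder_rot_R")
rot_cols <- function(series) {
  paste0(series, "_r", c("11", "12", "13", "21", "22", "23", "31", "32", "33"))
}
xyz_cols <- function(series) paste0(series, "_", c("x", "y", "z"))

#' Construct a single-trial kinematic recording
#'
#' A trial recording holds one trial's synchronized time series — whole-body
#' center-of-mass position, bilateral heel/toe marker positions and optional
#' joint rotation-matrix sequences — together with trial metadata. Axes follow
#' the laboratory convention x = direction of travel, y = mediolateral,
#' z = superior-inferior; positions are in metres, time in seconds.
#'
#' @param data Data frame with one row per frame: a `t` column (s) plus
#'   `com_x`, `com_y`, `com_z`, optional `heel_L_*`/`heel_R_*`/`toe_L_*`/
#'   `toe_R_*` triples and optional `hip_rot_*`/`shoulder_rot_*` rotation
#'   matrices stored row-major as nine `_r11` ... `_r33` columns.
#' @param trial_id Identifier string.
#' @param condition One of `"TUG"`, `"WALK_ST"`, `"WALK_DT"`.
#' @param rate_hz Sampling rate in frames per second (120 for the supported
#'   capture system).
#' @param impaired_side One of `"left"`, `"right"`, `"bilateral"`, `"none"`.
#'
#' @details Validation enforces a strictly increasing time vector with spacing
#'   `1/rate_hz` (tolerance 1e-9 s) and, for every rotation-matrix series,
#'   orthonormality with determinant +1 (tolerance 1e-6); matrices within
#'   tolerance are re-orthonormalized by polar projection.
#'
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(data, trial_id = "trial",
                            condition = c("TUG", "WALK_ST", "WALK_DT"),
                            rate_hz = 120,
                            impaired_side = c("none", "left", "right", "bilateral")) {
  condition <- match.arg(condition)
  impaired_side <- match.arg(impaired_side)
  data <- tibble::as_tibble(data)

  need <- c("t", xyz_cols("com"))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pdgait_schema_error")
  }
  t <- data$t
  if (nrow(data) < 2 || any(diff(t) <= 0)) {
    abort("Time vector must be strictly increasing with at least 2 frames.",
          class = "pdgait_format_error")
  }
  if (max(abs(diff(t) - 1 / rate_hz)) > 1e-9) {
    abort(sprintf("Time spacing deviates from 1/%g s by more than 1e-9 s.",
                  rate_hz),
          class = "pdgait_format_error")
  }
  # marker triples must be complete if any of the triple is present
  for (s in marker_series) {
    cols <- xyz_cols(s)
    present <- cols %in% names(data)
    if (any(present) && !all(present)) {
      abort(sprintf("Marker series '%s' is incomplete (needs x, y, z).", s),
            class = "pdgait_schema_error")
    }
  }
  for (s in rotation_series) {
    cols <- rot_cols(s)
    present <- cols %in% names(data)
    if (!any(present)) next
    if (!all(present)) {
      abort(sprintf("Rotation series '%s' is incomplete (needs 9 components).", s),
            class = "pdgait_schema_error")
    }
    R <- as.matrix(data[cols])
    data[cols] <- reorthonormalize(R, series = s)
  }

  structure(
    list(
      trial_id = trial_id,
      condition = condition,
      rate_hz = rate_hz,
      impaired_side = impaired_side,
      data = data
    ),
    class = "trial_recording"
  )
}

# orthonormality error and determinant of row-major 3x3 rotations, vectorized
rotation_checks <- function(R) {
  g <- function(j) R[, j]
  # unique entries of R R' - I (row dot products)
  e <- cbind(
    g(1)^2 + g(2)^2 + g(3)^2 - 1,
    g(4)^2 + g(5)^2 + g(6)^2 - 1,
    g(7)^2 + g(8)^2 + g(9)^2 - 1,
    g(1) * g(4) + g(2) * g(5) + g(3) * g(6),
    g(1) * g(7) + g(2) * g(8) + g(3) * g(9),
    g(4) * g(7) + g(5) * g(8) + g(6) * g(9)
  )
  dets <- g(1) * (g(5) * g(9) - g(6) * g(8)) -
    g(2) * (g(4) * g(9) - g(6) * g(7)) +
    g(3) * (g(4) * g(8) - g(5) * g(7))
  list(err = apply(abs(e), 1, max), det = dets)
}

# project each row-major 3x3 rotation onto SO(3) via SVD; error if the input
# is further than `tol` from a proper rotation
reorthonormalize <- function(R, tol = 1e-6, series = "rotation") {
  chk <- rotation_checks(R)
  bad_det <- which(chk$det < 0)
  if (length(bad_det)) {
    abort(sprintf(
      "Rotation series '%s' row %d has determinant %.3f; reflections are not rotations.",
      series, bad_det[1], chk$det[bad_det[1]]),
      class = "pdgait_validation_error")
  }
  bad <- which(chk$err > tol)
  if (length(bad)) {
    abort(sprintf(
      "Rotation series '%s' row %d is non-orthonormal (|R R' - I| = %.2e).",
      series, bad[1], chk$err[bad[1]]),
      class = "pdgait_validation_error")
  }
  fix <- which(chk$err > 1e-12)
  for (i in fix) {
    M <- matrix(R[i, ], 3, 3, byrow = TRUE)
    sv <- svd(M)
    R[i, ] <- as.vector(t(sv$u %*% t(sv$v)))
  }
  R
}

has_series <- function(trial, series) {
  cols <- if (series %in% rotation_series) rot_cols(series) else xyz_cols(series)
  all(cols %in% names(trial$data))
}

series_matrix <- function(trial, series) {
  cols <- if (series %in% rotation_series) rot_cols(series) else xyz_cols(series)
  if (!all(cols %in% names(trial$data))) {
    abort(sprintf("Trial '%s' lacks series '%s'.", trial$trial_id, series),
          class = "pdgait_schema_error")
  }
  as.matrix(trial$data[cols])
}

n_frames <- function(trial) nrow(trial$data)

#' @export
#' @method print trial_recording
print.trial_recording <- function(x, ...) {
  dur <- diff(range(x$data$t))
  cat(sprintf("<trial_recording '%s'> %s, %g Hz, %d frames (%.2f s)\n",
              x$trial_id, x$condition, x$rate_hz, nrow(x$data), dur))
  present <- c("com",
               marker_series[vapply(marker_series, has_series, TRUE, trial = x)],
               rotation_series[vapply(rotation_series, has_series, TRUE, trial = x)])
  cat("  series:", paste(present, collapse = ", "), "\n")
  cat("  impaired side:", x$impaired_side, "\n")
  invisible(x)
}

#' @rdname trial_recording
#' @param x Object to test or plot.
#' @export
is_trial_recording <- function(x) inherits(x, "trial_recording")
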