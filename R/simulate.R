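# Waveform families are chosen for closed-form event times and extrema, not
# biomechanical realism: smoothstep + Gaussian-overshoot COM height for the
# sit-stand-sit arc, piecewise C1 forward progression with a sinusoidal turn
# excursion, sinusoidal limb oscillation with a two-hump swing-phase toe
# trajectory whose interior minimum is the programmed toe clearance.

smoothstep <- function(u) {
  u <- pmax(0, pmin(1, u))
  u * u * (3 - 2 * u)
}

#' Simulate a TUG trial with analytic ground-truth events
#'
#' Generates a center-of-mass trajectory for the Timed Up and Go test whose
#' event-rule crossing times are known in closed form: COM height rises from
#' the seated baseline through a sharp standing overshoot (the height peak),
#' the forward excursion accelerates through the 1 m and 3 m thresholds,
#' reverses through them after the turn, and height descends through the
#' sitting threshold back to the seat. Ground-truth event times are the
#' exact crossing times of the detection rules on the continuous noise-free
#' waveforms (root-finding at 1e-12 s where no algebraic form exists).
#'
#' @param durations Seven phase durations (s): sit-to-stand, gait
#'   initiation, walk 1, turn, walk 2, slow down & turn, sit down.
#' @param seated_z,standing_z Seated and standing COM heights (m).
#' @param overshoot_m Height of the standing overshoot peak above the
#'   standing plateau (m); must keep the plateau above the sitting
#'   threshold.
#' @param walk_speed Optional nominal walk speed (m/s); the cruise speed is
#'   fixed by the walk-1 duration (2 m / duration) and a nominal speed
#'   incompatible with it beyond 25% is a parameter error.
#' @param sit_z_fraction Sitting threshold as a fraction of standing height.
#' @param z_tolerance_m Stand-initiation noise tolerance used by the
#'   matching detector rule.
#' @param noise_sd Additive i.i.d. Gaussian position noise (m).
#' @param rate_hz Sampling rate.
#' @param lead_in_s Seated time before stand initiation (must cover the
#'   detector's baseline window).
#' @param seed Optional integer seed; identical seeds give identical output.
#'
#' @return A list: `trial` (a [trial_recording()]), `events` (tibble of the
#'   eight ground-truth event times), `phases` (ground-truth `tug_phases`
#'   durations), and `params`.
#' @export
simulate_tug_trajectory <- function(durations = c(1.13, 0.59, 1.73, 2.98,
                                                  1.89, 1.32, 1.33),
                                    seated_z = 0.55, standing_z = 0.93,
                                    overshoot_m = 0.03,
                                    walk_speed = NULL,
                                    sit_z_fraction = 0.95,
                                    z_tolerance_m = 0.005,
                                    noise_sd = 0, rate_hz = 120,
                                    lead_in_s = 0.75, seed = NULL) {
  if (length(durations) != 7 || any(durations <= 0)) {
    abort("`durations` must be seven positive phase times.",
          class = "pdgait_param_error")
  }
  if (standing_z <= seated_z || noise_sd < 0) {
    abort("Standing height must exceed seated height; noise must be >= 0.",
          class = "pdgait_param_error")
  }
  d <- durations
  z0 <- seated_z; z1 <- standing_z; h <- overshoot_m
  frac <- sit_z_fraction
  if (z1 <= frac * (z1 + h)) {
    abort("Overshoot too large: standing plateau falls below the sitting threshold.",
          class = "pdgait_param_error")
  }
  v23 <- 2 / d[3]
  if (!is.null(walk_speed) && abs(v23 - walk_speed) / walk_speed > 0.25) {
    abort(sprintf(
      "walk1 duration %.2f s incompatible with walk speed %.2f m/s: cannot span 2 m.",
      d[3], walk_speed), class = "pdgait_param_error")
  }

  t1 <- lead_in_s
  tpk <- t1 + d[1]
  t3 <- tpk + d[2]
  t4 <- t3 + d[3]
  t5 <- t4 + d[4]
  t6 <- t5 + d[5]
  t7 <- t6 + d[6]
  t8 <- t7 + d[7]

  # forward progression: half-cosine speed ramp to the cruise speed fixed by
  # walk 1, reaching 1 m exactly at t3 and 3 m at t4
  if (v23 * (d[1] + d[2]) < 1) {
    abort(sprintf(
      "gait_init_end unreachable: cannot span 1 m by %.2f s at %.2f m/s.",
      d[1] + d[2], v23), class = "pdgait_param_error")
  }
  r <- min(0.6, 1.8 * (t3 - t1 - 1 / v23))
  if (r <= 0.02) {
    abort("gait_init_end unreachable: ramp window collapses.",
          class = "pdgait_param_error")
  }
  tx0 <- t3 - 1 / v23 - r / 2
  A_turn <- v23 * d[4] / pi

  rr <- min(0.4, d[5] / 2)
  v56 <- (2 - v23 * rr / 2) / (d[5] - rr / 2)
  if (v56 <= 0) {
    abort("walk2 duration incompatible with the turn exit speed.",
          class = "pdgait_param_error")
  }
  # slow-down / sit approach: speed decays from the walk-2 exit speed toward
  # a sustained creep so the start-line crossing happens at t8 with a
  # well-conditioned (non-vanishing) approach speed
  tau8 <- d[6] + d[7]
  Tr <- 0.35
  Efac <- exp(-tau8 / Tr)
  v_low <- (1 - v56 * Tr * (1 - Efac)) / (tau8 - Tr * (1 - Efac))
  if (!is.finite(v_low) || v_low <= 0.02) {
    abort("slow-down and sit phases incompatible with returning to the start position.",
          class = "pdgait_param_error")
  }

  x_of <- function(t) {
    x <- numeric(length(t))
    seg <- t >= tx0 & t < tx0 + r
    tau <- t[seg] - tx0
    x[seg] <- v23 / 2 * (tau - (r / pi) * sin(pi * tau / r))
    seg <- t >= tx0 + r & t < t4
    x[seg] <- v23 * (t[seg] - tx0 - r / 2)
    seg <- t >= t4 & t < t5
    x[seg] <- 3 + A_turn * sin(pi * (t[seg] - t4) / d[4])
    seg <- t >= t5 & t < t5 + rr
    tau <- t[seg] - t5
    x[seg] <- 3 - (v23 * tau + (v56 - v23) * tau^2 / (2 * rr))
    seg <- t >= t5 + rr & t < t6
    tau <- t[seg] - t5
    x[seg] <- 3 - (rr * (v23 + v56) / 2 + v56 * (tau - rr))
    seg <- t >= t6
    tau <- t[seg] - t6
    x[seg] <- 1 - (v_low * tau + (v56 - v_low) * Tr * (1 - exp(-tau / Tr)))
    x
  }

  # COM height: smoothstep rise peaking (with a Gaussian overshoot) at tpk,
  # plateau, cosine descent crossing the sitting threshold exactly at t7
  w_bump <- 0.08
  zth <- frac * (z1 + h)
  D_desc <- 0.9
  delta <- (D_desc / pi) * acos(2 * (zth - z0) / (z1 - z0) - 1)
  tds <- t7 - delta
  if (tds <= t6) {
    abort("slow-down phase too short for the sitting descent.",
          class = "pdgait_param_error")
  }
  z_of <- function(t) {
    base <- z0 + (z1 - z0) * smoothstep((t - t1) / d[1])
    desc <- t >= tds
    tau <- pmin(t[desc] - tds, D_desc)
    base[desc] <- z0 + (z1 - z0) * (1 + cos(pi * tau / D_desc)) / 2
    base + h * exp(-((t - tpk) / w_bump)^2)
  }

  ev <- c(
    stand_init = stats::uniroot(function(t) z_of(t) - (z0 + z_tolerance_m),
                                c(t1, tpk), tol = 1e-12)$root,
    stand_end = tpk,
    gait_init_end = t3,
    turn_begin = t4,
    turn_end = t5,
    walk2_end = t6,
    sit_begin = stats::uniroot(function(t) z_of(t) - zth,
                               c(tds + 1e-9, tds + D_desc), tol = 1e-12)$root,
    sit_end = t8
  )

  t <- seq(0, t8 + 1, by = 1 / rate_hz)
  if (!is.null(seed)) set.seed(seed)
  noise <- function() if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
  dat <- tibble::tibble(
    t = t,
    com_x = x_of(t) + noise(),
    com_y = 0 + noise(),
    com_z = z_of(t) + noise()
  )
  trial <- trial_recording(dat, trial_id = sprintf("tug_sim_%s", seed %||% "x"),
                           condition = "TUG", rate_hz = rate_hz)
  truth <- tibble::tibble(event = tug_event_names, time = unname(ev))
  list(
    trial = trial,
    events = truth,
    phases = compute_phase_times(truth$time),
    params = list(durations = d, seated_z = z0, standing_z = z1,
                  overshoot_m = h, cruise_speed = v23,
                  sit_z_fraction = frac, noise_sd = noise_sd,
                  rate_hz = rate_hz, seed = seed)
  )
}

#' Simulate a walking trial with closed-form gait events and metrics
#'
#' The COM advances at constant speed; heel and toe markers oscillate
#' sinusoidally about it at the stride frequency `v / stride_length`, with
#' the toe phase lag set so the programmed double-support time is realized
#' exactly. The swing-phase toe height is a two-hump curve whose interior
#' minimum equals the programmed minimum toe clearance at mid-swing. Hip and
#' shoulder flexion-extension follow sinusoids with the programmed ranges of
#' motion. All foot-strike/foot-off times and the metric panel are emitted
#' in closed form.
#'
#' @param velocity Walking speed (m/s).
#' @param stride_length Stride length (m).
#' @param double_support Double-support time per stride (s); must be less
#'   than the stride time.
#' @param toe_clearance Minimum toe clearance (m).
#' @param hip_rom Hip flexion-extension ROM (deg), recycled to both sides.
#' @param shoulder_rom_L,shoulder_rom_R Shoulder ROM per side (deg).
#' @param trial_length_m Walkway length (m, >= 15 so the central 3.3 m
#'   capture zone has > 5 m of lead-in).
#' @param noise_sd Additive i.i.d. Gaussian position noise (m).
#' @param rate_hz Sampling rate.
#' @param condition `"WALK_ST"` or `"WALK_DT"`.
#' @param impaired_side Impairment tag carried into the trial metadata.
#' @param seed Optional integer seed.
#'
#' @return A list: `trial`, `events` (ground-truth strike/off tibble) and
#'   `truth` (named list of programmed metric values).
#' @export
simulate_walking_trial <- function(velocity = 1.32, stride_length = 1.36,
                                   double_support = 0.34,
                                   toe_clearance = 0.034,
                                   hip_rom = 50.38,
                                   shoulder_rom_L = 30, shoulder_rom_R = 30,
                                   trial_length_m = 15,
                                   noise_sd = 0, rate_hz = 120,
                                   condition = c("WALK_ST", "WALK_DT"),
                                   impaired_side = "none", seed = NULL) {
  condition <- match.arg(condition)
  if (velocity <= 0 || stride_length <= 0 || toe_clearance <= 0) {
    abort("velocity, stride_length and toe_clearance must be positive.",
          class = "pdgait_param_error")
  }
  f <- velocity / stride_length
  T_str <- 1 / f
  if (double_support >= T_str) {
    abort(sprintf("double support %.2f s must be below the stride time %.2f s.",
                  double_support, T_str), class = "pdgait_param_error")
  }
  if (trial_length_m < 15) {
    abort("trial_length_m must be at least 15 m.", class = "pdgait_param_error")
  }
  hip_rom <- rep(hip_rom, length.out = 2)
  if (any(c(hip_rom, shoulder_rom_L, shoulder_rom_R) <= 0)) {
    abort("ROM parameters must be positive.", class = "pdgait_param_error")
  }

  dur <- trial_length_m / velocity
  t <- seq(0, dur, by = 1 / rate_hz)
  omega <- 2 * pi * f
  phi <- c(L = 0, R = pi)
  psi <- -pi * f * double_support     # toe lag realizing the programmed DS
  A <- stride_length / 4
  floor_z <- 0.02
  swing <- T_str / 2 - double_support / 2
  stance <- T_str - swing
  hump <- 3 * toe_clearance           # keeps the mid-swing dip interior

  if (!is.null(seed)) set.seed(seed)
  noise <- function() if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0

  com_x <- velocity * t
  dat <- tibble::tibble(t = t,
                        com_x = com_x + noise(),
                        com_y = 0 + noise(),
                        com_z = 0.9 + noise())

  times_at <- function(theta0) {
    # solutions of omega * t + offset = theta0 (mod 2pi) within the trial
    k <- seq(floor((omega * 0 - theta0) / (2 * pi)) - 1,
             ceiling((omega * dur - theta0) / (2 * pi)) + 1)
    tt <- (theta0 + 2 * pi * k) / omega
    sort(tt[tt >= 0 & tt <= dur])
  }

  events <- list()
  for (side in c("L", "R")) {
    th <- phi[[side]]
    dat[[paste0("heel_", side, "_x")]] <- com_x + A * sin(omega * t + th) + noise()
    dat[[paste0("heel_", side, "_y")]] <- (if (side == "L") 0.1 else -0.1) + noise()
    dat[[paste0("heel_", side, "_z")]] <- floor_z + noise()
    dat[[paste0("toe_", side, "_x")]] <- com_x + A * sin(omega * t + th + psi) + noise()
    dat[[paste0("toe_", side, "_y")]] <- (if (side == "L") 0.1 else -0.1) + noise()

    strikes <- times_at(pi / 2 - th)
    offs <- times_at(-pi / 2 - th - psi)
    events[[side]] <- dplyr::bind_rows(
      tibble::tibble(side = side, event = "strike", time = strikes),
      tibble::tibble(side = side, event = "off", time = offs)
    )

    # toe height: 0 in stance; in swing (fraction s from foot off) the curve
    # TC*sin^2(pi s) + 3*TC*sin^2(2 pi s) has its interior minimum TC at s = 1/2
    off0 <- offs[1] %% T_str
    u <- (t - off0) %% T_str
    s <- u / swing
    q <- ifelse(u < swing,
                toe_clearance * sin(pi * s)^2 + hump * sin(2 * pi * s)^2,
                0)
    dat[[paste0("toe_", side, "_z")]] <- floor_z + q + noise()

    hip_alpha <- 25 + (hip_rom[[if (side == "L") 1 else 2]] / 2) *
      sin(omega * t + th)
    sh_rom <- if (side == "L") shoulder_rom_L else shoulder_rom_R
    sh_alpha <- -10 + (sh_rom / 2) * sin(omega * t + th + pi)
    for (joint in c("hip", "shoulder")) {
      alpha <- if (joint == "hip") hip_alpha else sh_alpha
      Rflat <- cardan_xyz_series(alpha, 5, 3)
      colnames(Rflat) <- rot_cols(paste0(joint, "_rot_", side))
      dat <- dplyr::bind_cols(dat, tibble::as_tibble(Rflat))
    }
  }

  trial <- trial_recording(dat,
                           trial_id = sprintf("walk_sim_%s", seed %||% "x"),
                           condition = condition, rate_hz = rate_hz,
                           impaired_side = impaired_side)
  ev <- dplyr::arrange(dplyr::bind_rows(events), .data$time)
  truth <- list(
    velocity = velocity, stride_length = stride_length,
    double_support = double_support, toe_clearance = toe_clearance,
    hip_rom_L = hip_rom[1], hip_rom_R = hip_rom[2],
    shoulder_rom_L = shoulder_rom_L, shoulder_rom_R = shoulder_rom_R,
    shoulder_symmetry = symmetry_angle(shoulder_rom_L, shoulder_rom_R),
    stride_time = T_str, stance_time = stance, swing_time = swing
  )
  list(trial = trial, events = ev, truth = truth,
       params = list(noise_sd = noise_sd, rate_hz = rate_hz, seed = seed,
                     condition = condition))
}

#' Default cohort marginals (means, SDs, distribution shapes)
#'
#' The per-variable means and standard deviations of the 22 analysis
#' variables, with lognormal shapes for the variables whose observed
#' distributions are right-skewed (response inhibition, TUG sit-down time,
#' both shoulder asymmetries and dual-task double support) and Gaussian
#' shapes otherwise.
#'
#' @return Tibble with columns `variable`, `mean`, `sd`, `shape`.
#' @export
default_cohort_marginals <- function() {
  tb <- tibble::tribble(
    ~variable, ~mean, ~sd,
    "response_inhibition", 13.0, 13.9,
    "working_memory", 4.7, 1.2,
    "mental_rotation", 54.1, 31.3,
    "tug_sit_to_stand", 1.13, 0.30,
    "tug_gait_initiation", 0.59, 0.19,
    "tug_walk1", 1.73, 0.27,
    "tug_turn", 2.98, 0.68,
    "tug_walk2", 1.89, 0.38,
    "tug_slow_down_turn", 1.32, 0.44,
    "tug_sit_down", 1.33, 0.56,
    "velocity_st", 1.32, 0.21,
    "stride_length_st", 1.36, 0.19,
    "double_support_st", 0.34, 0.03,
    "toe_clearance_st", 0.034, 0.011,
    "hip_rom_st", 50.38, 6.11,
    "shoulder_asymmetry_st", 9.03, 8.30,
    "velocity_dt", 1.12, 0.28,
    "stride_length_dt", 1.22, 0.22,
    "double_support_dt", 0.40, 0.05,
    "toe_clearance_dt", 0.030, 0.012,
    "hip_rom_dt", 46.42, 8.37,
    "shoulder_asymmetry_dt", 12.85, 13.25
  )
  skewed <- c("response_inhibition", "tug_sit_down", "shoulder_asymmetry_st",
              "double_support_dt", "shoulder_asymmetry_dt")
  dplyr::mutate(tb, shape = ifelse(.data$variable %in% skewed,
                                   "lognormal", "gaussian"))
}

#' Default cohort correlation targets
#'
#' Embeds the observed cognitive-by-TUG and cognitive-by-dual-task
#' correlations; all other off-diagonal entries default to zero. The matrix
#' is a target: it is not positive semi-definite as printed (three
#' predictors each correlate strongly with the same responses while being
#' mutually uncorrelated), so [simulate_cohort()] applies a nearest-PSD
#' repair before sampling.
#'
#' @return A 22 x 22 symmetric matrix with unit diagonal.
#' @export
default_cohort_correlation <- function() {
  vars <- default_cohort_marginals()$variable
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  tug <- tug_phase_vars
  set_vec <- function(pred, deps, rs) {
    purrr::walk2(deps, rs, function(d, r) set_r(pred, d, r))
  }
  set_vec("response_inhibition", tug,
          c(-0.4704, 0.0705, -0.4861, -0.4366, -0.5114, -0.2148, -0.4102))
  set_vec("working_memory", tug,
          c(-0.613, 0.1025, -0.5186, -0.5592, -0.682, -0.4619, -0.4191))
  set_vec("mental_rotation", tug,
          c(-0.5401, -0.1389, -0.6458, -0.6377, -0.6755, -0.4989, -0.2917))
  dt <- walking_vars_dt
  set_vec("response_inhibition", dt,
          c(0.4179, 0.3555, -0.1477, 0.3413, 0.5632, 0.1337))
  set_vec("working_memory", dt,
          c(0.6524, 0.6758, -0.3145, 0.5234, 0.6803, 0.2411))
  set_vec("mental_rotation", dt,
          c(0.3583, 0.5178, -0.1418, 0.3514, 0.4886, 0.5894))
  R
}

#' Simulate a participant cohort with a known correlation structure
#'
#' Gaussian copula: draws multivariate-normal scores with the target
#' correlation matrix (repaired to the nearest positive semi-definite
#' correlation matrix if needed, with a log message) and transforms each
#' margin to its declared shape, moment-matched to the stated mean and SD.
#' Lognormal margins produce the right-skew that forces the Spearman gate.
#'
#' @param n Number of participants.
#' @param marginals Tibble as in [default_cohort_marginals()].
#' @param target_corr Symmetric correlation matrix over the marginal
#'   variables (defaults to [default_cohort_correlation()]).
#' @param seed Optional integer seed.
#'
#' @return A list: `cohort` (tibble with `participant_id` plus one column
#'   per variable) and `truth` (target and sampled-from correlation
#'   matrices, marginals, repair flag).
#' @export
simulate_cohort <- function(n = 19,
                            marginals = default_cohort_marginals(),
                            target_corr = NULL,
                            seed = NULL) {
  if (n < 2) abort("Cohort needs n >= 2.", class = "pdgait_param_error")
  if (any(marginals$sd <= 0)) {
    abort("Marginal SDs must be positive.", class = "pdgait_param_error")
  }
  vars <- marginals$variable
  R <- target_corr %||% default_cohort_correlation()
  R <- R[vars, vars]
  if (max(abs(R - t(R))) > 1e-12 || any(abs(diag(R) - 1) > 1e-12)) {
    abort("target_corr must be symmetric with unit diagonal.",
          class = "pdgait_param_error")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  R_use <- R
  if (min(ev) < -1e-10) {
    np <- Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE)
    if (!np$converged) {
      abort("Correlation matrix could not be repaired to PSD.",
            class = "pdgait_param_error")
    }
    R_use <- as.matrix(np$mat)
    repaired <- TRUE
    inform(sprintf(
      "Target correlation matrix is not PSD (min eigenvalue %.3g); using nearest-PSD repair.",
      min(ev)), class = "pdgait_log")
  }
  L <- chol(R_use + diag(1e-12, nrow(R_use)))
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n * length(vars)), n) %*% L
  U <- pnorm(Z)
  cohort <- tibble::tibble(participant_id = sprintf("P%02d", seq_len(n)))
  for (j in seq_along(vars)) {
    m <- marginals$mean[j]; s <- marginals$sd[j]
    cohort[[vars[j]]] <- if (marginals$shape[j] == "lognormal") {
      sdlog <- sqrt(log(1 + (s / m)^2))
      qlnorm(U[, j], meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    } else {
      qnorm(U[, j], mean = m, sd = s)
    }
  }
  list(
    cohort = cohort,
    truth = list(target_corr = R, sampling_corr = R_use,
                 repaired = repaired, marginals = marginals,
                 n = n, seed = seed)
  )
}
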