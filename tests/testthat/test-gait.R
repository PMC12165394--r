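test_that("gait events land on the analytic extrema of the simulator", {
  sim <- simulate_walking_trial(seed = 3, noise_sd = 0)
  ev <- detect_gait_events(sim$trial)
  for (s in c("L", "R")) {
    for (e in c("strike", "off")) {
      det <- ev$time[ev$side == s & ev$event == e]
      tru <- sim$events$time[sim$events$side == s & sim$events$event == e]
      tru <- tru[tru >= min(det) - 1 / 120 & tru <= max(det) + 1 / 120]
      expect_length(det, length(tru))
      expect_lt(max(abs(det - tru)), 1 / 120 + 1e-9)
    }
  }
})

test_that("markers without oscillation give an insufficient-strides error", {
  sim <- simulate_walking_trial(seed = 9)
  trial <- sim$trial
  trial$data$heel_L_x <- trial$data$com_x + 0.1
  expect_error(detect_gait_events(trial), "insufficient strides",
               class = "pdgait_detection_error")
})

test_that("capture-zone velocity equals zone length over crossing time", {
  rate <- 120
  t <- (0:1399) / rate
  trial <- make_com_trial(1.32 * t, condition = "WALK_ST")
  expect_equal(capture_zone_velocity(trial), 1.32, tolerance = 1e-3)

  # fluctuating but monotone speed: still displacement over time
  x <- 1.1 * t + 0.03 * sin(2 * pi * t / 1.4)
  trial2 <- make_com_trial(x, condition = "WALK_ST")
  v <- capture_zone_velocity(trial2)
  expect_equal(v, 3.3 / (uniroot(function(u) 1.1 * u + 0.03 * sin(2 * pi * u / 1.4) -
                                   (min(x) + max(x)) / 2 - 1.65,
                                 c(0, max(t)), tol = 1e-12)$root -
                           uniroot(function(u) 1.1 * u + 0.03 * sin(2 * pi * u / 1.4) -
                                     (min(x) + max(x)) / 2 + 1.65,
                                   c(0, max(t)), tol = 1e-12)$root),
               tolerance = 1e-3)

  # zone placed beyond the COM excursion: not fully traversed
  x3 <- pmin(1.2 * t, 7)
  expect_error(capture_zone_velocity(make_com_trial(x3, condition = "WALK_ST"),
                                     zone_center = 10),
               class = "pdgait_detection_error")
  # direction reversal inside the zone
  x4 <- 1.2 * t - 2.0 * pmax(0, pmin(t - 4, 1.5))
  expect_error(capture_zone_velocity(make_com_trial(x4, condition = "WALK_ST")),
               class = "pdgait_detection_error")
})

test_that("stride length averages same-side heel displacement at strikes", {
  sim <- simulate_walking_trial(seed = 21, stride_length = 1.22,
                                velocity = 1.12)
  ev <- detect_gait_events(sim$trial)
  expect_equal(stride_length(ev, sim$trial), 1.22, tolerance = 0.01)
})

test_that("double support matches the hand-laid example and the boundary case", {
  ev <- make_gait_events(
    list("L", "strike", 0.00), list("R", "off", 0.17),
    list("R", "strike", 0.55), list("L", "off", 0.72),
    list("L", "strike", 1.10)
  )
  expect_equal(double_support_time(ev), 0.34, tolerance = 1e-12)
  # off coincident with the opposite strike: zero double support
  ev0 <- make_gait_events(
    list("L", "strike", 0.00), list("R", "off", 0.00),
    list("R", "strike", 0.55), list("L", "off", 0.55),
    list("L", "strike", 1.10)
  )
  expect_equal(double_support_time(ev0), 0)
  # programmed double support from the simulator
  sim <- simulate_walking_trial(seed = 8, double_support = 0.40,
                                velocity = 1.12, stride_length = 1.22)
  evs <- detect_gait_events(sim$trial)
  expect_equal(double_support_time(evs), 0.40, tolerance = 1 / 120)
})

test_that("toe clearance recovers the programmed swing minimum", {
  sim <- simulate_walking_trial(seed = 6, toe_clearance = 0.030,
                                noise_sd = 0.001)
  ev <- detect_gait_events(sim$trial)
  tc <- min_toe_clearance(sim$trial, ev)
  expect_lt(abs(tc[["L"]] - 0.030), 0.002)
  expect_lt(abs(tc[["R"]] - 0.030), 0.002)
  expect_s3_class(attr(tc, "swings"), "tbl_df")
})

test_that("Cardan decomposition inverts composition away from gimbal lock", {
  R <- compose_cardan_xyz(10, 20, 30)
  ang <- cardan_xyz_angles(matrix(as.vector(t(R)), 1, 9))
  expect_equal(unlist(ang[1, c("alpha", "beta", "gamma")]),
               c(alpha = 10, beta = 20, gamma = 30), tolerance = 1e-9)
  expect_equal(unlist(cardan_xyz_angles(matrix(as.vector(diag(3)), 1, 9))[1, 1:3]),
               c(alpha = 0, beta = 0, gamma = 0))
  R30 <- compose_cardan_xyz(30, 0, 0)
  expect_equal(cardan_xyz_angles(matrix(as.vector(t(R30)), 1, 9))$alpha, 30,
               tolerance = 1e-9)
  expect_error(cardan_xyz_angles(matrix(rep(1, 9), 1, 9)),
               class = "pdgait_validation_error")
})

test_that("joint ROM recovers the programmed range and flags constants", {
  sim <- simulate_walking_trial(seed = 13, hip_rom = 46.4)
  ev <- detect_gait_events(sim$trial)
  ang <- cardan_xyz_angles(pdgait:::series_matrix(sim$trial, "hip_rot_L"))
  expect_equal(joint_rom(ang$alpha, sim$trial$data$t, ev, "L"), 46.4,
               tolerance = 0.5)
  expect_warning(rom0 <- joint_rom(rep(25, nrow(sim$trial$data)),
                                   sim$trial$data$t, ev, "L"),
                 class = "pdgait_degenerate_warning")
  expect_equal(rom0, 0)
})

test_that("symmetry angle matches direct evaluation and the impaired-side rule applies", {
  expect_equal(symmetry_angle(30, 30), 0)
  expect_equal(symmetry_angle(30, 40),
               abs((45 - atan(30 / 40) * 180 / pi) / 90 * 100),
               tolerance = 1e-12)
  expect_equal(symmetry_angle(0, 40), 50)
  expect_equal(symmetry_angle(30, 40, signed = TRUE),
               -symmetry_angle(40, 30, signed = TRUE), tolerance = 1e-12)
  expect_error(symmetry_angle(0, 0), class = "pdgait_precondition_error")

  expect_equal(impaired_side_value(0.030, 0.040, "left"), 0.030)
  expect_equal(impaired_side_value(0.030, 0.040, "bilateral"), 0.035)
  expect_equal(impaired_side_value(0.030, 0.040, "none"), 0.035)
  expect_error(impaired_side_value(NA_real_, 0.04, "left"),
               class = "pdgait_precondition_error")
})

test_that("the walking panel composes all metrics and averages across trials", {
  sim <- simulate_walking_trial(seed = 14, velocity = 1.12,
                                stride_length = 1.22, double_support = 0.40,
                                toe_clearance = 0.030, hip_rom = 46.4,
                                shoulder_rom_L = 30, shoulder_rom_R = 40,
                                condition = "WALK_DT", impaired_side = "left")
  panel <- suppressMessages(summarize_walking_trial(sim$trial))
  expect_lt(abs(panel$velocity - 1.12), 0.012)
  expect_lt(abs(panel$stride_length - 1.22), 0.015)
  expect_lt(abs(panel$double_support - 0.40), 0.004)
  expect_lt(abs(panel$toe_clearance - 0.030), 0.002)
  expect_equal(panel$hip_rom, panel$hip_rom_L) # impaired side = left
  expect_equal(panel$shoulder_symmetry, sim$truth$shoulder_symmetry,
               tolerance = 0.1)

  # shoulder series missing: shoulder fields NA, rest computed
  trial2 <- sim$trial
  trial2$data <- trial2$data[!grepl("^shoulder_rot", names(trial2$data))]
  expect_message(p2 <- summarize_walking_trial(trial2), class = "pdgait_log")
  expect_true(is.na(p2$shoulder_symmetry))
  expect_false(is.na(p2$velocity))

  avg <- suppressMessages(average_walking_trials(list(
    dplyr::mutate(panel, velocity = 1.1),
    dplyr::mutate(panel, velocity = 1.3)
  )))
  expect_equal(avg$velocity, 1.2)
})
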