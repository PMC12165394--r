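test_that("detected TUG events match analytic truth within one frame", {
  sim <- simulate_tug_trajectory(seed = 7, noise_sd = 0)
  ev <- detect_tug_events(sim$trial)
  expect_equal(ev$times$event, sim$events$event)
  expect_lt(max(abs(ev$times$time - sim$events$time)), 1 / 120 + 1e-9)
})

test_that("an excursion short of the turn distance names the missing event", {
  sim <- simulate_tug_trajectory(seed = 1)
  trial <- sim$trial
  # cap the forward excursion below 3 m
  trial$data$com_x <- pmin(trial$data$com_x, 2.5)
  expect_error(detect_tug_events(trial), "turn_begin",
               class = "pdgait_detection_error")
})

test_that("a trial without a seated baseline is rejected", {
  rate <- 120
  t <- (0:600) / rate
  z <- 0.55 + 0.4 * pmin(t / 2, 1) # rising from frame 0
  x <- pmin(1.2 * t, 4)
  trial <- make_com_trial(x, z)
  expect_error(detect_tug_events(trial), class = "pdgait_precondition_error")
})

test_that("phase durations telescope from the event times", {
  events <- c(0.5, 1.63, 2.22, 3.95, 6.93, 8.82, 10.14, 11.47)
  ph <- compute_phase_times(events)
  expect_equal(ph$duration, c(1.13, 0.59, 1.73, 2.98, 1.89, 1.32, 1.33),
               tolerance = 1e-12)
  expect_equal(sum(ph$duration), events[8] - events[1])
  expect_error(compute_phase_times(c(0.5, 1.63, 2.22, 3.95, 6.93, 6.93,
                                     10.14, 11.47)),
               class = "pdgait_detection_error")
})

test_that("repeated-trial averaging is the element-wise mean", {
  a <- compute_phase_times(cumsum(c(0.5, 1.0, 0.5, 1.7, 3.0, 1.9, 1.3, 1.3)))
  b <- compute_phase_times(cumsum(c(0.5, 1.2, 0.7, 1.9, 3.2, 2.1, 1.5, 1.5)))
  avg <- average_tug_trials(list(a, b))
  expect_equal(avg$duration, (a$duration + b$duration) / 2)
  expect_equal(average_tug_trials(list(a))$duration, a$duration)
  expect_error(average_tug_trials(list()), class = "pdgait_precondition_error")
})

test_that("detection is invariant to rigid translation along the walkway", {
  sim <- simulate_tug_trajectory(seed = 12, noise_sd = 0)
  ev0 <- detect_tug_events(sim$trial)
  shifted <- sim$trial
  shifted$data$com_x <- shifted$data$com_x + 3.7
  ev1 <- detect_tug_events(shifted)
  expect_equal(ev1$times$time, ev0$times$time, tolerance = 1e-9)

  # height offsets leave every baseline-relative event unchanged; the sitting
  # threshold is an absolute fraction of standing height by rule, so the two
  # sitting events may shift slightly
  shifted$data$com_z <- shifted$data$com_z + 0.25
  ev2 <- detect_tug_events(shifted)
  keep <- !ev2$times$event %in% c("sit_begin", "sit_end")
  expect_equal(ev2$times$time[keep], ev0$times$time[keep], tolerance = 1e-9)
})

test_that("randomized noise-free trials recover programmed durations", {
  set.seed(41)
  for (k in 1:15) {
    durs <- c(1.13, 0.59, 1.73, 2.98, 1.89, 1.32, 1.33) *
      runif(7, 0.8, 1.2)
    sim <- simulate_tug_trajectory(durations = durs, noise_sd = 0,
                                   seed = 1000 + k)
    ph <- compute_phase_times(detect_tug_events(sim$trial))
    expect_lt(max(abs(ph$duration - sim$phases$duration)), 2 / 120 + 1e-9)
  }
})

test_that("infeasible TUG geometry raises parameter errors", {
  expect_error(
    simulate_tug_trajectory(durations = c(1.13, 0.59, 0.1, 2.98, 1.89,
                                          1.32, 1.33), walk_speed = 1),
    class = "pdgait_param_error")
  expect_error(
    simulate_tug_trajectory(durations = c(0.2, 0.1, 4, 2.98, 1.89,
                                          1.32, 1.33)),
    class = "pdgait_param_error")
  expect_error(simulate_tug_trajectory(seated_z = 1.0, standing_z = 0.9),
               class = "pdgait_param_error")
})
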