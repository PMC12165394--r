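test_that("generators are seed-deterministic", {
  a <- simulate_tug_trajectory(seed = 7, noise_sd = 0.002)
  b <- simulate_tug_trajectory(seed = 7, noise_sd = 0.002)
  expect_identical(a$trial$data, b$trial$data)
  expect_identical(a$events, b$events)

  w1 <- simulate_walking_trial(seed = 3, noise_sd = 0.002)
  w2 <- simulate_walking_trial(seed = 3, noise_sd = 0.002)
  expect_identical(w1$trial$data, w2$trial$data)

  c1 <- simulate_cohort(n = 19, seed = 9)
  c2 <- simulate_cohort(n = 19, seed = 9)
  expect_identical(c1$cohort, c2$cohort)
})

test_that("walking simulator realizes its programmed double support and symmetry", {
  sim <- simulate_walking_trial(seed = 2, double_support = 0.34)
  ev <- sim$events
  lstr <- ev$time[ev$side == "L" & ev$event == "strike"]
  roff <- ev$time[ev$side == "R" & ev$event == "off"]
  nxt <- vapply(lstr, function(s) {
    cand <- roff[roff >= s]
    if (length(cand)) cand[1] - s else NA_real_
  }, numeric(1))
  expect_equal(stats::median(nxt, na.rm = TRUE), 0.17, tolerance = 1e-9)

  sym <- simulate_walking_trial(seed = 2, shoulder_rom_L = 20,
                                shoulder_rom_R = 20)
  panel <- suppressMessages(summarize_walking_trial(sym$trial))
  expect_lt(panel$shoulder_symmetry, 0.05)
})

test_that("walking simulator rejects an infeasible double support", {
  expect_error(simulate_walking_trial(velocity = 1.3, stride_length = 1.3,
                                      double_support = 1.1),
               class = "pdgait_param_error")
})

test_that("cohort margins match their programmed moments", {
  sim <- suppressMessages(simulate_cohort(n = 4000, seed = 123))
  co <- sim$cohort
  marg <- default_cohort_marginals()
  for (v in c("working_memory", "velocity_dt", "response_inhibition")) {
    m <- marg$mean[marg$variable == v]
    s <- marg$sd[marg$variable == v]
    expect_lt(abs(mean(co[[v]]) - m) / s, 0.1)
    expect_lt(abs(sd(co[[v]]) - s) / s, 0.1)
  }
  # lognormal-tagged margins carry positive skew
  ri <- co$response_inhibition
  skew <- mean(((ri - mean(ri)) / sd(ri))^3)
  expect_gt(skew, 0.5)
})

test_that("an identity correlation target yields near-independent columns", {
  vars <- default_cohort_marginals()$variable
  sim <- simulate_cohort(n = 2000, marginals = gaussian_marginals(),
                         target_corr = identity_corr(vars), seed = 42)
  R <- cor(as.matrix(sim$cohort[vars]))
  expect_lt(max(abs(R[upper.tri(R)])), 0.08)
})

test_that("default correlation targets require and receive a PSD repair", {
  expect_message(sim <- simulate_cohort(n = 50, seed = 77),
                 class = "pdgait_log")
  expect_true(sim$truth$repaired)
  ev <- eigen(sim$truth$sampling_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # the printed targets are strongly non-PSD jointly, so the repair shrinks
  # them; signs and a substantial share of the magnitude must survive
  strong <- sim$truth$sampling_corr["working_memory",
                                    c("velocity_dt", "tug_walk2")]
  expect_gt(strong[["velocity_dt"]], 0.3)
  expect_lt(strong[["tug_walk2"]], -0.3)
})

test_that("small default cohorts sit near the programmed means", {
  sim <- suppressMessages(simulate_cohort(n = 19, seed = 8))
  marg <- default_cohort_marginals()
  for (j in seq_len(nrow(marg))) {
    v <- marg$variable[j]
    expect_lt(abs(mean(sim$cohort[[v]]) - marg$mean[j]),
              3 * marg$sd[j] / sqrt(19) + 0.35 * marg$sd[j])
  }
})
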