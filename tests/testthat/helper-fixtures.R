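# fixtures built in code: tiny trials, hand-laid gait events, marginals

make_com_trial <- function(x, z = NULL, rate_hz = 120, condition = "TUG",
                           y = NULL) {
  n <- length(x)
  trial_recording(
    tibble::tibble(
      t = (seq_len(n) - 1) / rate_hz,
      com_x = x,
      com_y = y %||% rep(0, n),
      com_z = z %||% rep(0.9, n)
    ),
    condition = condition, rate_hz = rate_hz
  )
}

# a gait_events tibble laid out by hand (times in s)
make_gait_events <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(side = r[[1]], event = r[[2]], time = as.numeric(r[[3]]))
  }))
  out <- dplyr::arrange(out, time)
  class(out) <- c("gait_events", class(out))
  out
}

gaussian_marginals <- function() {
  dplyr::mutate(default_cohort_marginals(), shape = "gaussian")
}

identity_corr <- function(vars) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  R
}

# amplitude of the Fourier component at f_hz for a series sampled at rate_hz
fft_amplitude <- function(x, f_hz, rate_hz) {
  n <- length(x)
  k <- round(f_hz * n / rate_hz)
  2 * Mod(fft(x)[k + 1]) / n
}
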