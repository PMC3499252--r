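#' Configuration for a synthetic spicule-thrust trace
#'
#' Parameters of an oscillatory intensity-variability trace emulating the
#' 7-11 Hz spicule thrusting a male performs against the vulval slit. Each
#' cycle contributes a raised-cosine deflection of half-width a quarter
#' period (50% duty cycle, so the trace median equals the baseline), with
#' optional per-cycle timing jitter and cycle dropouts.
#'
#' @param frequency thrust frequency in Hz (> 0).
#' @param duration bout duration in seconds; prodding bouts run uninterrupted
#'   for roughly 6-10 s.
#' @param sample_rate samples per second; must exceed twice the frequency.
#' @param amplitude_pct peak height above baseline, percent of baseline.
#' @param jitter_sd SD of per-cycle timing jitter (s).
#' @param dropout_prob probability that a cycle is skipped.
#' @param noise_pct additive Gaussian noise SD, percent of baseline.
#' @param baseline resting trace level (AU).
#' @param seed integer seed.
#' @return An object of class `thrust_sim_config`.
#' @export
thrust_sim_config <- function(frequency,
                              duration,
                              sample_rate = 35,
                              amplitude_pct = 10,
                              jitter_sd = 0.005,
                              dropout_prob = 0,
                              noise_pct = 0.5,
                              baseline = 100,
                              seed) {
  check_scalar(frequency, "frequency", min = 0, strict_min = TRUE)
  check_scalar(duration, "duration", min = 0, strict_min = TRUE)
  check_scalar(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  if (sample_rate <= 2 * frequency)
    stopf("sample_rate (%g) must exceed twice the thrust frequency (%g Hz) to avoid aliasing",
          sample_rate, frequency)
  check_scalar(amplitude_pct, "amplitude_pct", min = 0)
  check_scalar(jitter_sd, "jitter_sd", min = 0)
  check_prob(dropout_prob, "dropout_prob")
  check_scalar(noise_pct, "noise_pct", min = 0)
  check_scalar(baseline, "baseline", min = 0, strict_min = TRUE)
  structure(list(
    frequency = frequency, duration = duration, sample_rate = sample_rate,
    amplitude_pct = amplitude_pct, jitter_sd = jitter_sd,
    dropout_prob = dropout_prob, noise_pct = noise_pct,
    baseline = baseline, seed = check_seed(seed)
  ), class = "thrust_sim_config")
}

#' Simulate an oscillatory spicule-thrust trace with ground truth
#'
#' @param config a [thrust_sim_config()].
#' @return A list with components:
#'   * `trace`: a [thrust_trace()] (times, sd_mpi in AU, normalized percent).
#'   * `deflection_times`: ground-truth times (s) of the non-dropped cycle
#'     peaks; with `amplitude_pct = 0` or `dropout_prob = 1` the trace is
#'     flat and this is empty.
#' @export
simulate_thrust_trace <- function(config) {
  if (!inherits(config, "thrust_sim_config"))
    stopf("`config` must be a thrust_sim_config")
  cf <- config
  period <- 1 / cf$frequency
  n_cycles <- floor(cf$duration * cf$frequency)
  ns <- floor(cf$duration * cf$sample_rate)
  times <- (seq_len(ns) - 1) / cf$sample_rate

  withr::with_seed(cf$seed, {
    centres <- (seq_len(n_cycles) - 0.5) * period
    if (cf$jitter_sd > 0)
      centres <- sort(centres + stats::rnorm(n_cycles, 0, cf$jitter_sd))
    kept <- stats::runif(n_cycles) >= cf$dropout_prob
    noise <- if (cf$noise_pct > 0)
      stats::rnorm(ns, 0, cf$baseline * cf$noise_pct / 100) else 0
  })
  centres <- pmin(pmax(centres, 0), cf$duration)

  half_width <- 0.25 * period
  y <- numeric(ns)
  if (cf$amplitude_pct > 0) {
    for (c0 in centres[kept]) {
      x <- times - c0
      inb <- abs(x) < half_width
      y[inb] <- y[inb] +
        (cf$amplitude_pct / 100) * cos(pi * x[inb] / (2 * half_width))
    }
  }
  sd_mpi <- cf$baseline * (1 + y) + noise

  truth <- if (cf$amplitude_pct > 0) centres[kept] else numeric()
  list(trace = thrust_trace(times, sd_mpi), deflection_times = truth)
}
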