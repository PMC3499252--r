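#' Configuration for a synthetic dual-channel imaging stack
#'
#' Describes a simulated two-channel (green calcium reporter / red reference)
#' time-lapse recording of fluorescent cells at the male tail. The green
#' channel carries multiplicative calcium transients on a baseline; the red
#' channel is calcium-insensitive but photobleaches with one-phase-decay
#' kinetics. Both channels share a per-frame multiplicative artifact series
#' emulating focusing, gross movement, muscle contraction and lamp flicker,
#' the non-interesting intensity changes that ratiometric correction is meant
#' to remove.
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_rate acquisition rate in frames per second.
#' @param image_size `c(height, width)` in pixels.
#' @param cell_positions list of `c(row, col)` disc centres (1-based); discs
#'   must lie fully inside the image and must not overlap.
#' @param cell_radius disc radius in pixels.
#' @param baseline_green,baseline_red resting cell intensities (AU) above
#'   background.
#' @param background_level uniform background intensity (AU).
#' @param transient_schedule list of `c(onset_s, duration_s, amplitude)`
#'   calcium events shared by all cells; `amplitude` is the peak fractional
#'   increase over the green baseline (0.5 = a 50% dF/F0 peak). Onsets must be
#'   positive (frame 0 defines F0) and events must not overlap.
#' @param red_bleach `c(plateau, span, rate)` of the red-channel one-phase
#'   decay: intensity `plateau + span * exp(-rate * t)` (AU, AU, 1/s).
#' @param green_bleach_rate exponential bleach rate of the green channel
#'   (1/s); the green reporter bleaches minimally so the default is 0.
#' @param artifact_series per-frame multiplicative factor (> 0) applied to
#'   both channels, or `NULL` to draw a smoothed random walk confined to
#'   roughly \[0.9, 1.1\], sized so the apparent percent change it induces
#'   relative to the first frame stays within the ~0-20% band measured in
#'   hyperpolarized-neuron control recordings.
#' @param noise_sd additive Gaussian pixel noise SD (AU); pixel values are
#'   truncated at 0.
#' @param seed integer seed; all randomness in [simulate_stack()] derives
#'   from it.
#'
#' @return An object of class `stack_sim_config`.
#' @seealso [simulate_stack()]
#' @export
stack_sim_config <- function(n_frames,
                             frame_rate = 30,
                             image_size = c(64, 64),
                             cell_positions = list(c(32, 32)),
                             cell_radius = 4,
                             baseline_green = 100,
                             baseline_red = 150,
                             background_level = 10,
                             transient_schedule = list(),
                             red_bleach = c(plateau = 90, span = 60, rate = 0.2),
                             green_bleach_rate = 0,
                             artifact_series = NULL,
                             noise_sd = 2,
                             seed) {
  check_scalar(n_frames, "n_frames", min = 2)
  check_scalar(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  stopifnot(length(image_size) == 2L, all(image_size >= 1))
  check_scalar(cell_radius, "cell_radius", min = 1)
  check_scalar(baseline_green, "baseline_green", min = 0)
  check_scalar(baseline_red, "baseline_red", min = 0)
  check_scalar(background_level, "background_level", min = 0)
  check_scalar(green_bleach_rate, "green_bleach_rate", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 0)
  if (length(red_bleach) != 3L || any(red_bleach < 0))
    stopf("`red_bleach` must be c(plateau, span, rate), all >= 0")
  names(red_bleach) <- c("plateau", "span", "rate")

  n_frames <- as.integer(n_frames)
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])

  for (p in cell_positions) {
    if (length(p) != 2L) stopf("each cell position must be c(row, col)")
    if (p[1] - cell_radius < 1 || p[1] + cell_radius > h ||
        p[2] - cell_radius < 1 || p[2] + cell_radius > w)
      stopf("cell at (%g, %g) with radius %g falls outside the %d x %d image",
            p[1], p[2], cell_radius, h, w)
  }
  if (length(cell_positions) > 1L) {
    ctr <- do.call(rbind, cell_positions)
    d <- stats::dist(ctr)
    if (any(d < 2 * cell_radius))
      stopf("cell discs overlap (centre distance < 2 * cell_radius)")
  }

  times <- (seq_len(n_frames) - 1) / frame_rate
  for (ev in transient_schedule) {
    if (length(ev) != 3L) stopf("each transient must be c(onset, duration, amplitude)")
    if (ev[1] <= 0) stopf("transient onsets must be > 0 (frame 0 defines F0)")
    if (ev[2] <= 0) stopf("transient durations must be > 0")
    if (ev[3] < 0) stopf("transient amplitudes must be >= 0")
  }
  if (length(transient_schedule) > 1L) {
    on <- vapply(transient_schedule, `[`, 0, 1)
    off <- on + vapply(transient_schedule, `[`, 0, 2)
    o <- order(on)
    if (any(on[o][-1] < off[o][-length(off)]))
      stopf("transients must not overlap")
  }
  if (!is.null(artifact_series)) {
    if (length(artifact_series) != n_frames)
      stopf("`artifact_series` must have one factor per frame (%d)", n_frames)
    if (any(artifact_series <= 0)) stopf("artifact factors must be > 0")
  }

  structure(list(
    n_frames = n_frames, frame_rate = frame_rate, image_size = c(h, w),
    cell_positions = cell_positions, cell_radius = cell_radius,
    baseline_green = baseline_green, baseline_red = baseline_red,
    background_level = background_level,
    transient_schedule = transient_schedule, red_bleach = red_bleach,
    green_bleach_rate = green_bleach_rate, artifact_series = artifact_series,
    noise_sd = noise_sd, seed = check_seed(seed), times = times
  ), class = "stack_sim_config")
}

# Transient profile on the frame-time grid: linear rise over the first 20% of
# the event, exponential fall (tau = duration/4) over the rest. Peak value is
# exactly the scheduled amplitude, so 100 * profile is the true percent dF/F0.
transient_profile <- function(times, schedule) {
  tr <- numeric(length(times))
  for (ev in schedule) {
    onset <- ev[1]; dur <- ev[2]; amp <- ev[3]
    x <- times - onset
    rise_t <- 0.2 * dur
    in_rise <- x >= 0 & x < rise_t
    in_fall <- x >= rise_t & x <= dur
    tr[in_rise] <- tr[in_rise] + amp * x[in_rise] / rise_t
    tr[in_fall] <- tr[in_fall] + amp * exp(-(x[in_fall] - rise_t) / (dur / 4))
  }
  tr
}

# Frame-scale shared fluctuations squashed via tanh into roughly
# [0.9, 1.1]; emulates the artifacts ratiometric correction removes —
# mercury-arc lamp flicker, focus wobble, muscle-contraction shifts — which
# act on the timescale of single frames because focus and stage position
# are actively corrected throughout a recording. Slow focus drift is
# deliberately absent from the default: it is degenerate with the
# photobleaching decay, no red-referenced correction can separate the two,
# and users who want that failure mode can pass their own artifact_series.
# The squash is sized so the apparent percent change the artifact induces
# stays within the ~0-20% band measured in hyperpolarized-neuron controls.
artifact_walk <- function(n_frames, frame_rate) {
  1 + 0.1 * tanh(stats::rnorm(n_frames, 0, 0.5))
}

disc_mask <- function(h, w, centre, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - centre[1])^2 + (cols - centre[2])^2 <= radius^2
}

#' Simulate a dual-channel calcium-imaging stack with known ground truth
#'
#' Renders cells as filled discs. At a green-channel cell pixel the intensity
#' is `baseline_green * (1 + transient(t)) * exp(-green_bleach_rate * t) *
#' artifact(t) + background + noise`; at a red-channel cell pixel it is
#' `(plateau + span * exp(-rate * t)) * artifact(t) + background + noise`.
#' Background pixels carry `background + noise` only. Output is bit-identical
#' for a fixed config (the seed is part of the config).
#'
#' @param config a [stack_sim_config()].
#' @return A list with components:
#'   * `stack`: a `dual_channel_stack` — `data` array of dimension
#'     frames x height x width x 2 (channel 1 = green, channel 2 = red),
#'     `times`, `frame_rate`.
#'   * `truth`: a `stack_ground_truth` — `true_dff` (cells x frames matrix of
#'     percent dF/F0, first frame 0), `transient_times`, `artifact_series`,
#'     `bleach_params`, `cell_positions`, `cell_radius`.
#' @export
simulate_stack <- function(config) {
  if (!inherits(config, "stack_sim_config"))
    stopf("`config` must be a stack_sim_config")
  cf <- config
  nf <- cf$n_frames; h <- cf$image_size[1]; w <- cf$image_size[2]
  t <- cf$times

  withr::with_seed(cf$seed, {
    artifact <- cf$artifact_series %||% artifact_walk(nf, cf$frame_rate)
    tr <- transient_profile(t, cf$transient_schedule)
    green_cell <- cf$baseline_green * (1 + tr) *
      exp(-cf$green_bleach_rate * t) * artifact
    red_cell <- (cf$red_bleach[["plateau"]] +
                   cf$red_bleach[["span"]] * exp(-cf$red_bleach[["rate"]] * t)) *
      artifact

    masks <- lapply(cf$cell_positions, function(p)
      disc_mask(h, w, p, cf$cell_radius))

    data <- array(cf$background_level, dim = c(nf, h, w, 2))
    for (f in seq_len(nf)) {
      g <- matrix(cf$background_level, h, w)
      r <- matrix(cf$background_level, h, w)
      for (m in masks) {
        g[m] <- green_cell[f] + cf$background_level
        r[m] <- red_cell[f] + cf$background_level
      }
      data[f, , , 1] <- g
      data[f, , , 2] <- r
    }
    if (cf$noise_sd > 0) {
      data <- data + stats::rnorm(length(data), 0, cf$noise_sd)
      data[data < 0] <- 0
    }
  })

  true_dff <- matrix(100 * tr, nrow = length(cf$cell_positions),
                     ncol = nf, byrow = TRUE)
  stack <- structure(list(data = data, times = t, frame_rate = cf$frame_rate),
                     class = "dual_channel_stack")
  truth <- structure(list(
    true_dff = true_dff,
    transient_times = lapply(cf$transient_schedule, function(ev) ev[1:2]),
    artifact_series = artifact,
    bleach_params = cf$red_bleach,
    cell_positions = cf$cell_positions,
    cell_radius = cf$cell_radius
  ), class = "stack_ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.dual_channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dual_channel_stack> %d frames, %d x %d px, 2 channels, %.3g fps\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}
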