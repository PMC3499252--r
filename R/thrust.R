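#' Intensity-variability (SD of MPI) trace over a spicule ROI
#'
#' For a rectangular ROI drawn over the spicule region, the per-frame
#' population standard deviation of the pixel intensities inside the ROI is
#' an oscillation readout: spicule movement changes the pixel mix and so the
#' within-ROI spread. The trace is normalized as percent deviation from a
#' baseline (the bout median by default, which resists contamination by the
#' deflection peaks themselves).
#'
#' @param stack a `dual_channel_stack` or single-channel stack.
#' @param roi a [roi_track()]; ROI area must be at least 2 px.
#' @return A [thrust_trace()].
#' @export
sd_trace <- function(stack, roi) {
  d <- stack_dims(stack)
  rects <- roi_rects_for(roi, d$n_frames, d$image_size)
  if (any(rects[, 3] * rects[, 4] < 2))
    stopf("spicule ROI area must be >= 2 px")
  sd_mpi <- vapply(seq_len(d$n_frames), function(f) {
    r <- rects[f, ]
    m <- stack_frame_matrix(stack, f, roi$channel)
    px <- m[(r[1] + 1):(r[1] + r[3]), (r[2] + 1):(r[2] + r[4])]
    sqrt(mean((px - mean(px))^2))  # population SD
  }, 0)
  thrust_trace(stack$times, sd_mpi)
}

#' Construct a thrust trace
#'
#' @param times sample times (s), sampled at roughly 35 frames/s in the
#'   source recordings; the window should cover a single uninterrupted
#'   prodding bout (typically 6-10 s).
#' @param sd_mpi per-frame SD of pixel intensity within the spicule ROI (AU).
#' @param baseline `"median"` (default) or `"mean"` reference level for the
#'   percent normalization.
#' @return A `thrust_trace`: `times`, `sd_mpi`, `normalized_pct`, `baseline`.
#' @export
thrust_trace <- function(times, sd_mpi, baseline = c("median", "mean")) {
  baseline <- match.arg(baseline)
  if (length(times) != length(sd_mpi)) stopf("times and sd_mpi lengths differ")
  b <- if (baseline == "median") stats::median(sd_mpi) else mean(sd_mpi)
  if (b <= 0) b <- 1  # degenerate all-zero trace; keeps normalization defined
  structure(list(times = times, sd_mpi = sd_mpi,
                 normalized_pct = 100 * (sd_mpi - b) / b,
                 baseline = b),
            class = "thrust_trace")
}

#' Detect spicule deflections in a thrust trace
#'
#' One deflection is scored per oscillation whose peak-to-baseline amplitude
#' exceeds the threshold (default 5% — smaller oscillations are not
#' attributed to spicule deflections). Because a 7-11 Hz cycle holds only
#' 3-5 samples at ~35 frames/s, the sampled maximum can understate the
#' continuous oscillation amplitude by up to half; the trace is therefore
#' upsampled by band-limited cubic-spline interpolation before peak picking,
#' the threshold is applied to interpolated peak heights, and a refractory
#' window suppresses double counting within one peak.
#'
#' @param trace a [thrust_trace()] covering at least 1 s.
#' @param amplitude_threshold_pct percent threshold (> 0, default 5).
#' @param refractory_s minimum separation between deflections (s).
#' @param upsample integer interpolation factor (1 disables upsampling).
#' @return A [deflection_set()].
#' @export
detect_deflections <- function(trace, amplitude_threshold_pct = 5,
                               refractory_s = 0.03, upsample = 8L) {
  if (!inherits(trace, "thrust_trace")) stopf("`trace` must be a thrust_trace")
  if (amplitude_threshold_pct <= 0) stopf("threshold must be > 0")
  span <- diff(range(trace$times))
  if (span < 1) stopf("trace spans %.2f s; need at least 1 s of bout", span)

  if (upsample > 1L) {
    fine <- stats::spline(trace$times, trace$normalized_pct,
                          n = upsample * length(trace$times))
    tt <- fine$x; x <- fine$y
  } else {
    tt <- trace$times; x <- trace$normalized_pct
  }
  dt <- stats::median(diff(tt))
  min_dist <- max(1L, as.integer(round(refractory_s / dt)))
  pk <- pracma::findpeaks(x, minpeakheight = amplitude_threshold_pct,
                          minpeakdistance = min_dist)
  if (is.null(pk)) return(deflection_set(numeric()))
  deflection_set(sort(tt[pk[, 2]]))
}

#' Construct a deflection set from detected thrust times
#'
#' @param deflection_times strictly increasing deflection times (s).
#' @return A `deflection_set`: `deflection_times`, `intervals` (successive
#'   differences, s), `mean_freq` (`(count - 1) / (last - first)`, Hz),
#'   `interval_sd` (s), `n`.
#' @export
deflection_set <- function(deflection_times) {
  intervals <- if (length(deflection_times) >= 2) diff(deflection_times) else numeric()
  mean_freq <- if (length(deflection_times) >= 2)
    (length(deflection_times) - 1) /
      (deflection_times[length(deflection_times)] - deflection_times[1])
  else NA_real_
  structure(list(
    deflection_times = deflection_times,
    intervals = intervals,
    mean_freq = mean_freq,
    interval_sd = if (length(intervals) >= 2) stats::sd(intervals) else
      if (length(intervals) == 1) 0 else NA_real_,
    n = length(deflection_times)
  ), class = "deflection_set")
}

#' Summarize thrust rhythmicity across bouts
#'
#' One row per bout/animal with deflection count, mean frequency and the SD
#' of inter-thrust intervals; a higher interval SD operationalizes the less
#' rhythmic, more random runs of sustained and rapid shallow thrusts seen in
#' D2-like receptor mutants. The pooled interval distribution is attached for
#' group-level comparison.
#'
#' @param sets list of `deflection_set`s, one per bout.
#' @return A list: `summary` data frame (`animal`, `n_deflections`,
#'   `mean_freq_hz`, `mean_interval_s`, `interval_sd_s`) and
#'   `pooled_intervals` (numeric vector, s).
#' @export
rhythmicity_summary <- function(sets) {
  if (!length(sets))
    return(list(summary = data.frame(animal = character(),
                                     n_deflections = integer(),
                                     mean_freq_hz = numeric(),
                                     mean_interval_s = numeric(),
                                     interval_sd_s = numeric()),
                pooled_intervals = numeric()))
  ids <- names(sets) %||% as.character(seq_along(sets))
  if (is.null(names(sets))) ids <- as.character(seq_along(sets))
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(animal = ids[i], n_deflections = s$n,
               mean_freq_hz = s$mean_freq,
               mean_interval_s = if (length(s$intervals)) mean(s$intervals) else NA_real_,
               interval_sd_s = s$interval_sd,
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows),
       pooled_intervals = unlist(lapply(sets, `[[`, "intervals"), use.names = FALSE))
}
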