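#' Red-referenced correction and percent dF/F0
#'
#' For each frame the background-subtracted red MPI is divided by the fitted
#' reference to give a dimensionless correction value
#' `c(t) = red(t) / Rhat(t)` that captures the shared, non-interesting
#' intensity changes (focusing, movement, lamp flicker). The background-
#' subtracted green MPI is divided by `c(t)` (equivalently multiplied by its
#' inverse) so that remaining changes reflect calcium transients, and the
#' percent change is computed against the first frame:
#' `dff_pct(t) = 100 * (G_corr(t) - G_corr(0)) / G_corr(0)`.
#'
#' @param green,red equal-length background-subtracted MPI series (AU).
#' @param fit a [fit_reference()] result for `red`.
#' @return A `corrected_trace`: `correction`, `green_corrected`, `f0`,
#'   `dff_pct` (first entry exactly 0).
#' @export
correct_and_dff <- function(green, red, fit) {
  if (length(green) != length(red))
    stopf("green (%d) and red (%d) series lengths differ",
          length(green), length(red))
  if (!inherits(fit, "reference_fit")) stopf("`fit` must be a reference_fit")
  if (length(fit$fitted) != length(red))
    stopf("reference fit length (%d) does not match series length (%d)",
          length(fit$fitted), length(red))
  correction <- red / fit$fitted
  if (any(correction <= 0))
    stopf("correction value <= 0 at frame %d", which(correction <= 0)[1])
  g <- green / correction
  f0 <- g[1]
  if (f0 == 0) stopf("F0 (corrected MPI at frame 1) is zero")
  structure(list(correction = correction, green_corrected = g, f0 = f0,
                 dff_pct = 100 * (g - f0) / f0),
            class = "corrected_trace")
}

#' Call calcium events above the motion-artifact band
#'
#' Focusing/motion artifacts move the apparent percent dF/F0 by up to about
#' 20%, a band established with hyperpolarized-neuron control recordings;
#' only excursions above the band are classified as calcium events. Events
#' are contiguous runs of `dff_pct > band_pct`; runs separated by fewer than
#' `min_gap` frames are merged, and runs shorter than `min_len` frames are
#' discarded.
#'
#' @param trace a `corrected_trace` or a numeric percent dF/F0 series.
#' @param band_pct artifact-band threshold in percent (default 20).
#' @param min_gap merge runs separated by fewer than this many frames.
#' @param min_len minimum event duration in frames.
#' @return A data frame (class `event_call_set`) with one row per event:
#'   `onset`, `offset` (frame indices), `peak_frame`, `peak_pct`. Attribute
#'   `band_pct` records the threshold.
#' @export
call_events <- function(trace, band_pct = 20, min_gap = 3, min_len = 2) {
  if (band_pct <= 0) stopf("`band_pct` must be > 0")
  dff <- if (inherits(trace, "corrected_trace")) trace$dff_pct else as.numeric(trace)
  empty <- data.frame(onset = integer(), offset = integer(),
                      peak_frame = integer(), peak_pct = numeric())
  if (!length(dff))
    return(structure(empty, band_pct = band_pct, class = c("event_call_set", "data.frame")))

  above <- dff > band_pct
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < min_gap) merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  if (nrow(runs))
    runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  if (!nrow(runs))
    return(structure(empty, band_pct = band_pct, class = c("event_call_set", "data.frame")))

  peaks <- vapply(seq_len(nrow(runs)), function(i) {
    w <- runs$start[i]:runs$end[i]
    w[which.max(dff[w])]
  }, 0L)
  out <- data.frame(onset = runs$start, offset = runs$end,
                    peak_frame = peaks, peak_pct = dff[peaks])
  structure(out, band_pct = band_pct, class = c("event_call_set", "data.frame"))
}
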