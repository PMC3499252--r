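channel_index <- function(channel) if (channel == "green") 1L else 2L

stack_frame_matrix <- function(stack, f, channel) {
  if (length(dim(stack$data)) == 4L)
    stack$data[f, , , channel_index(channel)]
  else
    stack$data[f, , ]  # single-channel stack; channel ignored
}

stack_dims <- function(stack) {
  d <- dim(stack$data)
  list(n_frames = d[1], image_size = d[2:3])
}

#' Mean pixel intensity of an ROI across frames
#'
#' The value at frame f is the arithmetic mean of the pixel intensities
#' inside the ROI's rectangle for that frame, on the ROI's channel.
#' Intensities are handled as floating point regardless of source bit depth.
#'
#' @param stack a `dual_channel_stack` (or a single-channel stack whose
#'   `data` is a frames x height x width array).
#' @param roi a [roi_track()].
#' @return Numeric vector, one MPI value (AU) per frame.
#' @export
extract_mpi <- function(stack, roi) {
  d <- stack_dims(stack)
  rects <- roi_rects_for(roi, d$n_frames, d$image_size)
  vapply(seq_len(d$n_frames), function(f) {
    r <- rects[f, ]
    m <- stack_frame_matrix(stack, f, roi$channel)
    mean(m[(r[1] + 1):(r[1] + r[3]), (r[2] + 1):(r[2] + r[4])])
  }, 0)
}

#' Subtract a background trace from a cell trace
#'
#' Elementwise cell minus background MPI. Values are left signed unless
#' `clip = TRUE`.
#'
#' @param cell,background equal-length numeric series (AU).
#' @param clip clamp negative results at 0 (default off).
#' @return Numeric series.
#' @export
subtract_background <- function(cell, background, clip = FALSE) {
  if (length(cell) != length(background))
    stopf("cell (%d) and background (%d) series lengths differ",
          length(cell), length(background))
  out <- cell - background
  if (clip) out[out < 0] <- 0
  out
}

#' Extract background-subtracted fluorescence traces from a stack
#'
#' Measures the MPI of every ROI in every frame, pairs each cell ROI with its
#' same-channel background ROI ([pair_rois()]), and subtracts background
#' framewise.
#'
#' @param stack a `dual_channel_stack`.
#' @param tracks list of [roi_track()] objects.
#' @return A `fluorescence_traces` list: `times`, `raw` (named list of MPI
#'   series for all ROIs), `bg_subtracted` (named list for cell ROIs),
#'   `channel` (named channel per cell ROI), `pairing`.
#' @export
extract_traces <- function(stack, tracks) {
  ids <- vapply(tracks, `[[`, "", "roi_id")
  names(tracks) <- ids
  raw <- lapply(tracks, function(tr) extract_mpi(stack, tr))
  pairing <- pair_rois(tracks)
  bg_sub <- lapply(names(pairing), function(id)
    subtract_background(raw[[id]], raw[[pairing[[id]]]]))
  names(bg_sub) <- names(pairing)
  structure(list(
    times = stack$times,
    raw = raw,
    bg_subtracted = bg_sub,
    channel = vapply(tracks[names(pairing)], `[[`, "", "channel"),
    pairing = pairing
  ), class = "fluorescence_traces")
}

#' Write / read MPI traces as tidy CSV
#'
#' Long format with columns `frame, time_s, roi_id, mpi`.
#'
#' @param traces a `fluorescence_traces` object (raw series are written).
#' @param path CSV file path.
#' @return `read_trace_csv` returns the data frame.
#' @export
write_trace_csv <- function(traces, path) {
  rows <- lapply(names(traces$raw), function(id)
    data.frame(frame = seq_along(traces$times), time_s = traces$times,
               roi_id = id, mpi = traces$raw[[id]], stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
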