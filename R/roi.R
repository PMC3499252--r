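#' Define a per-frame rectangular ROI track
#'
#' A region of interest over a cell, a background patch or the spicule,
#' positioned per frame (ROIs are repositioned manually per frame in the
#' original workflow; positions are an input here, no tracking is done).
#' Rectangles are axis-aligned, 0-based, half-open `[row0, row0 + height) x
#' [col0, col0 + width)`, and must keep the same area across frames (ROIs of
#' equal areas).
#'
#' @param roi_id identifier.
#' @param role `"cell"` or `"background"`.
#' @param channel `"green"` or `"red"`.
#' @param rects a length-4 vector `c(row0, col0, height, width)` used for
#'   every frame, or a matrix with one such row per frame.
#' @param n_frames frame count used to recycle a single rect; ignored when
#'   `rects` is a matrix.
#' @return An object of class `roi_track`.
#' @export
roi_track <- function(roi_id, role = c("cell", "background"),
                      channel = c("green", "red"), rects, n_frames = NULL) {
  role <- match.arg(role)
  channel <- match.arg(channel)
  if (is.null(dim(rects))) {
    if (length(rects) != 4L) stopf("`rects` must be c(row0, col0, height, width)")
    n <- n_frames %||% 1L
    rects <- matrix(rects, nrow = n, ncol = 4, byrow = TRUE)
  }
  rects <- as.matrix(rects)
  if (ncol(rects) != 4L) stopf("`rects` must have 4 columns")
  dimnames(rects) <- list(NULL, c("row0", "col0", "height", "width"))
  if (any(rects[, "height"] < 1) || any(rects[, "width"] < 1))
    stopf("ROI `%s`: rect area must be > 0", roi_id)
  areas <- rects[, "height"] * rects[, "width"]
  if (length(unique(areas)) != 1L)
    stopf("ROI `%s`: rect area must be equal across frames", roi_id)
  structure(list(roi_id = as.character(roi_id), role = role,
                 channel = channel, rects = rects),
            class = "roi_track")
}

# expand/validate a track against a stack's frame count and image size
roi_rects_for <- function(roi, n_frames, image_size) {
  rects <- roi$rects
  if (nrow(rects) == 1L && n_frames > 1L)
    rects <- rects[rep(1L, n_frames), , drop = FALSE]
  if (nrow(rects) != n_frames)
    stopf("ROI `%s`: %d rects for %d frames", roi$roi_id, nrow(rects), n_frames)
  bad <- which(rects[, 1] < 0 | rects[, 2] < 0 |
                 rects[, 1] + rects[, 3] > image_size[1] |
                 rects[, 2] + rects[, 4] > image_size[2])
  if (length(bad))
    stopf("ROI `%s`: rect out of image bounds at frame %d", roi$roi_id, bad[1])
  rects
}

#' Pair each cell ROI with a same-channel background ROI
#'
#' Background subtraction requires, for every cell ROI, a background ROI on
#' the same emission channel. When several candidates exist the one nearest
#' by id is chosen (numeric distance when ids are numeric-like, otherwise the
#' first in sort order).
#'
#' @param tracks list of [roi_track()] objects.
#' @return Named character vector mapping each cell `roi_id` to its
#'   background `roi_id`.
#' @export
pair_rois <- function(tracks) {
  roles <- vapply(tracks, `[[`, "", "role")
  channels <- vapply(tracks, `[[`, "", "channel")
  ids <- vapply(tracks, `[[`, "", "roi_id")
  cells <- which(roles == "cell")
  pairing <- character(0)
  for (i in cells) {
    cand <- which(roles == "background" & channels == channels[i])
    if (!length(cand))
      stopf("no background ROI for channel `%s` (needed by cell `%s`)",
            channels[i], ids[i])
    if (length(cand) > 1L) {
      num <- suppressWarnings(as.numeric(ids[cand]))
      me <- suppressWarnings(as.numeric(ids[i]))
      cand <- if (!any(is.na(num)) && !is.na(me))
        cand[which.min(abs(num - me))] else cand[order(ids[cand])][1]
    }
    pairing[ids[i]] <- ids[cand]
  }
  pairing
}

#' Read / write ROI tracks as CSV
#'
#' Columns: `roi_id, role, channel, frame, row0, col0, height, width`.
#' Coordinates are 0-based with half-open extents; `frame` is 1-based.
#'
#' @param path CSV file path.
#' @param tracks list of [roi_track()] objects (for writing).
#' @return `read_roi_csv` returns a list of [roi_track()]s.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "role", "channel", "frame", "row0", "col0", "height", "width")
  if (!all(need %in% names(df)))
    stopf("ROI CSV must have columns: %s", paste(need, collapse = ", "))
  lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$frame), ]
    roi_track(d$roi_id[1], d$role[1], d$channel[1],
              as.matrix(d[, c("row0", "col0", "height", "width")]))
  })
}

#' @rdname read_roi_csv
#' @export
write_roi_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(roi_id = tr$roi_id, role = tr$role, channel = tr$channel,
               frame = seq_len(nrow(tr$rects)), tr$rects,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
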