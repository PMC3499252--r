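#' Write / read a dual-channel stack as multi-page TIFF
#'
#' Pages are frame-major with alternating channels: page `2f - 1` is frame
#' `f` green, page `2f` is frame `f` red. Intensities are stored as 32-bit
#' floats; because TIFF floats are confined to \[0, 1\], AU values are divided
#' by `scale` on write and multiplied back on read (use the same `scale` for
#' both directions).
#'
#' @param stack a `dual_channel_stack`.
#' @param path TIFF file path.
#' @param scale AU-per-unit scaling factor.
#' @param frame_rate frames per second to attach on read.
#' @return `read_stack_tiff` returns a `dual_channel_stack`.
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  d <- dim(stack$data)
  pages <- vector("list", 2L * d[1])
  for (f in seq_len(d[1])) {
    pages[[2L * f - 1L]] <- stack$data[f, , , 1] / scale
    pages[[2L * f]] <- stack$data[f, , , 2] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, frame_rate = 30, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L)
    stopf("expected an even page count (green/red per frame), got %d",
          length(pages))
  nf <- length(pages) %/% 2L
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, dim = c(nf, h, w, 2))
  for (f in seq_len(nf)) {
    data[f, , , 1] <- pages[[2L * f - 1L]] * scale
    data[f, , , 2] <- pages[[2L * f]] * scale
  }
  structure(list(data = data, times = (seq_len(nf) - 1) / frame_rate,
                 frame_rate = frame_rate),
            class = "dual_channel_stack")
}
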