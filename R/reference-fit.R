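#' Fit the red-channel reference line
#'
#' The background-subtracted red (calcium-insensitive) trace is summarized by
#' an arbitrary reference against which shared motion/illumination artifacts
#' are quantified: either a flat average line, or a one-phase decay
#' `plateau + span * exp(-rate * t)` when red-specific photobleaching makes a
#' flat reference inappropriate. `auto` fits the decay and falls back to the
#' mean when the fit fails, the fitted rate is not positive, or the decay does
#' not reduce the sum of squared residuals by at least `sse_margin` relative
#' to the mean line.
#'
#' Decay fitting is bounded least squares (plateau, span, rate all >= 0),
#' initialized at `plateau = min(red)`, `span = max - min`,
#' `rate = 1 / total duration`.
#'
#' @param red background-subtracted red MPI series (AU).
#' @param times frame times (s).
#' @param mode `"auto"`, `"mean"` or `"one_phase_decay"`.
#' @param sse_margin minimum relative SSE improvement that justifies the
#'   decay over the mean in `auto` mode.
#' @return A `reference_fit`: `mode` (resolved to `"mean"` or
#'   `"one_phase_decay"`), `plateau`, `span`, `rate`, `fitted` (per-frame
#'   reference), `residual_sse`.
#' @export
fit_reference <- function(red, times, mode = c("auto", "mean", "one_phase_decay"),
                          sse_margin = 0.05) {
  mode <- match.arg(mode)
  if (length(red) < 3L) stopf("need at least 3 frames to fit a reference")
  if (length(red) != length(times)) stopf("red and times lengths differ")
  if (any(!is.finite(red))) stopf("red series contains non-finite values")

  mean_fit <- new_reference_fit("mean", plateau = mean(red), span = 0, rate = 0,
                                fitted = rep(mean(red), length(red)), red = red)

  if (mode == "mean") return(check_reference_fit(mean_fit))

  decay_fit <- try(fit_one_phase_decay(red, times), silent = TRUE)

  if (mode == "one_phase_decay") {
    if (inherits(decay_fit, "try-error")) {
      if (stats::var(red) == 0)  # constant series: mean-equivalent decay
        return(check_reference_fit(new_reference_fit(
          "one_phase_decay", plateau = mean(red), span = 0, rate = 0,
          fitted = rep(mean(red), length(red)), red = red)))
      stopf("one-phase decay fit failed: %s", attr(decay_fit, "condition")$message)
    }
    return(check_reference_fit(decay_fit))
  }

  # auto
  if (inherits(decay_fit, "try-error") || decay_fit$rate <= 0 ||
      decay_fit$residual_sse > (1 - sse_margin) * mean_fit$residual_sse)
    check_reference_fit(mean_fit)
  else
    check_reference_fit(decay_fit)
}

new_reference_fit <- function(mode, plateau, span, rate, fitted, red) {
  structure(list(mode = mode, plateau = unname(plateau), span = unname(span),
                 rate = unname(rate), fitted = fitted,
                 residual_sse = sum((red - fitted)^2)),
            class = "reference_fit")
}

check_reference_fit <- function(fit) {
  if (any(fit$fitted <= 0))
    stopf("fitted reference is <= 0 at frame %d; correction undefined",
          which(fit$fitted <= 0)[1])
  fit
}

fit_one_phase_decay <- function(red, times) {
  if (stats::var(red) == 0)
    return(new_reference_fit("one_phase_decay", plateau = mean(red), span = 0,
                             rate = 0, fitted = red, red = red))
  t0 <- times - times[1]
  start <- list(plateau = min(red), span = max(red) - min(red),
                rate = 1 / diff(range(t0)))
  fit <- minpack.lm::nlsLM(
    red ~ plateau + span * exp(-rate * t0),
    start = start, lower = c(0, 0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- stats::coef(fit)
  fitted <- cf[["plateau"]] + cf[["span"]] * exp(-cf[["rate"]] * t0)
  new_reference_fit("one_phase_decay", plateau = cf[["plateau"]],
                    span = cf[["span"]], rate = cf[["rate"]],
                    fitted = fitted, red = red)
}

#' @export
print.reference_fit <- function(x, ...) {
  cat(sprintf("<reference_fit> mode=%s plateau=%.4g span=%.4g rate=%.4g /s SSE=%.4g\n",
              x$mode, x$plateau, x$span, x$rate, x$residual_sse))
  invisible(x)
}
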