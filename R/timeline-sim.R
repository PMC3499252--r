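#' Configuration for a synthetic mating timeline
#'
#' Parameters of a stochastic ethogram for one male paired with a paralyzed
#' hermaphrodite: alternating scanning and spicule-prodding bouts with
#' exponential durations, observation capped (120 s by default) or stopped at
#' the first successful penetration. A prodding bout is "ectopic" (occurs off
#' the vulva) with probability `p_ectopic`; ectopic bouts are recorded as
#' non-productive contact (`scanning` label) and can never penetrate. Raising
#' `p_ectopic` emulates the dopamine-deficient regime of precocious thrusts at
#' random locations on the mate.
#'
#' @param observation_cap observation window in seconds.
#' @param p_ectopic probability that a prodding bout occurs off-vulva.
#' @param mean_scan_bout,mean_prod_bout mean bout durations (s) of the
#'   exponential draws.
#' @param p_penetration_per_bout probability that an on-vulva prodding bout
#'   that completes within the window ends in full spicule insertion.
#' @param first_bout label of the first bout, `"scanning"` (default) or
#'   `"vulva_prodding"`.
#' @param seed integer seed.
#' @return An object of class `timeline_sim_config`.
#' @export
timeline_sim_config <- function(observation_cap = 120,
                                p_ectopic = 0.1,
                                mean_scan_bout = 10,
                                mean_prod_bout = 8,
                                p_penetration_per_bout = 0.3,
                                first_bout = c("scanning", "vulva_prodding"),
                                seed) {
  check_scalar(observation_cap, "observation_cap", min = 0, strict_min = TRUE)
  check_prob(p_ectopic, "p_ectopic")
  check_prob(p_penetration_per_bout, "p_penetration_per_bout")
  check_scalar(mean_scan_bout, "mean_scan_bout", min = 0, strict_min = TRUE)
  check_scalar(mean_prod_bout, "mean_prod_bout", min = 0, strict_min = TRUE)
  structure(list(
    observation_cap = observation_cap, p_ectopic = p_ectopic,
    mean_scan_bout = mean_scan_bout, mean_prod_bout = mean_prod_bout,
    p_penetration_per_bout = p_penetration_per_bout,
    first_bout = match.arg(first_bout), seed = check_seed(seed)
  ), class = "timeline_sim_config")
}

#' Simulate a labeled mating timeline
#'
#' Draws alternating scanning / prodding bouts until the observation cap or
#' the first penetration. Intervals are non-overlapping, ordered, and labeled
#' from `{scanning, vulva_prodding, insertion}`; a terminal `insertion`
#' interval (nominal 1 s) marks penetration, whose start time is the
#' penetration time.
#'
#' @param config a [timeline_sim_config()].
#' @return A [behavior_timeline()].
#' @export
simulate_timeline <- function(config) {
  if (!inherits(config, "timeline_sim_config"))
    stopf("`config` must be a timeline_sim_config")
  cf <- config
  cap <- cf$observation_cap

  withr::with_seed(cf$seed, {
    start <- numeric(); end <- numeric(); label <- character()
    t <- 0
    state <- cf$first_bout
    penetration <- NA_real_
    while (t < cap) {
      if (state == "scanning") {
        len <- stats::rexp(1, 1 / cf$mean_scan_bout)
        e <- min(t + len, cap)
        start <- c(start, t); end <- c(end, e); label <- c(label, "scanning")
        t <- e
        state <- "vulva_prodding"
      } else {
        len <- stats::rexp(1, 1 / cf$mean_prod_bout)
        ectopic <- stats::runif(1) < cf$p_ectopic
        e <- min(t + len, cap)
        lab <- if (ectopic) "scanning" else "vulva_prodding"
        start <- c(start, t); end <- c(end, e); label <- c(label, lab)
        penetrates <- !ectopic && e < cap &&
          stats::runif(1) < cf$p_penetration_per_bout
        t <- e
        if (penetrates) {
          penetration <- t
          start <- c(start, t); end <- c(end, t + 1)
          label <- c(label, "insertion")
          break
        }
        state <- "scanning"
      }
    }
  })

  behavior_timeline(data.frame(start = start, end = end, label = label,
                               stringsAsFactors = FALSE),
                    observation_cap = cap)
}
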