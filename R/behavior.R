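TIMELINE_LABELS <- c("off", "scanning", "vulva_prodding", "insertion")
CONTACT_LABELS <- c("scanning", "vulva_prodding")

#' Construct a labeled behavioral timeline
#'
#' Ordered, non-overlapping intervals describing one male's mating bout with
#' labels from `{off, scanning, vulva_prodding, insertion}`. `scanning`
#' covers any in-contact time not spent attempting insertion at the vulva
#' (including ectopic, off-vulva prodding); `vulva_prodding` is spicule
#' insertion attempts at the vulva; at most one `insertion` interval is
#' allowed and it must be terminal — its start is the penetration time.
#' Observation is capped (120 s by default) and stops at penetration.
#'
#' @param intervals data frame with columns `start`, `end`, `label`
#'   (seconds; `start < end`).
#' @param observation_cap observation window in seconds.
#' @return An object of class `behavior_timeline` (the interval data frame
#'   with attributes `observation_cap` and `penetration_time`).
#' @export
behavior_timeline <- function(intervals, observation_cap = 120) {
  need <- c("start", "end", "label")
  if (!all(need %in% names(intervals)))
    stopf("`intervals` must have columns start, end, label")
  iv <- intervals[order(intervals$start), need, drop = FALSE]
  if (!all(iv$label %in% TIMELINE_LABELS))
    stopf("labels must be in {%s}", paste(TIMELINE_LABELS, collapse = ", "))
  if (any(iv$start >= iv$end)) stopf("every interval needs start < end")
  if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-9))
    stopf("intervals must not overlap")
  ins <- which(iv$label == "insertion")
  if (length(ins) > 1L) stopf("at most one insertion interval is allowed")
  if (length(ins) == 1L && ins != nrow(iv))
    stopf("the insertion interval must be terminal")
  penetration <- if (length(ins)) iv$start[ins] else NA_real_
  structure(iv, observation_cap = observation_cap,
            penetration_time = penetration,
            class = c("behavior_timeline", "data.frame"))
}

# total duration of intervals with given labels, clipped to [0, t_end]
clipped_duration <- function(tl, labels, t_end) {
  iv <- tl[tl$label %in% labels, , drop = FALSE]
  if (!nrow(iv)) return(0)
  sum(pmax(0, pmin(iv$end, t_end) - pmin(iv$start, t_end)))
}

#' Efficiency of spicule insertion (E_SI)
#'
#' A single score ranking the spectrum of insertion performances observed in
#' the first 120 s of contact with a paralyzed mate. It combines (i) the
#' fraction of contact time spent attempting insertion at the vulva, (ii) a
#' penalty of one over the time spent in contact without attempting insertion
#' (scanning and ectopic prodding), and (iii) a bonus of the fraction of the
#' observation window remaining after a successful penetration:
#'
#' `E_SI = (t_prod / t_total) * (1 / max(t_nonprod, 1)) * (1 + bonus)`,
#' `bonus = 0` without penetration, else `(cap - t_pen) / cap`.
#'
#' The penalty denominator is clamped at 1 s: a male that prods immediately
#' on contact has zero non-productive time, and the clamp is the minimal rule
#' under which instant prodding with penetration ~1 s after contact scores
#' `1 * 1 * (1 + 119/120) = 1.99`, while 120 s of contact without any
#' insertion attempt scores 0. All durations are truncated at the cap before
#' any ratio is formed.
#'
#' @param timeline a [behavior_timeline()] with positive contact time.
#' @return An `esi_result` list: `t_prod`, `t_nonprod`, `t_total`,
#'   `penetrated`, `bonus`, `score`.
#' @export
compute_esi <- function(timeline) {
  if (!inherits(timeline, "behavior_timeline"))
    stopf("`timeline` must be a behavior_timeline")
  cap <- attr(timeline, "observation_cap")
  pen <- attr(timeline, "penetration_time")
  t_end <- if (is.na(pen)) cap else min(pen, cap)
  t_prod <- clipped_duration(timeline, "vulva_prodding", t_end)
  t_nonprod <- clipped_duration(timeline, "scanning", t_end)
  t_total <- t_prod + t_nonprod
  if (t_total <= 0) stopf("timeline has no contact time; E_SI undefined")
  penetrated <- !is.na(pen) && pen <= cap
  bonus <- if (penetrated) (cap - pen) / cap else 0
  score <- (t_prod / t_total) * (1 / max(t_nonprod, 1)) * (1 + bonus)
  structure(list(t_prod = t_prod, t_nonprod = t_nonprod, t_total = t_total,
                 penetrated = penetrated, bonus = bonus, score = score),
            class = "esi_result")
}

#' @export
print.esi_result <- function(x, ...) {
  cat(sprintf("E_SI = %.3g (prod %.3g s, non-prod %.3g s, %s)\n",
              x$score, x$t_prod, x$t_nonprod,
              if (x$penetrated) sprintf("penetrated, bonus %.3g", x$bonus)
              else "no penetration"))
  invisible(x)
}

#' In-contact length percentage (ICL%)
#'
#' Percent of the male body length in contact with the mate's cuticle, a
#' proxy for posture: lower values indicate a progressively arched posture.
#' Lengths come from skeletonized outline measurements supplied by the
#' analyst.
#'
#' @param contact_length length of the male outline touching the mate (px).
#' @param body_length total male body length (px, > 0).
#' @return Percentage, `100 * contact_length / body_length`.
#' @export
compute_icl <- function(contact_length, body_length) {
  if (any(body_length <= 0)) stopf("`body_length` must be > 0")
  if (any(contact_length < 0)) stopf("`contact_length` must be >= 0")
  if (any(contact_length > body_length))
    stopf("contact length exceeds body length")
  100 * contact_length / body_length
}

#' Vulva-contact and cumulative-contact metrics of a timeline
#'
#' Counts vulva-prodding bouts and their total duration, the mean in-contact
#' time separating successive prodding bouts (the interval between insertion
#' attempts), the cumulative time in contact, and the average duration of a
#' contact episode (maximal runs of in-contact intervals uninterrupted by
#' `off` time).
#'
#' @param timeline a [behavior_timeline()].
#' @return A `contact_metrics` list: `n_vulva_contacts`,
#'   `total_vulva_contact`, `mean_interval_between_attempts` (`NA` with < 2
#'   prodding bouts), `cumulative_contact`, `average_contact`, `n_contacts`.
#' @export
contact_metrics <- function(timeline) {
  if (!inherits(timeline, "behavior_timeline"))
    stopf("`timeline` must be a behavior_timeline")
  tl <- as.data.frame(timeline)
  prod <- tl[tl$label == "vulva_prodding", , drop = FALSE]
  contact <- tl[tl$label %in% CONTACT_LABELS, , drop = FALSE]

  # in-contact time separating successive prodding bouts
  gaps <- numeric()
  if (nrow(prod) >= 2L) {
    for (i in seq_len(nrow(prod) - 1L)) {
      lo <- prod$end[i]; hi <- prod$start[i + 1L]
      between <- pmax(0, pmin(contact$end, hi) - pmax(contact$start, lo))
      gaps <- c(gaps, sum(between))
    }
  }

  # contact episodes: maximal runs of contiguous in-contact intervals
  n_episodes <- 0L
  if (nrow(contact)) {
    breaks <- c(TRUE, contact$start[-1] > contact$end[-nrow(contact)] + 1e-9)
    n_episodes <- sum(breaks)
  }
  cumulative <- sum(contact$end - contact$start)

  structure(list(
    n_vulva_contacts = nrow(prod),
    total_vulva_contact = sum(prod$end - prod$start),
    mean_interval_between_attempts = if (length(gaps)) mean(gaps) else NA_real_,
    cumulative_contact = cumulative,
    average_contact = if (n_episodes) cumulative / n_episodes else 0,
    n_contacts = n_episodes
  ), class = "contact_metrics")
}

#' Distance traveled and velocity from a centroid track
#'
#' Converts per-frame centroid X/Y coordinates of a crawling male into the
#' distance traveled and a per-step velocity series.
#'
#' @param times strictly increasing frame times (s), length >= 2.
#' @param xy matrix or data frame of centroid coordinates (px), one row per
#'   frame.
#' @param px_per_mm pixel-to-millimetre scale.
#' @return A list: `distance_mm` (sum of Euclidean steps), `velocity_mm_s`
#'   (length `n - 1`), `mean_velocity_mm_s`.
#' @export
centroid_kinematics <- function(times, xy, px_per_mm = 1) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) stopf("need at least 2 frames of centroid positions")
  if (length(times) != nrow(xy)) stopf("times and xy lengths differ")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(!is.finite(xy))) stopf("centroid coordinates must be finite")
  steps <- sqrt(rowSums(diff(xy)^2)) / px_per_mm
  vel <- steps / diff(times)
  list(distance_mm = sum(steps), velocity_mm_s = vel,
       mean_velocity_mm_s = sum(steps) / (times[length(times)] - times[1]))
}

#' Fraction of potent males
#'
#' A male is potent if his mating plate contains cross-progeny; the
#' proportion and count feed downstream contingency tests.
#'
#' @param outcomes logical vector (or character `"potent"`/`"not_potent"`).
#' @return A list: `proportion`, `n_potent`, `n`.
#' @export
potency_fraction <- function(outcomes) {
  if (!length(outcomes)) stopf("no outcomes supplied")
  if (is.character(outcomes)) {
    if (!all(outcomes %in% c("potent", "not_potent")))
      stopf("character outcomes must be 'potent' or 'not_potent'")
    outcomes <- outcomes == "potent"
  }
  list(proportion = mean(outcomes), n_potent = sum(outcomes),
       n = length(outcomes))
}

#' Read / write behavioral timelines as CSV
#'
#' Columns: `start_s, end_s, label`.
#'
#' @param path CSV file path.
#' @param timeline a [behavior_timeline()] (for writing).
#' @param observation_cap cap attached on read (s).
#' @return `read_timeline_csv` returns a [behavior_timeline()].
#' @export
read_timeline_csv <- function(path, observation_cap = 120) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  behavior_timeline(data.frame(start = df$start_s, end = df$end_s,
                               label = df$label, stringsAsFactors = FALSE),
                    observation_cap = observation_cap)
}

#' @rdname read_timeline_csv
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(data.frame(start_s = timeline$start, end_s = timeline$end,
                              label = timeline$label),
                   path, row.names = FALSE)
  invisible(path)
}
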