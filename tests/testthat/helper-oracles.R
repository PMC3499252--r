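# Independent oracles, kept free of the code paths they check.

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins: sum P(X = x) over x whose point probability is
# no greater than the observed one (within a relative float tolerance).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c          # first-column margin
  n <- b + d
  k <- a + b          # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to the two groups (requires untied values).
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  mu <- nx * length(y) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hand evaluation of the one-way ANOVA F statistic.
anova_f_hand <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups); n <- length(all_v)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Study-condition fixtures -------------------------------------------------

# Standard synthetic recording emulating a 10 s vulval-contact episode:
# 300 frames at 30 fps, 64 x 64 px, one composite ray-neuron cell, two
# calcium transients with peaks in the 30-80% range seen at the vulva,
# red-channel photobleaching, shared frame-scale artifacts, pixel noise at
# 2% of the green baseline.
std_stack_config <- function(seed,
                             transient_schedule = list(c(2, 1.5, 0.45),
                                                       c(6, 2, 0.6))) {
  stack_sim_config(n_frames = 300, frame_rate = 30, image_size = c(64, 64),
                   cell_positions = list(c(32, 32)), cell_radius = 4,
                   transient_schedule = transient_schedule,
                   noise_sd = 2, seed = seed)
}

# ROI layout of a standard recording: cell ROIs cover the cell disc's
# bounding box, background ROIs sit over an empty corner; ids follow the
# red-bg/green-cell/green-bg/red-cell numbering of a typical session.
std_rois <- function() {
  list(roi_track("2", "cell", "green", c(28, 28, 7, 7)),
       roi_track("4", "cell", "red",   c(28, 28, 7, 7)),
       roi_track("3", "background", "green", c(2, 2, 12, 12)),
       roi_track("1", "background", "red",   c(2, 2, 12, 12)))
}

# Full extraction -> reference fit -> correction -> event-calling pipeline.
run_ratiometric_pipeline <- function(sim, band_pct = 20) {
  tr <- extract_traces(sim$stack, std_rois())
  fit <- fit_reference(tr$bg_subtracted[["4"]], tr$times, "auto")
  ct <- correct_and_dff(tr$bg_subtracted[["2"]], tr$bg_subtracted[["4"]], fit)
  list(traces = tr, fit = fit, corrected = ct,
       events = call_events(ct, band_pct))
}

# In-memory single-channel stack from a frames x h x w array.
mini_stack <- function(data, frame_rate = 30) {
  structure(list(data = data,
                 times = (seq_len(dim(data)[1]) - 1) / frame_rate,
                 frame_rate = frame_rate),
            class = "dual_channel_stack")
}
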