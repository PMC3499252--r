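test_that("extract_mpi computes the arithmetic mean inside the rect", {
  # uniform field: MPI equals the field value wherever the rect sits
  u <- mini_stack(array(7, dim = c(3, 8, 8)))
  r1 <- roi_track("a", "cell", "green", c(0, 0, 4, 4))
  r2 <- roi_track("a", "cell", "green", c(3, 2, 4, 4))
  expect_equal(extract_mpi(u, r1), rep(7, 3))
  expect_equal(extract_mpi(u, r2), rep(7, 3))

  # hand mean of a 2x2 patch
  m <- array(0, dim = c(1, 4, 4))
  m[1, 1:2, 1:2] <- c(10, 30, 20, 40)  # column-major fill
  expect_equal(extract_mpi(mini_stack(m), roi_track("b", "cell", "green",
                                                    c(0, 0, 2, 2))), 25)

  # area-1 rect reproduces a single pixel's time series
  s <- array(stats::rnorm(5 * 6 * 6), dim = c(5, 6, 6))
  stack <- mini_stack(s)
  expect_equal(extract_mpi(stack, roi_track("c", "cell", "green", c(2, 3, 1, 1))),
               s[, 3, 4])
})

test_that("bad ROI geometry fails with the offending frame named", {
  u <- mini_stack(array(1, dim = c(3, 8, 8)))
  rects <- rbind(c(0, 0, 4, 4), c(6, 6, 4, 4), c(0, 0, 4, 4))
  expect_error(extract_mpi(u, roi_track("a", "cell", "green", rects)),
               "frame 2")
  expect_error(extract_mpi(u, roi_track("a", "cell", "green",
                                        rbind(c(0, 0, 4, 4), c(0, 0, 4, 4)))),
               "2 rects for 3 frames")
  expect_error(roi_track("a", "cell", "green",
                         rbind(c(0, 0, 4, 4), c(0, 0, 2, 2))),
               "equal across frames")
})

test_that("extract_mpi is linear in the pixel values", {
  s <- array(stats::runif(4 * 8 * 8, 10, 50), dim = c(4, 8, 8))
  roi <- roi_track("a", "cell", "green", c(1, 2, 5, 4))
  base <- extract_mpi(mini_stack(s), roi)
  scaled <- extract_mpi(mini_stack(3 * s + 2), roi)
  expect_equal(scaled, 3 * base + 2)
})

test_that("subtract_background is elementwise with optional clipping", {
  expect_equal(subtract_background(c(100, 110), c(20, 20)), c(80, 90))
  expect_equal(subtract_background(c(5, 5), c(5, 5)), c(0, 0))
  expect_equal(subtract_background(numeric(), numeric()), numeric())
  expect_equal(subtract_background(c(1, 5), c(3, 1), clip = TRUE), c(0, 4))
  expect_error(subtract_background(1:3, 1:2), "lengths differ")
})

test_that("pair_rois matches cells to same-channel backgrounds", {
  tracks <- list(roi_track("2", "cell", "green", c(0, 0, 2, 2)),
                 roi_track("4", "cell", "red", c(0, 0, 2, 2)),
                 roi_track("3", "background", "green", c(4, 4, 2, 2)),
                 roi_track("1", "background", "red", c(4, 4, 2, 2)))
  p <- pair_rois(tracks)
  expect_equal(p[["2"]], "3")
  expect_equal(p[["4"]], "1")

  # nearest-by-id when several backgrounds share the channel
  tracks2 <- c(tracks, list(roi_track("9", "background", "green", c(6, 6, 2, 2))))
  expect_equal(pair_rois(tracks2)[["2"]], "3")

  expect_error(pair_rois(list(roi_track("2", "cell", "green", c(0, 0, 2, 2)))),
               "green")
})

test_that("noiseless extraction round-trips the generative cell model", {
  cfg <- stack_sim_config(n_frames = 60, frame_rate = 30,
                          transient_schedule = list(c(0.5, 1, 0.5)),
                          red_bleach = c(80, 70, 0.3),
                          artifact_series = 1 + 0.1 * sin(seq(0, 4, length.out = 60)),
                          noise_sd = 0, seed = 4)
  sim <- simulate_stack(cfg)
  rois <- list(roi_track("g", "cell", "green", c(30, 30, 3, 3)),
               roi_track("r", "cell", "red", c(30, 30, 3, 3)),
               roi_track("gb", "background", "green", c(2, 2, 8, 8)),
               roi_track("rb", "background", "red", c(2, 2, 8, 8)))
  tr <- extract_traces(sim$stack, rois)
  t <- sim$stack$times
  a <- sim$truth$artifact_series
  expect_equal(tr$bg_subtracted[["g"]],
               100 * (1 + sim$truth$true_dff[1, ] / 100) * a)
  expect_equal(tr$bg_subtracted[["r"]], (80 + 70 * exp(-0.3 * t)) * a)
})

test_that("ROI and trace CSV round-trips preserve the data", {
  tracks <- list(roi_track("c1", "cell", "green",
                           rbind(c(0, 0, 3, 3), c(1, 1, 3, 3))),
                 roi_track("b1", "background", "green", c(4, 4, 3, 3),
                           n_frames = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_csv(tracks, path)
  back <- read_roi_csv(path)
  expect_equal(unname(back[["c1"]]$rects[, "row0"]), c(0, 1))
  expect_equal(back[["b1"]]$role, "background")

  s <- mini_stack(array(stats::runif(2 * 8 * 8), dim = c(2, 8, 8)))
  s$data <- array(rep(s$data, 2), dim = c(2, 8, 8, 2))
  tr <- extract_traces(s, list(roi_track("c1", "cell", "green", c(0, 0, 3, 3)),
                               roi_track("b1", "background", "green", c(4, 4, 3, 3))))
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, tpath)
  df <- read_trace_csv(tpath)
  expect_equal(sort(unique(df$roi_id)), c("b1", "c1"))
  expect_equal(df$mpi[df$roi_id == "c1"], tr$raw[["c1"]])
})
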