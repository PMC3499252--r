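tl_from <- function(...) behavior_timeline(data.frame(...))

test_that("E_SI reproduces the hand-evaluated scores", {
  # instant prodding, penetration 1 s after contact
  fast <- tl_from(start = c(0, 1), end = c(1, 2),
                  label = c("vulva_prodding", "insertion"))
  e <- compute_esi(fast)
  expect_equal(round(e$score, 2), 1.99)
  expect_equal(e$bonus, 119 / 120)

  # full window of contact without a single insertion attempt
  idle <- tl_from(start = 0, end = 120, label = "scanning")
  expect_equal(compute_esi(idle)$score, 0)

  # mixed bout: 30 s prodding, 10 s scanning, penetration at 40 s
  mixed <- tl_from(start = c(0, 10, 40), end = c(10, 40, 41),
                   label = c("scanning", "vulva_prodding", "insertion"))
  expect_equal(compute_esi(mixed)$score, (30 / 40) * (1 / 10) * (1 + 80 / 120))
})

test_that("E_SI is zero iff no time was spent prodding the vulva", {
  for (s in 1:40) {
    tl <- simulate_timeline(timeline_sim_config(p_ectopic = 0.5,
                                                p_penetration_per_bout = 0.3,
                                                seed = s))
    e <- compute_esi(tl)
    expect_equal(e$score == 0, e$t_prod == 0)
    expect_gte(e$score, 0)
    expect_true(e$bonus >= 0 && e$bonus <= 1)
    expect_lte(e$score, 2 * (e$t_prod / e$t_total) / max(e$t_nonprod, 1))
    expect_equal(e$t_total, e$t_prod + e$t_nonprod)
  }
})

test_that("E_SI responds monotonically to prodding and non-productive time", {
  base <- function(prod, scan) {
    tl <- tl_from(start = c(0, scan), end = c(scan, scan + prod),
                  label = c("scanning", "vulva_prodding"))
    compute_esi(tl)$score
  }
  prods <- vapply(c(5, 10, 20, 40), function(p) base(p, 10), 0)
  expect_true(all(diff(prods) > 0))
  scans <- vapply(c(2, 5, 10, 30, 60), function(s) base(20, s), 0)
  expect_true(all(diff(scans) < 0))
})

test_that("timeline validation enforces the interval contract", {
  expect_error(tl_from(start = 0, end = 0, label = "scanning"), "start < end")
  expect_error(tl_from(start = c(0, 5), end = c(10, 15),
                       label = c("scanning", "scanning")), "overlap")
  expect_error(tl_from(start = c(0, 10), end = c(5, 15),
                       label = c("insertion", "scanning")), "terminal")
  expect_error(compute_esi(tl_from(start = 0, end = 5, label = "off")),
               "no contact")
})

test_that("ICL percentage is the contact-to-body ratio", {
  expect_equal(compute_icl(1000, 1000), 100)
  expect_equal(compute_icl(250, 1000), 25)
  expect_equal(compute_icl(0, 500), 0)
  expect_error(compute_icl(600, 500), "exceeds")
  expect_error(compute_icl(10, 0), "> 0")
})

test_that("contact metrics count bouts, durations and attempt intervals", {
  # one prodding bout spanning the whole window
  single <- tl_from(start = 0, end = 120, label = "vulva_prodding")
  m <- contact_metrics(single)
  expect_equal(m$n_vulva_contacts, 1L)
  expect_equal(m$total_vulva_contact, 120)
  expect_true(is.na(m$mean_interval_between_attempts))
  expect_equal(m$n_contacts, 1L)

  # two prodding bouts separated by 20 s of scanning
  two <- tl_from(start = c(0, 10, 30), end = c(10, 30, 40),
                 label = c("vulva_prodding", "scanning", "vulva_prodding"))
  m2 <- contact_metrics(two)
  expect_equal(m2$n_vulva_contacts, 2L)
  expect_equal(m2$mean_interval_between_attempts, 20)
  expect_equal(m2$cumulative_contact, 40)
  expect_equal(m2$n_contacts, 1L)  # uninterrupted contact episode

  # off-time splits contact episodes; average = cumulative / episodes
  eps <- tl_from(start = c(0, 10, 20), end = c(8, 14, 26),
                 label = c("scanning", "off", "scanning"))
  m3 <- contact_metrics(eps)
  expect_equal(m3$n_contacts, 2L)
  expect_equal(m3$cumulative_contact, 14)
  expect_equal(m3$average_contact, 7)

  # empty timeline: all zeros
  m4 <- contact_metrics(behavior_timeline(
    data.frame(start = numeric(), end = numeric(), label = character())))
  expect_equal(m4$n_vulva_contacts, 0L)
  expect_equal(m4$cumulative_contact, 0)
  expect_equal(m4$average_contact, 0)
})

test_that("centroid kinematics convert pixel steps to distance and velocity", {
  # stationary animal
  still <- centroid_kinematics(0:9, cbind(rep(5, 10), rep(7, 10)), 100)
  expect_equal(still$distance_mm, 0)
  expect_equal(still$velocity_mm_s, rep(0, 9))

  # straight 300 px crawl over 10 s at 100 px/mm
  xy <- cbind(seq(0, 300, length.out = 11), rep(0, 11))
  k <- centroid_kinematics(seq(0, 10, by = 1), xy, 100)
  expect_equal(k$distance_mm, 3)
  expect_equal(k$velocity_mm_s, rep(0.3, 10))
  expect_equal(k$mean_velocity_mm_s, 0.3)

  expect_error(centroid_kinematics(0, cbind(1, 1), 100), "at least 2")
})

test_that("potency fraction summarizes cross-progeny outcomes", {
  expect_equal(potency_fraction(rep(TRUE, 8))$proportion, 1)
  p <- potency_fraction(c(rep("potent", 7), rep("not_potent", 3)))
  expect_equal(p$proportion, 0.7)
  expect_equal(p$n, 10L)
  expect_error(potency_fraction(logical()), "no outcomes")
})

test_that("timelines round-trip through CSV", {
  tl <- simulate_timeline(timeline_sim_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeline_csv(tl, path)
  back <- read_timeline_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tl), tolerance = 1e-9)
})
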