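test_that("canonical runs are classified per the 50-500 ms rule", {
  n <- 200
  # 20 ticks = 200 ms, both eyes: one blink
  s <- samples_with_runs(n, list(list(start = 50, len = 20)))
  b <- detect_blinks(s)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_ms, 200L)
  expect_equal(b$onset_ms, 490L)

  # 3 ticks = 30 ms: discarded as noise
  s <- samples_with_runs(n, list(list(start = 50, len = 3)))
  b <- detect_blinks(s)
  sum <- summarize_blinks(b, scene_session("Library", s, gaze_events(0, "x")[0, ],
                                           n * 10L))
  expect_equal(nrow(b), 0)
  expect_equal(sum$discarded_short, 1)

  # 70 ticks = 700 ms: discarded as microsleep
  s <- samples_with_runs(n, list(list(start = 50, len = 70)))
  b <- detect_blinks(s)
  cand <- attr(b, "candidates")
  expect_equal(nrow(b), 0)
  expect_equal(sum(cand$class == "long"), 1)

  # fully present trace: nothing
  s <- samples_with_runs(n, list())
  expect_equal(nrow(detect_blinks(s)), 0)
})

test_that("the 50 and 500 ms thresholds are sharp and inclusive", {
  n <- 300
  for (case in list(list(len = 4, blink = FALSE),   # 40 ms
                    list(len = 5, blink = TRUE),    # 50 ms
                    list(len = 50, blink = TRUE),   # 500 ms
                    list(len = 51, blink = FALSE))) # 510 ms
  {
    s <- samples_with_runs(n, list(list(start = 100, len = case$len)))
    expect_equal(nrow(detect_blinks(s)), as.integer(case$blink),
                 label = paste(case$len * 10, "ms run"))
  }
})

test_that("eye modes differ exactly on monocular dropouts", {
  n <- 200
  s <- samples_with_runs(n, list(list(start = 40, len = 10, eye = "L"),
                                 list(start = 100, len = 10)))
  expect_equal(nrow(detect_blinks(s, "BOTH_EYES")), 1)    # only binocular run
  expect_equal(nrow(detect_blinks(s, "EITHER_EYE")), 2)   # plus the L-eye run
})

test_that("runs truncated by scene end are tallied, not classified", {
  n <- 100
  s <- samples_with_runs(n, list(list(start = 91, len = 10)))
  b <- detect_blinks(s)
  expect_equal(nrow(b), 0)
  expect_equal(sum(attr(b, "candidates")$class == "truncated"), 1)
})

test_that("every missing tick belongs to exactly one candidate (partition)", {
  set.seed(77)
  for (rep in 1:50) {
    n <- 400
    miss <- runif(n) < 0.2
    pl <- ifelse(miss, NA_real_, 4)
    s <- make_samples(pl, pl)
    cand <- blink_candidates(s)
    expect_equal(sum(cand$n_ticks), sum(miss))
    # counts partition the candidates
    b <- detect_blinks(s)
    sm <- summarize_blinks(b, scene_session("Library", s, gaze_events(0, "x")[0, ],
                                            n * 10L))
    expect_equal(nrow(b) + sm$discarded_short + sm$discarded_long +
                   sm$discarded_truncated, nrow(cand))
  }
})

test_that("blink rate arithmetic is exact", {
  s <- samples_with_runs(100, list())
  ses <- scene_session("Bus", s, gaze_events(0, "cellphone"), 300000L)
  # zero blinks: rate is exactly zero
  expect_equal(summarize_blinks(detect_blinks(ses$samples), ses)$ebr_per_min, 0)
  # 150 blinks in a 5-minute scene: exactly 30 per minute
  fake <- tibble::tibble(onset_ms = seq_len(150) * 1000L, duration_ms = 100L,
                         n_ticks = 10L, object_at_onset = "cellphone")
  attr(fake, "candidates") <- tibble::tibble(onset_ms = fake$onset_ms,
                                             duration_ms = fake$duration_ms,
                                             n_ticks = fake$n_ticks,
                                             class = "blink",
                                             object_at_onset = fake$object_at_onset)
  expect_equal(summarize_blinks(fake, ses)$ebr_per_min, 30)
})

test_that("detected blinks recover the ground truth without dropouts", {
  cfg <- sim_config(seed = 31, dropout_rate_per_min = 0,
                    scene_duration_ms = 30000)
  for (s in 1:20) {
    x <- simulate_scene(cfg, "WaitingRoom", s)
    det <- detect_blinks(x$session$samples, "BOTH_EYES")
    expect_identical(as.integer(det$onset_ms), as.integer(x$truth$blinks$onset_ms))
    expect_identical(as.integer(det$duration_ms),
                     as.integer(x$truth$blinks$duration_ms))
  }
})

test_that("the detector matches the simulator at a configured rate", {
  cfg <- sim_config(seed = 99, blink_rate_per_min = 25, blink_rate_sdlog = 0,
                    scene_duration_ms = 60000)
  rates <- vapply(1:100, function(s) {
    x <- simulate_scene(cfg, "Bus", s)
    sm <- summarize_blinks(detect_blinks(x$session$samples), x$session)
    sm$ebr_per_min
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 25), 3 * se)
})

test_that("off-grid samples are rejected", {
  s <- make_samples(rep(4, 10), rep(4, 10))
  s$t_ms[5] <- s$t_ms[5] + 5L
  expect_error(blink_candidates(s), "grid")
})
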