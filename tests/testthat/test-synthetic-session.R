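test_that("scene catalogs satisfy the category contracts", {
  for (nm in c("Driving", "Patio", "OutdoorBBQ")) {
    cat <- make_scene_catalog(nm)
    expect_gte(sum(cat$category == "Active"), 4)
    expect_gte(sum(cat$category == "Neutral"), 4)
    expect_true(any(cat$category == "Miscellaneous"))
    expect_true(any(cat$category == "Background"))
    expect_equal(anyDuplicated(cat$name), 0)
    expect_true(all(cat$radius > 0))
  }
  for (nm in c("Bus", "WaitingRoom", "Library")) {
    cat <- make_scene_catalog(nm)
    expect_equal(sum(cat$category == "Active"), 0)
    expect_gte(sum(cat$category == "Neutral"), 4)
  }
  expect_error(make_scene_catalog("Casino"), "unknown scene")
  # the driving-reversal preset recategorises the street video panel
  drv <- make_scene_catalog("Driving", driving_reversal = TRUE)
  expect_identical(drv$category[drv$name == "street_video"], "Neutral")
})

test_that("scene order alternates Active/Neutral and is seed-deterministic", {
  for (seed in c(1, 99, 4242)) {
    ord <- draw_scene_order(seed)
    expect_identical(scene_type(ord), rep(c("Active", "Neutral"), 3))
    expect_identical(draw_scene_order(seed), ord)
    expect_equal(anyDuplicated(ord), 0)
  }
  # over many seeds each Active scene opens the session about 1/3 of the time
  firsts <- vapply(1:600, function(s) draw_scene_order(s)[1], character(1))
  freq <- table(firsts) / 600
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("simulation is reproducible and internally consistent", {
  cfg <- sim_config(seed = 21, n_participants = 2, scene_duration_ms = 10000)
  a <- simulate_participant(cfg, 1)
  b <- simulate_participant(cfg, 1)
  expect_equal(a, b)

  for (nm in names(a$log$sessions)) {
    ses <- a$log$sessions[[nm]]
    truth <- a$truth$scenes[[nm]]
    # ground-truth dwell equals dwell recomputed from the emitted events
    cat <- make_scene_catalog(nm, driving_reversal = cfg$driving_reversal)
    led <- accumulate_fixations(ses$events, cat, ses$duration_ms)
    expect_equal(setNames(led$fixation_ms, led$object)[order(led$object)],
                 setNames(truth$dwell$ms, truth$dwell$object)[order(truth$dwell$object)])
    # realized dwell tiles the scene exactly
    expect_equal(sum(truth$dwell$ms), ses$duration_ms)
    # the object column of the timeseries agrees with the event stream
    sw <- ses$events[ses$events$kind == "gaze_switch", ]
    sw_obj <- vapply(sw$payload, function(p) p$object, character(1))
    idx <- findInterval(ses$samples$t_ms, sw$t_ms)
    expect_identical(ses$samples$object, sw_obj[idx])
    # both pupils are missing during every true blink and microsleep
    for (i in seq_len(nrow(truth$blinks))) {
      sel <- ses$samples$t_ms >= truth$blinks$onset_ms[i] &
        ses$samples$t_ms < truth$blinks$onset_ms[i] + truth$blinks$duration_ms[i]
      expect_true(all(is.na(ses$samples$pupil_l_mm[sel])))
      expect_true(all(is.na(ses$samples$pupil_r_mm[sel])))
    }
  }
})

test_that("realized blink counts follow the configured Poisson rate", {
  cfg <- sim_config(seed = 8, blink_rate_per_min = 20, blink_rate_sdlog = 0,
                    scene_duration_ms = 60000)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_scene(cfg, "Library", s)$truth$blinks)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # durations respect the configured blink range
  d <- simulate_scene(cfg, "Library", 7)$truth$blinks$duration_ms
  expect_true(all(d >= 50 & d <= 500))
})

test_that("unbiased dwell yields symmetric category totals", {
  # Patio has five Active and five Neutral objects of equal attractiveness
  cfg <- sim_config(seed = 13, dwell_bias = 1, scene_duration_ms = 30000)
  diffs <- vapply(1:50, function(s) {
    x <- simulate_scene(cfg, "Patio", s)
    cat <- make_scene_catalog("Patio")
    cat_f <- factor(cat$category[match(x$truth$dwell$object, cat$name)],
                    levels = c("Active", "Neutral"))
    by_cat <- tapply(x$truth$dwell$ms, cat_f, sum, default = 0)
    unname(by_cat["Active"] - by_cat["Neutral"])  # un-gazed category = 0 dwell
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("a null pupil effect leaves the true category means equal", {
  cfg <- sim_config(seed = 2, pupil_cue_delta_mm = 0, scene_duration_ms = 5000)
  x <- simulate_scene(cfg, "Patio", 1)
  expect_equal(x$truth$pupil_mean_active, x$truth$pupil_mean_other)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(dropout_dur_ms_max = 60), "50 ms")
  expect_error(sim_config(microsleep_dur_ms_min = 400), "500 ms")
  expect_error(sim_config(blink_dur_ms_range = c(30, 400)), "50, 500")
  expect_error(sim_config(dwell_bias = -1), "positive")
  expect_error(sim_config(scene_duration_ms = 1005), "multiple")
})

test_that("config files round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9, n_participants = 4, dwell_bias = 1.5), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$n_participants, 4)
  expect_equal(cfg$dwell_bias, 1.5)
  expect_equal(cfg$blink_rate_per_min, 20)  # untouched default
  yaml::write_yaml(list(not_a_key = 1), path)
  expect_error(read_sim_config(path), "unknown config key")
})
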