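patio_cat <- make_scene_catalog("Patio")

test_that("the switch-interval rule drives the ledger", {
  # A@0, B@1000, A@1500, scene end 3000 -> A: 2500 ms, B: 500 ms
  ev <- gaze_events(c(0, 1000, 1500), c("ashtray", "magazine", "ashtray"))
  led <- accumulate_fixations(ev, patio_cat, 3000)
  expect_equal(led$fixation_ms[led$object == "ashtray"], 2500)
  expect_equal(led$fixation_ms[led$object == "magazine"], 500)

  # a single switch at 0 owns the whole scene
  led <- accumulate_fixations(gaze_events(0, "hookah"), patio_cat, 300000)
  expect_equal(led$fixation_ms, 300000)
  expect_equal(sum(led$fixation_ms), 300000)

  # revisits accumulate onto the same key
  ev <- gaze_events(c(0, 100, 200, 400), c("juul", "pen", "juul", "pen"))
  expect_error(accumulate_fixations(ev, patio_cat, 1000), "absent")  # no pen in Patio
  ev <- gaze_events(c(0, 100, 200, 400), c("juul", "cellphone", "juul", "cellphone"))
  led <- accumulate_fixations(ev, patio_cat, 1000)
  expect_equal(led$fixation_ms[led$object == "juul"], 100 + 200)
  expect_equal(led$fixation_ms[led$object == "cellphone"], 100 + 600)
})

test_that("ledgers equal the brute-force interval-sum oracle", {
  set.seed(123)
  for (rep in 1:60) {
    k <- sample(1:40, 1)
    duration <- 60000
    times <- sort(sample(0:(duration - 1), k))
    objects <- sample(patio_cat$name, k, replace = TRUE)
    led <- accumulate_fixations(gaze_events(times, objects), patio_cat, duration)
    oracle <- oracle_fixation_sums(times, objects, duration)
    expect_equal(setNames(led$fixation_ms, led$object),
                 oracle[sort(names(oracle))])
    # conservation: category totals + time before the first switch = duration
    idx <- fixation_indices(led)
    expect_equal(sum(idx$by_category$total_ms) + idx$uncovered_ms, duration)
  }
})

test_that("indices report totals, means, and absent categories correctly", {
  ev <- gaze_events(c(0, 4000), c("ashtray", "lighter"))
  led <- accumulate_fixations(ev, patio_cat, 6000)
  idx <- fixation_indices(led)
  act <- idx$by_category[idx$by_category$category == "Active", ]
  expect_equal(act$total_ms, 6000)
  expect_equal(act$mean_ms, 3000)   # 6000 over two distinct objects
  expect_equal(act$n_objects, 2)
  neu <- idx$by_category[idx$by_category$category == "Neutral", ]
  expect_true(is.na(neu$mean_ms))   # no gazed Neutral object: mean is absent
  expect_equal(neu$total_ms, 0)
  expect_equal(idx$bias_ms, 6000)   # bias uses the zero Neutral total
  # mean * object count recovers the total exactly
  expect_equal(act$mean_ms * act$n_objects, act$total_ms)
})

test_that("shuffling switch-aligned segments leaves totals unchanged", {
  set.seed(5)
  duration <- 20000
  times <- c(0, sort(sample(1:(duration - 1), 19)))
  objects <- sample(patio_cat$name, 20, replace = TRUE)
  cut <- times[11]  # boundary aligned with a switch
  a <- accumulate_fixations(gaze_events(times, objects), patio_cat, duration)
  # swap [0, cut) and [cut, duration): shift each block, preserve order inside
  t1 <- times[times < cut]; o1 <- objects[times < cut]
  t2 <- times[times >= cut]; o2 <- objects[times >= cut]
  times2 <- c(t2 - cut, t1 + (duration - cut))
  objects2 <- c(o2, o1)
  b <- accumulate_fixations(gaze_events(times2, objects2), patio_cat, duration)
  expect_equal(setNames(a$fixation_ms, a$object), setNames(b$fixation_ms, b$object))
})

test_that("the attentional-bias score is the mean per-scene bias", {
  mk <- function(scene, obj_a, obj_n, x, dur) {
    gaze_events(c(0, x), c(obj_a, obj_n))
  }
  events <- list(
    Patio = mk("Patio", "ashtray", "magazine", 10000, 17598),
    OutdoorBBQ = mk("OutdoorBBQ", "cigarette", "soda_can", 5000, 9050),
    Driving = mk("Driving", "cigarette", "magazine", 1000, 26485),
    Bus = gaze_events(0, "cellphone"),
    WaitingRoom = gaze_events(0, "magazine"),
    Library = gaze_events(0, "book")
  )
  durations <- list(Patio = 17598, OutdoorBBQ = 9050, Driving = 26485,
                    Bus = 1000, WaitingRoom = 1000, Library = 1000)
  log <- bare_log(events, durations)
  res <- attentional_bias_score(log)
  # per-scene biases +2402, +950, -24485 average to -7044.333
  expect_equal(unname(res$per_scene[c("Driving", "Patio", "OutdoorBBQ")]),
               c(-24485, 2402, 950))
  expect_equal(res$score_ms, mean(c(2402, 950, -24485)), tolerance = 1e-12)
  expect_equal(res$n_scenes, 3)

  # a missing Active scene: mean over the remaining two, with a warning
  log2 <- bare_log(events[names(events) != "Driving"],
                   durations[names(durations) != "Driving"])
  expect_warning(res2 <- attentional_bias_score(log2), "2 of 3")
  expect_equal(res2$score_ms, mean(c(2402, 950)))
})

test_that("default and reversal scenarios reproduce the sign pattern", {
  # default: Active-cue dwell dominates in Patio and OutdoorBBQ
  cfg <- sim_config(seed = 17, scene_duration_ms = 30000)
  bias_of <- function(cfg, scene, seeds) {
    vapply(seeds, function(s) {
      x <- simulate_scene(cfg, scene, s)
      cat <- make_scene_catalog(scene, driving_reversal = cfg$driving_reversal)
      fixation_indices(accumulate_fixations(x$session$events, cat,
                                            x$session$duration_ms))$bias_ms
    }, numeric(1))
  }
  expect_gt(mean(bias_of(cfg, "Patio", 1:20)), 0)
  expect_gt(mean(bias_of(cfg, "OutdoorBBQ", 1:20)), 0)
  # reversal preset: the street video drags dwell to Neutral in Driving
  cfg_rev <- sim_config(seed = 17, scene_duration_ms = 30000,
                        driving_reversal = TRUE)
  expect_lt(mean(bias_of(cfg_rev, "Driving", 1:20)), 0)
})

test_that("dwell-bias coupling to use episodes induces a positive correlation", {
  cfg <- sim_config(seed = 71, n_participants = 200, scene_duration_ms = 20000,
                    use_episodes_slope = 3e-4)
  res <- lapply(1:200, function(i) simulate_participant(cfg, i))
  bias <- vapply(res, function(x) attentional_bias_score(x$log)$score_ms,
                 numeric(1))
  episodes <- vapply(res, function(x) x$truth$use_episodes, numeric(1))
  expect_gt(pearson_r(bias, episodes)$r, 0)
})
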