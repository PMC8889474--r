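# Synthetic VR session simulator.
#
# Generates participant logs with the statistical structure the analysis
# assumes -- category-biased gaze dwell, cue-evoked pupil shifts, Poisson
# blinks/dropouts/microsleeps, post-scene VAS surveys -- together with a
# ground-truth record for parameter-recovery testing. All randomness is
# seeded; a participant's log depends only on (config, participant_index), so
# adding participants never perturbs existing ones.

# Deterministic substream seed below 2^31, derived by modular hashing so that
# products stay exactly representable in doubles.
substream_seed <- function(seed, ...) {
  h <- seed %% 94906249
  for (idx in c(...)) {
    h <- (h * 69069 + idx + 1) %% 94906249
  }
  as.integer(h + 1)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Exact truncated-normal draws via inverse-CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulator configuration
#'
#' Defaults encode the study conditions the analysis targets: 5-minute scenes
#' sampled at 100 Hz; a 2:1 dwell preference for Active-category objects in
#' Active scenes; a -0.10 mm pupil shift while gazing nicotine cues (Active
#' pooled mean 3.87 mm vs Neutral 3.97 mm); ~20 blinks/min (centre of the
#' 12-40 blinks/min plausibility band) with mean-preserving lognormal
#' between-participant spread; brief single-eye tracker dropouts (< 50 ms) and
#' rare microsleeps (> 500 ms); craving VAS latent means 42.77 (Active) vs
#' 29.42 (Neutral); and heavily right-skewed past-90-day use-episode counts
#' (lognormal matching mean 772.29, SD 1008.20).
#'
#' @param seed Integer master seed.
#' @param n_participants Number of participants to simulate.
#' @param scene_duration_ms Scene duration (ms); default 300000 (5 min).
#' @param dwell_bias Ratio of dwell propensity for Active-category vs
#'   Neutral-category objects (1 = no bias).
#' @param mean_dwell_ms Mean single-fixation duration (exponential, truncated
#'   at 10 s).
#' @param pupil_base_mm,pupil_base_sd_mm Participant baseline pupil diameter:
#'   normal mean/SD (mm).
#' @param pupil_cue_delta_mm Additive diameter shift while gazing an
#'   Active-category object (mm; negative = constriction).
#' @param pupil_noise_sd_mm Per-sample, per-eye noise SD (mm).
#' @param blink_rate_per_min Mean true blink rate (Poisson, per minute).
#' @param blink_rate_sdlog Lognormal sdlog of the between-participant blink
#'   rate (mean-preserving; 0 disables heterogeneity).
#' @param blink_dur_ms_range Blink duration range (ms), within \[50, 500\].
#' @param dropout_rate_per_min,dropout_dur_ms_max Single-eye tracker dropout
#'   rate and maximum duration (< 50 ms).
#' @param microsleep_rate_per_min,microsleep_dur_ms_min,microsleep_dur_ms_max
#'   Microsleep rate and duration range (> 500 ms).
#' @param craving_active_mean,craving_neutral_mean,craving_sd Craving VAS
#'   generator: latent scene-type means and per-scene noise SD (0-100 scale).
#' @param craving_between_sd Between-participant SD of the latent craving
#'   level shared by all scenes.
#' @param relevance_active_mean,relevance_neutral_mean,relevance_sd Scene
#'   relevance VAS generator.
#' @param use_episodes_meanlog,use_episodes_sdlog Lognormal parameters of the
#'   past-90-day use-episode count.
#' @param use_episodes_slope Linear coupling of use episodes to a
#'   participant's dwell bias (per episode, about the episode mean).
#' @param driving_reversal Ship the Driving catalog with its street-video
#'   panel categorised Neutral and highly attractive (reproduces the
#'   Driving-scene attentional-bias reversal).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 31L,
                       scene_duration_ms = 300000L,
                       dwell_bias = 2.0,
                       mean_dwell_ms = 1200,
                       pupil_base_mm = 3.97,
                       pupil_base_sd_mm = 0.7,
                       pupil_cue_delta_mm = -0.10,
                       pupil_noise_sd_mm = 0.30,
                       blink_rate_per_min = 20,
                       blink_rate_sdlog = 0.25,
                       blink_dur_ms_range = c(50, 500),
                       dropout_rate_per_min = 6,
                       dropout_dur_ms_max = 40,
                       microsleep_rate_per_min = 0.3,
                       microsleep_dur_ms_min = 600,
                       microsleep_dur_ms_max = 2000,
                       craving_active_mean = 42.77,
                       craving_neutral_mean = 29.42,
                       craving_sd = 20,
                       craving_between_sd = 18,
                       relevance_active_mean = 55,
                       relevance_neutral_mean = 40,
                       relevance_sd = 20,
                       use_episodes_meanlog = 6.152,
                       use_episodes_sdlog = 0.997,
                       use_episodes_slope = 0,
                       driving_reversal = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; stops on violation.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 0) stop("n_participants must be >= 0", call. = FALSE)
    if (scene_duration_ms <= 0 || scene_duration_ms %% SAMPLE_PERIOD_MS != 0) {
      stop("scene_duration_ms must be a positive multiple of 10 ms", call. = FALSE)
    }
    rates <- c(blink_rate_per_min, dropout_rate_per_min, microsleep_rate_per_min,
               mean_dwell_ms, pupil_noise_sd_mm, craving_sd)
    if (any(rates < 0)) stop("rates and dispersions must be nonnegative", call. = FALSE)
    if (dwell_bias <= 0) stop("dwell_bias must be positive", call. = FALSE)
    if (blink_dur_ms_range[1] < 50 || blink_dur_ms_range[2] > 500 ||
        blink_dur_ms_range[1] > blink_dur_ms_range[2]) {
      stop("blink_dur_ms_range must lie within [50, 500]", call. = FALSE)
    }
    if (dropout_dur_ms_max >= 50) stop("dropout durations must be < 50 ms", call. = FALSE)
    if (microsleep_dur_ms_min <= 500) stop("microsleep durations must be > 500 ms", call. = FALSE)
  })
  invisible(cfg)
}

#' Read a simulator configuration from a YAML or JSON file
#'
#' Keys mirror the [sim_config()] argument names; unspecified keys keep their
#' defaults.
#'
#' @param path File path (`.json` parsed as JSON, anything else as YAML).
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  bad <- setdiff(names(vals), names(formals(sim_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(sim_config, vals)
}

#' Draw a pseudorandomised scene order
#'
#' The fixed pattern Active, Neutral, Active, Neutral, Active, Neutral with the
#' three Active scenes permuted over the odd positions and the three Neutral
#' scenes over the even positions; deterministic given the seed.
#'
#' @param seed Integer seed.
#' @return Character vector of 6 scene names.
#' @export
draw_scene_order <- function(seed) {
  with_seed(seed, {
    act <- sample(ACTIVE_SCENES)
    neu <- sample(NEUTRAL_SCENES)
    as.vector(rbind(act, neu))
  })
}

# Place k non-overlapping intervals (tick durations `dur`) uniformly on a grid
# of n_ticks, with a one-tick guard after each interval so adjacent intervals
# never merge into a single missing run and no interval touches the final
# sample. Returns 0-based onset ticks (sorted), dropping intervals only if the
# grid cannot hold them.
place_intervals <- function(n_ticks, dur) {
  k <- length(dur)
  if (k == 0) return(list(onset = integer(), dur = integer()))
  dur <- dur[sample.int(k)]
  while (k > 0 && sum(dur[seq_len(k)]) + k > n_ticks) k <- k - 1
  if (k == 0) return(list(onset = integer(), dur = integer()))
  dur <- dur[seq_len(k)]
  free <- n_ticks - sum(dur) - k
  u <- sort(sample.int(free + 1, k, replace = TRUE) - 1L)
  onset <- u + c(0L, cumsum(dur + 1L))[seq_len(k)]
  list(onset = as.integer(onset), dur = as.integer(dur))
}

# Participant-level latent draws shared across that participant's six scenes.
participant_params <- function(cfg, participant_index) {
  with_seed(substream_seed(cfg$seed, 1, participant_index), {
    use_episodes <- stats::rlnorm(1, cfg$use_episodes_meanlog, cfg$use_episodes_sdlog)
    episode_mean <- exp(cfg$use_episodes_meanlog + cfg$use_episodes_sdlog^2 / 2)
    rate_meanlog <- log(cfg$blink_rate_per_min) - cfg$blink_rate_sdlog^2 / 2
    list(
      participant_index = participant_index,
      pupil_base_mm = stats::rnorm(1, cfg$pupil_base_mm, cfg$pupil_base_sd_mm),
      blink_rate_per_min = stats::rlnorm(1, rate_meanlog, cfg$blink_rate_sdlog),
      craving_latent = stats::rnorm(1, 0, cfg$craving_between_sd),
      use_episodes = use_episodes,
      dwell_bias = max(0.1, cfg$dwell_bias +
                         cfg$use_episodes_slope * (use_episodes - episode_mean))
    )
  })
}

# Simulate one scene for given participant-level parameters. Returns the
# scene_session plus its ground truth.
sim_scene_impl <- function(cfg, scene_name, pp, seed, catalog) {
  duration_ms <- as.integer(cfg$scene_duration_ms)
  n_ticks <- duration_ms %/% SAMPLE_PERIOD_MS
  stype <- scene_type(scene_name)
  with_seed(seed, {
    ## --- gaze: iid weighted object draws with exponential dwell; consecutive
    ## identical draws merge, so time share per object is proportional to its
    ## weight (Active-category weights scaled by the participant's dwell bias).
    w <- catalog$weight * ifelse(catalog$category == "Active", pp$dwell_bias, 1)
    k <- ceiling(duration_ms / cfg$mean_dwell_ms * 1.7) + 20
    repeat {
      durs <- pmin(stats::rexp(k, 1 / cfg$mean_dwell_ms), 10000)
      if (sum(durs) >= duration_ms) break
      k <- k * 2
    }
    starts <- cumsum(c(0, durs))
    keep <- starts < duration_ms
    starts <- round(starts[keep])
    obj_idx <- sample.int(nrow(catalog), sum(keep), replace = TRUE, prob = w)
    # merge consecutive repeats and rounding-collapsed starts
    dedup <- c(TRUE, diff(starts) > 0)
    starts <- starts[dedup]; obj_idx <- obj_idx[dedup]
    merge <- c(TRUE, diff(obj_idx) != 0)
    starts <- as.integer(starts[merge]); obj_idx <- obj_idx[merge]
    seg_ms <- diff(c(starts, duration_ms))
    dwell <- rowsum(seg_ms, group = catalog$name[obj_idx])
    dwell_truth <- fast_tibble(object = rownames(dwell),
                               ms = as.numeric(dwell[, 1]))

    t_ms <- as.integer(seq(0L, duration_ms - SAMPLE_PERIOD_MS,
                           by = SAMPLE_PERIOD_MS))
    tick_obj_idx <- obj_idx[findInterval(t_ms, starts)]
    tick_obj <- catalog$name[tick_obj_idx]
    on_active <- catalog$category[tick_obj_idx] == "Active"

    ## --- pupil signal
    sig <- pp$pupil_base_mm + cfg$pupil_cue_delta_mm * on_active
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    pupil_l <- clamp(sig + stats::rnorm(n_ticks, 0, cfg$pupil_noise_sd_mm), 0.1, 9.9)
    pupil_r <- clamp(sig + stats::rnorm(n_ticks, 0, cfg$pupil_noise_sd_mm), 0.1, 9.9)

    ## --- blinks + microsleeps (binocular closures), guard-separated
    minutes <- duration_ms / 60000
    n_blink <- stats::rpois(1, pp$blink_rate_per_min * minutes)
    n_micro <- stats::rpois(1, cfg$microsleep_rate_per_min * minutes)
    blink_dur <- sample(seq(cfg$blink_dur_ms_range[1] %/% SAMPLE_PERIOD_MS,
                            cfg$blink_dur_ms_range[2] %/% SAMPLE_PERIOD_MS),
                        n_blink, replace = TRUE)
    micro_dur <- sample(seq(ceiling(cfg$microsleep_dur_ms_min / SAMPLE_PERIOD_MS),
                            cfg$microsleep_dur_ms_max %/% SAMPLE_PERIOD_MS),
                        n_micro, replace = TRUE)
    placed <- place_intervals(n_ticks, c(blink_dur, micro_dur))
    # place_intervals shuffles, so recover the event type from the duration
    # class: blinks are <= 50 ticks (500 ms), microsleeps strictly longer.
    placed_is_blink <- placed$dur <= 50L
    miss_l <- rep(FALSE, n_ticks)
    miss_r <- rep(FALSE, n_ticks)
    for (i in seq_along(placed$onset)) {
      idx <- (placed$onset[i] + 1):(placed$onset[i] + placed$dur[i])
      miss_l[idx] <- TRUE
      miss_r[idx] <- TRUE
    }
    blink_truth <- fast_tibble(
      onset_ms = placed$onset[placed_is_blink] * SAMPLE_PERIOD_MS,
      duration_ms = placed$dur[placed_is_blink] * SAMPLE_PERIOD_MS
    )
    micro_truth <- fast_tibble(
      onset_ms = placed$onset[!placed_is_blink] * SAMPLE_PERIOD_MS,
      duration_ms = placed$dur[!placed_is_blink] * SAMPLE_PERIOD_MS
    )

    ## --- single-eye tracker dropouts (may overlap anything)
    n_drop <- stats::rpois(1, cfg$dropout_rate_per_min * minutes)
    drop_dur <- sample.int(cfg$dropout_dur_ms_max %/% SAMPLE_PERIOD_MS,
                           n_drop, replace = TRUE)
    drop_onset <- vapply(drop_dur, function(d) {
      sample.int(n_ticks - d + 1L, 1L) - 1L
    }, integer(1))
    drop_eye <- sample(c("L", "R"), n_drop, replace = TRUE)
    for (i in seq_len(n_drop)) {
      idx <- (drop_onset[i] + 1):(drop_onset[i] + drop_dur[i])
      if (drop_eye[i] == "L") miss_l[idx] <- TRUE else miss_r[idx] <- TRUE
    }
    dropout_truth <- fast_tibble(onset_ms = drop_onset * SAMPLE_PERIOD_MS,
                                 duration_ms = drop_dur * SAMPLE_PERIOD_MS,
                                 eye = drop_eye)

    pupil_l[miss_l] <- NA_real_
    pupil_r[miss_r] <- NA_real_
    open_l <- ifelse(miss_l, NA_real_,
                     clamp(stats::rnorm(n_ticks, 0.95, 0.03), 0, 1))
    open_r <- ifelse(miss_r, NA_real_,
                     clamp(stats::rnorm(n_ticks, 0.95, 0.03), 0, 1))

    ## --- geometry: gaze point near the gazed object, headset at eye height
    ox <- catalog$x[tick_obj_idx]; oy <- catalog$y[tick_obj_idx]
    oz <- catalog$z[tick_obj_idx]
    gx <- ox + stats::rnorm(n_ticks, 0, 0.01)
    gy <- oy + stats::rnorm(n_ticks, 0, 0.01)
    gz <- oz + stats::rnorm(n_ticks, 0, 0.01)
    hx <- 0; hy <- 1.6; hz <- 0
    fx <- ox - hx; fy <- oy - hy; fz <- oz - hz
    fn <- sqrt(fx^2 + fy^2 + fz^2)
    fx <- fx / fn; fy <- fy / fn; fz <- fz / fn

    samples <- tibble::new_tibble(list(
      t_ms = t_ms, gx = gx, gy = gy, gz = gz,
      hx = rep(hx, n_ticks), hy = rep(hy, n_ticks), hz = rep(hz, n_ticks),
      fx = fx, fy = fy, fz = fz,
      pupil_l_mm = pupil_l, pupil_r_mm = pupil_r,
      open_l = open_l, open_r = open_r, object = tick_obj
    ), nrow = n_ticks)

    ## --- events
    crav_mean <- if (stype == "Active") cfg$craving_active_mean else cfg$craving_neutral_mean
    rel_mean <- if (stype == "Active") cfg$relevance_active_mean else cfg$relevance_neutral_mean
    craving <- as.integer(round(rtruncnorm(1, crav_mean + pp$craving_latent,
                                           cfg$craving_sd, 0, 100)))
    relevance <- as.integer(round(rtruncnorm(1, rel_mean, cfg$relevance_sd, 0, 100)))
    n_gaze <- length(starts)
    blink_onsets <- as.integer(blink_truth$onset_ms)
    ev_t <- c(starts, blink_onsets, rep(duration_ms, 2L))
    ev_kind <- c(rep("gaze_switch", n_gaze),
                 rep("blink", length(blink_onsets)),
                 rep("survey", 2L))
    ev_payload <- c(
      lapply(catalog$name[obj_idx], function(o) list(object = o)),
      lapply(seq_along(blink_onsets), function(i) {
        tick <- blink_onsets[i] %/% SAMPLE_PERIOD_MS + 1L
        list(count = i, object = tick_obj[tick])
      }),
      list(list(scale = "craving", value = craving),
           list(scale = "relevance", value = relevance))
    )
    ord <- order(ev_t)
    events <- fast_tibble(t_ms = ev_t[ord], kind = ev_kind[ord],
                          payload = ev_payload[ord])

    session <- scene_session(scene_name, samples, events, duration_ms)
    truth <- list(
      scene_name = scene_name,
      scene_type = stype,
      blinks = blink_truth[order(blink_truth$onset_ms), ],
      microsleeps = micro_truth[order(micro_truth$onset_ms), ],
      dropouts = dropout_truth,
      dwell = dwell_truth,
      pupil_mean_active = pp$pupil_base_mm + cfg$pupil_cue_delta_mm,
      pupil_mean_other = pp$pupil_base_mm,
      craving = craving,
      relevance = relevance,
      craving_latent_mean = crav_mean + pp$craving_latent
    )
    list(session = session, truth = truth)
  })
}

#' Simulate a single scene
#'
#' Convenience wrapper around the participant simulator for single-scene
#' studies (parameter-recovery experiments): participant-level latents and the
#' scene realisation are both drawn from `seed`.
#'
#' @param config A `sim_config`.
#' @param scene_name Scene to simulate.
#' @param seed Integer seed for this scene.
#' @return List with `session` (a `scene_session`) and `truth`.
#' @export
simulate_scene <- function(config, scene_name, seed) {
  validate_sim_config(config)
  catalog <- make_scene_catalog(scene_name,
                                driving_reversal = config$driving_reversal)
  cfg2 <- config
  cfg2$seed <- seed
  pp <- participant_params(cfg2, 1L)
  sim_scene_impl(config, scene_name, pp, substream_seed(seed, 3, 1, 1), catalog)
}

#' Simulate one participant's full session
#'
#' Draws participant-level latents (baseline pupil size, blink rate, craving
#' level, use episodes, dwell bias), a pseudorandomised scene order, and six
#' scene sessions. Deterministic given `(config, participant_index)`.
#'
#' @param config A `sim_config`.
#' @param participant_index 1-based participant index.
#' @return List with `log` (a `participant_log`) and `truth` (ground-truth
#'   record: participant latents plus per-scene realised blinks, dwell totals,
#'   true category pupil means, and survey latents).
#' @export
simulate_participant <- function(config, participant_index) {
  validate_sim_config(config)
  pp <- participant_params(config, participant_index)
  order <- draw_scene_order(substream_seed(config$seed, 2, participant_index))
  catalogs <- scene_catalogs(driving_reversal = config$driving_reversal)
  sessions <- list()
  truths <- list()
  for (i in seq_along(order)) {
    nm <- order[i]
    res <- sim_scene_impl(config, nm, pp,
                          substream_seed(config$seed, 3, participant_index, i),
                          catalogs[[nm]])
    sessions[[nm]] <- res$session
    truths[[nm]] <- res$truth
  }
  baseline <- with_seed(substream_seed(config$seed, 4, participant_index), {
    c(mood = as.integer(round(rtruncnorm(1, 35, 20, 0, 100))),
      anxiety = as.integer(round(rtruncnorm(1, 30, 20, 0, 100))))
  })
  log <- participant_log(
    participant_id = sprintf("sim%03d", participant_index),
    scene_order = order,
    sessions = sessions,
    baseline_surveys = baseline
  )
  truth <- list(
    participant_id = log$participant_id,
    pupil_base_mm = pp$pupil_base_mm,
    blink_rate_per_min = pp$blink_rate_per_min,
    craving_latent = pp$craving_latent,
    use_episodes = pp$use_episodes,
    dwell_bias = pp$dwell_bias,
    scenes = truths
  )
  list(log = log, truth = truth)
}

#' Simulate a cohort
#'
#' @param config A `sim_config`.
#' @return List of length `n_participants`, each element a
#'   `list(log, truth)` from [simulate_participant()].
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_participants < 1) {
    stop("n_participants must be >= 1 to simulate a cohort", call. = FALSE)
  }
  lapply(seq_len(config$n_participants),
         function(i) simulate_participant(config, i))
}

#' Paper-like preset configuration
#'
#' A 31-participant cohort with the Driving-scene reversal enabled (the
#' street-video panel categorised Neutral and highly attractive) and a mild
#' positive coupling of use episodes to dwell bias, so the simulated battery
#' reproduces the qualitative sign pattern of the pilot results.
#'
#' @param seed Integer master seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_paper <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_participants = 31L, driving_reversal = TRUE,
               use_episodes_slope = 3e-4)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
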