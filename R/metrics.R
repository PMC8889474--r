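# Per-scene and per-participant metric extraction: ties the blink, fixation,
# pupil and survey modules together into the tables the contrast battery
# consumes.

#' Extract all eye metrics for one scene
#'
#' @param session A `scene_session`.
#' @param catalog The matching scene catalog.
#' @param mode Blink candidate mode (see [blink_candidates()]).
#' @param margin_ms Pupil exclusion margin (see [pupil_by_category()]).
#' @return One-row tibble: blink summary, per-category fixation totals/means,
#'   attentional bias, per-category pupil means, and post-scene survey values.
#' @export
process_scene <- function(session, catalog, mode = "BOTH_EYES", margin_ms = 0) {
  blinks <- detect_blinks(session$samples, mode)
  bsum <- summarize_blinks(blinks, session)
  ledger <- accumulate_fixations(session$events, catalog, session$duration_ms)
  fix <- fixation_indices(ledger)
  pup <- pupil_by_category(session$samples, blinks, catalog, margin_ms, mode)
  fx <- fix$by_category
  pc <- pup$by_category
  resp <- session$events[session$events$kind == "survey", ]
  getv <- function(scale) {
    v <- vapply(resp$payload, function(p) {
      if (identical(p$scale, scale)) as.numeric(p$value) else NA_real_
    }, numeric(1))
    if (any(!is.na(v))) v[!is.na(v)][1] else NA_real_
  }
  fast_tibble(
    scene_name = session$scene_name,
    scene_type = session$scene_type,
    duration_ms = session$duration_ms,
    blink_count = bsum$blink_count,
    ebr_per_min = bsum$ebr_per_min,
    discarded_short = bsum$discarded_short,
    discarded_long = bsum$discarded_long,
    discarded_truncated = bsum$discarded_truncated,
    fix_active_ms = fx$total_ms[fx$category == "Active"],
    fix_neutral_ms = fx$total_ms[fx$category == "Neutral"],
    fix_misc_ms = fx$total_ms[fx$category == "Miscellaneous"],
    fix_background_ms = fx$total_ms[fx$category == "Background"],
    fix_active_mean_ms = fx$mean_ms[fx$category == "Active"],
    fix_neutral_mean_ms = fx$mean_ms[fx$category == "Neutral"],
    bias_ms = fix$bias_ms,
    pupil_active_mm = pc$mean_mm[pc$category == "Active"],
    pupil_neutral_mm = pc$mean_mm[pc$category == "Neutral"],
    pupil_excluded_samples = pup$n_excluded_samples,
    craving = getv("craving"),
    relevance = getv("relevance")
  )
}

#' Extract all eye metrics for one participant
#'
#' @param log A `participant_log`.
#' @param catalogs Named list of scene catalogs.
#' @inheritParams process_scene
#' @return Tibble with one row per scene (columns of [process_scene()] plus
#'   `participant`).
#' @export
process_participant <- function(log, catalogs = scene_catalogs(),
                                mode = "BOTH_EYES", margin_ms = 0) {
  rows <- lapply(names(log$sessions), function(nm) {
    process_scene(log$sessions[[nm]], catalogs[[nm]], mode, margin_ms)
  })
  out <- dplyr::bind_rows(rows)
  out$participant <- log$participant_id
  dplyr::relocate(out, "participant")
}

#' Per-participant wide metric table for a cohort
#'
#' Pools the scene-level metrics into the per-participant quantities the
#' contrast battery tests: mean craving per scene type; mean Active/Neutral
#' cue fixation totals over the three Active scenes (pooled) and per scene;
#' the attentional-bias score; pooled and per-scene cue pupil means; and mean
#' EBR per scene type plus per-Active-scene EBR.
#'
#' @param logs List of `participant_log`s (or of `list(log, truth)` pairs as
#'   returned by [simulate_cohort()]).
#' @inheritParams process_participant
#' @return List with `scenes` (long scene-level tibble) and `participants`
#'   (wide per-participant tibble).
#' @export
cohort_metrics <- function(logs, catalogs = scene_catalogs(),
                           mode = "BOTH_EYES", margin_ms = 0) {
  logs <- lapply(logs, function(x) if (inherits(x, "participant_log")) x else x$log)
  scenes <- dplyr::bind_rows(lapply(logs, process_participant,
                                    catalogs = catalogs, mode = mode,
                                    margin_ms = margin_ms))
  wide_one <- function(pid) {
    s <- scenes[scenes$participant == pid, ]
    act <- s[s$scene_type == "Active", ]
    neu <- s[s$scene_type == "Neutral", ]
    per_scene <- function(col, nm) {
      v <- s[[col]][s$scene_name == nm]
      if (length(v)) v else NA_real_
    }
    tibble::tibble(
      participant = pid,
      craving_active = mean(act$craving, na.rm = TRUE),
      craving_neutral = mean(neu$craving, na.rm = TRUE),
      bias_score = mean(act$bias_ms, na.rm = TRUE),
      fix_active_pooled = mean(act$fix_active_ms, na.rm = TRUE),
      fix_neutral_pooled = mean(act$fix_neutral_ms, na.rm = TRUE),
      fix_active_Patio = per_scene("fix_active_ms", "Patio"),
      fix_neutral_Patio = per_scene("fix_neutral_ms", "Patio"),
      fix_active_OutdoorBBQ = per_scene("fix_active_ms", "OutdoorBBQ"),
      fix_neutral_OutdoorBBQ = per_scene("fix_neutral_ms", "OutdoorBBQ"),
      fix_active_Driving = per_scene("fix_active_ms", "Driving"),
      fix_neutral_Driving = per_scene("fix_neutral_ms", "Driving"),
      pupil_active_pooled = mean(act$pupil_active_mm, na.rm = TRUE),
      pupil_neutral_pooled = mean(act$pupil_neutral_mm, na.rm = TRUE),
      pupil_active_Patio = per_scene("pupil_active_mm", "Patio"),
      pupil_neutral_Patio = per_scene("pupil_neutral_mm", "Patio"),
      pupil_active_OutdoorBBQ = per_scene("pupil_active_mm", "OutdoorBBQ"),
      pupil_neutral_OutdoorBBQ = per_scene("pupil_neutral_mm", "OutdoorBBQ"),
      pupil_active_Driving = per_scene("pupil_active_mm", "Driving"),
      pupil_neutral_Driving = per_scene("pupil_neutral_mm", "Driving"),
      ebr_active = mean(act$ebr_per_min, na.rm = TRUE),
      ebr_neutral = mean(neu$ebr_per_min, na.rm = TRUE),
      ebr_Patio = per_scene("ebr_per_min", "Patio"),
      ebr_OutdoorBBQ = per_scene("ebr_per_min", "OutdoorBBQ"),
      ebr_Driving = per_scene("ebr_per_min", "Driving")
    )
  }
  participants <- dplyr::bind_rows(lapply(unique(scenes$participant), wide_one))
  list(scenes = scenes, participants = participants)
}
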