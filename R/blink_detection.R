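# Blink detection from pupil-diameter dropout runs.
#
# A missing pupil-diameter reading marks a possible complete eyelid closure.
# Maximal contiguous runs of missing samples are blink candidates; a candidate
# shorter than 50 ms is discarded as tracker noise, one longer than 500 ms as a
# microsleep, and durations of exactly 50 or 500 ms count as blinks (the
# discard rules are strict inequalities). Candidates truncated by the end of
# the scene have undefined duration and are tallied separately.

#' Classify all missing-pupil candidate runs in a scene timeseries
#'
#' @param samples Scene timeseries on the 10-ms grid (see [scene_session()]).
#' @param mode `"BOTH_EYES"` (a candidate tick has both pupils missing;
#'   default) or `"EITHER_EYE"` (at least one missing).
#' @return Tibble with one row per maximal run: `onset_ms`, `duration_ms`,
#'   `n_ticks`, `class` (`"blink"`, `"short"`, `"long"`, `"truncated"`) and
#'   `object_at_onset` (last named gazed object at/before onset, else
#'   `"BACKGROUND"`).
#' @export
blink_candidates <- function(samples, mode = c("BOTH_EYES", "EITHER_EYE")) {
  mode <- match.arg(mode)
  t <- samples$t_ms
  if (length(t) > 1 && any(diff(t) != SAMPLE_PERIOD_MS)) {
    stop("samples must lie on a contiguous ", SAMPLE_PERIOD_MS, "-ms grid",
         call. = FALSE)
  }
  miss_l <- is.na(samples$pupil_l_mm)
  miss_r <- is.na(samples$pupil_r_mm)
  miss <- if (mode == "BOTH_EYES") miss_l & miss_r else miss_l | miss_r
  empty <- fast_tibble(onset_ms = integer(), duration_ms = integer(),
                       n_ticks = integer(), class = character(),
                       object_at_onset = character())
  if (!any(miss)) return(empty)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  n_ticks <- ends - starts + 1L
  duration_ms <- n_ticks * SAMPLE_PERIOD_MS
  class <- ifelse(duration_ms < 50, "short",
                  ifelse(duration_ms > 500, "long", "blink"))
  # A run reaching the final sample has an undefined true duration.
  class[ends == length(miss)] <- "truncated"
  # index of the last named gazed object at or before each tick
  last_named <- cummax(ifelse(nzchar(samples$object), seq_along(miss), 0L))
  j <- last_named[starts]
  object_at_onset <- ifelse(j > 0, samples$object[pmax(j, 1L)], BACKGROUND)
  fast_tibble(onset_ms = t[starts],
              duration_ms = as.integer(duration_ms),
              n_ticks = as.integer(n_ticks),
              class = class,
              object_at_onset = object_at_onset)
}

#' Detect blinks in a scene timeseries
#'
#' Returns the candidates classified as blinks (duration in \[50, 500\] ms,
#' inclusive). The full classified candidate table is attached as attribute
#' `"candidates"` so downstream accounting (discard tallies, pupil-sample
#' exclusion) does not need to rescan the trace.
#'
#' @inheritParams blink_candidates
#' @return Tibble of blink events (`onset_ms`, `duration_ms`, `n_ticks`,
#'   `object_at_onset`), time-ordered and disjoint, with attribute
#'   `"candidates"`.
#' @export
detect_blinks <- function(samples, mode = c("BOTH_EYES", "EITHER_EYE")) {
  mode <- match.arg(mode)
  cand <- blink_candidates(samples, mode)
  out <- cand[cand$class == "blink",
              c("onset_ms", "duration_ms", "n_ticks", "object_at_onset")]
  attr(out, "candidates") <- cand
  out
}

#' Summarise blink events for one scene
#'
#' @param events Output of [detect_blinks()] on `scene$samples`.
#' @param scene The `scene_session` the events came from.
#' @return One-row tibble: `scene_name`, `blink_count`, `ebr_per_min`
#'   (blink count divided by the scene duration in minutes, exactly),
#'   `discarded_short`, `discarded_long`, `discarded_truncated`.
#' @export
summarize_blinks <- function(events, scene) {
  cand <- attr(events, "candidates")
  if (is.null(cand)) {
    cand <- blink_candidates(scene$samples)
  }
  minutes <- scene$duration_ms / 60000
  fast_tibble(
    scene_name = scene$scene_name,
    blink_count = nrow(events),
    ebr_per_min = nrow(events) / minutes,
    discarded_short = sum(cand$class == "short"),
    discarded_long = sum(cand$class == "long"),
    discarded_truncated = sum(cand$class == "truncated")
  )
}
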