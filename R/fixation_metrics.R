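# Fixation-time accounting by cue category.
#
# The fixation unit is the object-switch interval: each gaze_switch event to
# object o at time t contributes (t_next - t) ms to o's cumulative dwell,
# where t_next is the next switch or the scene end for the final segment.
# Cumulative dwell is kept per object within four category dictionaries
# (Active, Neutral, Miscellaneous, Background). Time before the first switch
# is assigned to no object.

gaze_switch_objects <- function(events) {
  idx <- which(events$kind == "gaze_switch")
  fast_tibble(
    t_ms = events$t_ms[idx],
    object = vapply(events$payload[idx], function(p) as.character(p$object),
                    character(1))
  )
}

#' Accumulate per-object fixation time from gaze-switch events
#'
#' @param events Event tibble of a scene (only `gaze_switch` rows are used),
#'   time-ordered within \[0, duration_ms\].
#' @param catalog Scene catalog; every switched-to object must appear in it.
#' @param duration_ms Scene duration in ms.
#' @return A `fixation_ledger`: tibble with columns `object`, `category`,
#'   `fixation_ms`, one row per distinct gazed object, plus attributes
#'   `duration_ms` and `uncovered_ms` (time before the first switch).
#' @export
accumulate_fixations <- function(events, catalog, duration_ms) {
  sw <- gaze_switch_objects(events)
  if (nrow(sw) > 0 && (any(diff(sw$t_ms) < 0) || min(sw$t_ms) < 0 ||
                       max(sw$t_ms) > duration_ms)) {
    stop("gaze_switch events must be time-ordered within [0, duration_ms]",
         call. = FALSE)
  }
  category <- object_category(sw$object, catalog)  # errors on unknown objects
  if (nrow(sw) == 0) {
    ledger <- fast_tibble(object = character(), category = character(),
                          fixation_ms = numeric())
    attr(ledger, "duration_ms") <- duration_ms
    attr(ledger, "uncovered_ms") <- duration_ms
    class(ledger) <- c("fixation_ledger", class(ledger))
    return(ledger)
  }
  seg_ms <- diff(c(sw$t_ms, duration_ms))
  totals <- rowsum(seg_ms, group = sw$object)
  ledger <- fast_tibble(
    object = rownames(totals),
    category = object_category(rownames(totals), catalog),
    fixation_ms = as.numeric(totals[, 1])
  )
  ledger <- ledger[order(ledger$object), ]
  attr(ledger, "duration_ms") <- duration_ms
  attr(ledger, "uncovered_ms") <- sw$t_ms[1]
  class(ledger) <- c("fixation_ledger", class(ledger))
  ledger
}

#' Total and mean fixation-time indices per cue category
#'
#' Totals sum the cumulative dwell of every object in a category; means divide
#' the total by the number of distinct objects gazed in that category.
#' Categories with no gazed object have an undefined mean (`NA`, not zero) and
#' a zero total. The attentional-bias index `bias_ms` is the Active-category
#' total minus the Neutral-category total, in milliseconds.
#'
#' @param ledger A `fixation_ledger` from [accumulate_fixations()].
#' @param duration_ms Scene duration in ms (defaults to the ledger attribute).
#' @return List with `by_category` (tibble `category`, `total_ms`, `mean_ms`,
#'   `n_objects`), `bias_ms`, and `uncovered_ms`.
#' @export
fixation_indices <- function(ledger, duration_ms = attr(ledger, "duration_ms")) {
  cat_f <- factor(ledger$category, levels = CUE_CATEGORIES)
  total_ms <- as.numeric(tapply(ledger$fixation_ms, cat_f, sum, default = 0))
  n_objects <- as.integer(table(cat_f))
  by_cat <- fast_tibble(
    category = CUE_CATEGORIES,
    total_ms = total_ms,
    mean_ms = ifelse(n_objects > 0, total_ms / n_objects, NA_real_),
    n_objects = n_objects
  )
  list(
    by_category = by_cat,
    bias_ms = by_cat$total_ms[by_cat$category == "Active"] -
      by_cat$total_ms[by_cat$category == "Neutral"],
    uncovered_ms = attr(ledger, "uncovered_ms") %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-participant attentional-bias score
#'
#' The mean, over the three Active scenes, of the per-scene Active-minus-Neutral
#' cue fixation-time difference (ms). Positive values indicate more dwell on
#' nicotine-product cues than on neutral cues. If an Active scene is missing
#' from the log, the mean is taken over the available scenes with a warning.
#'
#' @param log A `participant_log`.
#' @param catalogs Named list of scene catalogs (default [scene_catalogs()]).
#' @return List: `score_ms`, `n_scenes`, and `per_scene` (named numeric of
#'   per-scene biases).
#' @export
attentional_bias_score <- function(log, catalogs = scene_catalogs()) {
  present <- intersect(ACTIVE_SCENES, names(log$sessions))
  if (length(present) < length(ACTIVE_SCENES)) {
    warning("attentional bias computed over ", length(present),
            " of 3 Active scenes for participant ", log$participant_id,
            call. = FALSE)
  }
  per_scene <- vapply(present, function(nm) {
    ses <- log$sessions[[nm]]
    led <- accumulate_fixations(ses$events, catalogs[[nm]], ses$duration_ms)
    fixation_indices(led)$bias_ms
  }, numeric(1))
  list(score_ms = if (length(per_scene)) mean(per_scene) else NA_real_,
       n_scenes = length(per_scene),
       per_scene = per_scene)
}
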