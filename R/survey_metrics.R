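# In-task VAS survey aggregation and questionnaire scoring.

#' Extract the post-scene survey ratings from a participant log
#'
#' @param log A `participant_log`.
#' @return Tibble: `scene_name`, `scene_type`, `scale`, `value`.
#' @export
survey_responses <- function(log) {
  rows <- lapply(names(log$sessions), function(nm) {
    ses <- log$sessions[[nm]]
    idx <- which(ses$events$kind == "survey")
    if (length(idx) == 0) return(NULL)
    tibble::tibble(
      scene_name = nm,
      scene_type = ses$scene_type,
      scale = vapply(ses$events$payload[idx],
                     function(p) as.character(p$scale), character(1)),
      value = vapply(ses$events$payload[idx],
                     function(p) as.numeric(p$value), numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}

#' Mean in-task craving ratings for Active and Neutral scenes
#'
#' Averages the post-scene 0-100 craving VAS ratings over the three Active and
#' the three Neutral scenes. If a scene's rating is missing the mean is taken
#' over the available scenes and the participant is flagged.
#'
#' @param log A `participant_log`.
#' @return List: `craving_active_mean`, `craving_neutral_mean`, `per_scene`
#'   tibble (craving and relevance per scene), `n_active`, `n_neutral`,
#'   `flagged` (TRUE when any of the six craving ratings is missing).
#' @export
aggregate_craving <- function(log) {
  resp <- survey_responses(log)
  crav <- resp[resp$scale == "craving", ]
  act <- crav$value[crav$scene_type == "Active"]
  neu <- crav$value[crav$scene_type == "Neutral"]
  flagged <- length(act) < 3 || length(neu) < 3
  if (flagged) {
    warning("participant ", log$participant_id, " is missing ",
            6 - length(act) - length(neu), " craving rating(s)", call. = FALSE)
  }
  list(
    craving_active_mean = if (length(act)) mean(act) else NA_real_,
    craving_neutral_mean = if (length(neu)) mean(neu) else NA_real_,
    per_scene = resp,
    n_active = length(act),
    n_neutral = length(neu),
    flagged = flagged
  )
}

#' Score a questionnaire by simple averaging to a 0-100 scale
#'
#' Implements the averaging rule used for the presence (IPQ) and VR-sickness
#' (VRSQ) questionnaires: the item mean is rescaled linearly from
#' \[0, scale_max\] to \[0, 100\]. Item wording and subscale membership are
#' instrument-specific and supplied by the caller.
#'
#' @param item_scores Numeric vector of item responses, each in
#'   \[0, scale_max\]; must be non-empty.
#' @param scale_max Maximum of the item response scale (e.g. 6 for a 0-6
#'   Likert item).
#' @return A score in \[0, 100\].
#' @export
score_average_scale <- function(item_scores, scale_max) {
  if (length(item_scores) == 0) {
    stop("item_scores must be non-empty", call. = FALSE)
  }
  if (scale_max <= 0) stop("scale_max must be positive", call. = FALSE)
  if (any(item_scores < 0 | item_scores > scale_max)) {
    stop("item scores must lie in [0, scale_max]", call. = FALSE)
  }
  100 * mean(item_scores) / scale_max
}

#' Score questionnaire items from a long item table
#'
#' Items arrive in long form — one row per participant, instrument and item —
#' either as a tibble or as a CSV file with columns
#' `participant, instrument, item, value`. Each instrument is scored by
#' [score_average_scale()] with its caller-supplied response-scale maximum
#' (item wording and subscale membership are instrument-specific and not
#' bundled).
#'
#' @param items A tibble, or a path to a CSV file, with columns
#'   `participant`, `instrument`, `item`, `value`.
#' @param scale_max Named numeric vector mapping instrument name to its item
#'   scale maximum, e.g. `c(IPQ = 6, VRSQ = 3)`.
#' @return Tibble: `participant`, `instrument`, `score` (0-100), `n_items`.
#' @export
score_questionnaires <- function(items, scale_max) {
  if (is.character(items) && length(items) == 1) {
    items <- readr::read_csv(items, show_col_types = FALSE, progress = FALSE)
  }
  needed <- c("participant", "instrument", "item", "value")
  if (!all(needed %in% names(items))) {
    stop("items must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  missing_max <- setdiff(unique(items$instrument), names(scale_max))
  if (length(missing_max)) {
    stop("no scale_max given for instrument(s): ",
         paste(missing_max, collapse = ", "), call. = FALSE)
  }
  groups <- split(items, paste(items$participant, items$instrument, sep = "\r"))
  rows <- lapply(groups, function(g) {
    tibble::tibble(
      participant = g$participant[1],
      instrument = g$instrument[1],
      score = score_average_scale(g$value, scale_max[[g$instrument[1]]]),
      n_items = nrow(g)
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$participant, out$instrument), ]
}
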