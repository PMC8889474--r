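#' @importFrom stats rnorm rexp rpois runif rlnorm qnorm pnorm dnorm pt sd
#'   integrate cor.test t.test complete.cases setNames
#' @importFrom utils head tail
NULL

# Sampling grid of the tracker timeseries: one sample every 10 ms (100 Hz).
SAMPLE_PERIOD_MS <- 10L

# Fast tibble construction for hot paths (no name/recycling machinery).
fast_tibble <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = length(cols[[1]]))
}

ACTIVE_SCENES <- c("Driving", "Patio", "OutdoorBBQ")
NEUTRAL_SCENES <- c("Bus", "WaitingRoom", "Library")
ALL_SCENES <- c(ACTIVE_SCENES, NEUTRAL_SCENES)

CUE_CATEGORIES <- c("Active", "Neutral", "Miscellaneous", "Background")

# Name returned by the gaze mapper when no catalog object is gated in.
BACKGROUND <- "BACKGROUND"

# On-disk sentinel for a missing pupil-diameter / eye-openness reading.
MISSING_SENTINEL <- -1.0

#' Scene type (Active or Neutral) for a scene name
#'
#' The paradigm comprises three Active scenes containing nicotine and tobacco
#' product cues (Driving, Patio, OutdoorBBQ) and three Neutral scenes with only
#' neutral objects (Bus, WaitingRoom, Library).
#'
#' @param scene_name Character vector of scene names.
#' @return Character vector, `"Active"` or `"Neutral"`.
#' @export
scene_type <- function(scene_name) {
  bad <- setdiff(scene_name, ALL_SCENES)
  if (length(bad) > 0) {
    stop("unknown scene name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ifelse(scene_name %in% ACTIVE_SCENES, "Active", "Neutral")
}

#' Construct one scene's worth of session data
#'
#' Bundles the 100 Hz tracker timeseries and the event stream recorded while a
#' participant was in a single scene. Timestamps are scene-relative integer
#' milliseconds, 0-based. Missing pupil/openness readings are `NA` internally.
#'
#' @param scene_name One of Driving, Patio, OutdoorBBQ, Bus, WaitingRoom, Library.
#' @param samples Tibble with columns `t_ms, gx, gy, gz, hx, hy, hz, fx, fy, fz,
#'   pupil_l_mm, pupil_r_mm, open_l, open_r, object`.
#' @param events Tibble with columns `t_ms` (integer), `kind` (one of
#'   `gaze_switch`, `blink`, `button`, `survey`) and `payload` (list column).
#' @param duration_ms Scene duration in ms (default 300000, i.e. 5 minutes).
#' @return A `scene_session` object (list).
#' @export
scene_session <- function(scene_name, samples, events, duration_ms = 300000L) {
  x <- structure(
    list(
      scene_name = scene_name,
      scene_type = scene_type(scene_name),
      duration_ms = as.integer(duration_ms),
      samples = tibble::as_tibble(samples),
      events = tibble::as_tibble(events)
    ),
    class = "scene_session"
  )
  validate_scene_session(x)
  x
}

#' Validate a scene_session against its invariants
#'
#' Checks the sampling grid (timestamps strictly increasing multiples of 10 ms),
#' pupil-diameter range, head-direction unit norm, event kinds, and that all
#' timestamps lie within the scene duration.
#'
#' @param x A `scene_session`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_scene_session <- function(x) {
  stopifnot(inherits(x, "scene_session"))
  if (!x$scene_name %in% ALL_SCENES) {
    stop("unknown scene name: ", x$scene_name, call. = FALSE)
  }
  if (x$scene_type != scene_type(x$scene_name)) {
    stop("scene_type inconsistent with scene_name", call. = FALSE)
  }
  s <- x$samples
  if (nrow(s) > 0) {
    t <- s$t_ms
    if (any(t %% SAMPLE_PERIOD_MS != 0)) {
      stop("sample timestamps must be multiples of ", SAMPLE_PERIOD_MS, " ms",
           call. = FALSE)
    }
    if (any(diff(t) <= 0)) {
      stop("sample timestamps must be strictly increasing", call. = FALSE)
    }
    if (min(t) < 0 || max(t) > x$duration_ms) {
      stop("sample timestamps outside [0, duration_ms]", call. = FALSE)
    }
    for (col in c("pupil_l_mm", "pupil_r_mm")) {
      v <- s[[col]]
      if (any(!is.na(v) & (v <= 0 | v >= 10))) {
        stop(col, " values must lie in (0, 10) mm when present", call. = FALSE)
      }
    }
    fwd_norm <- sqrt(s$fx^2 + s$fy^2 + s$fz^2)
    if (any(abs(fwd_norm - 1) > 1e-6)) {
      stop("head forward direction must have unit norm (tol 1e-6)", call. = FALSE)
    }
  }
  e <- x$events
  if (nrow(e) > 0) {
    if (any(!e$kind %in% c("gaze_switch", "blink", "button", "survey"))) {
      stop("event kind must be gaze_switch, blink, button or survey", call. = FALSE)
    }
    if (min(e$t_ms) < 0 || max(e$t_ms) > x$duration_ms) {
      stop("event timestamps outside [0, duration_ms]", call. = FALSE)
    }
    sv <- e$payload[e$kind == "survey"]
    vals <- vapply(sv, function(p) as.numeric(p$value), numeric(1))
    if (length(vals) && any(vals != round(vals) | vals < 0 | vals > 100)) {
      stop("survey values must be integers in [0, 100]", call. = FALSE)
    }
  }
  invisible(x)
}

#' Construct a participant-level session log
#'
#' @param participant_id Opaque string identifier.
#' @param scene_order Character vector of the 6 scene names in presentation
#'   order; must alternate Active/Neutral starting with Active, no repeats.
#' @param sessions Named list of `scene_session`s, keyed by scene name.
#' @param baseline_surveys Named numeric vector of the pre-task VAS ratings
#'   (mood, anxiety), each in \[0, 100\].
#' @return A `participant_log` object.
#' @export
participant_log <- function(participant_id, scene_order, sessions,
                            baseline_surveys = c(mood = NA_real_, anxiety = NA_real_)) {
  x <- structure(
    list(
      participant_id = as.character(participant_id),
      scene_order = as.character(scene_order),
      sessions = sessions,
      baseline_surveys = baseline_surveys
    ),
    class = "participant_log"
  )
  validate_participant_log(x)
  x
}

#' Validate a participant_log against its invariants
#'
#' @param x A `participant_log`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_participant_log <- function(x) {
  stopifnot(inherits(x, "participant_log"))
  ord <- x$scene_order
  if (length(ord) != 6 || anyDuplicated(ord) > 0) {
    stop("scene_order must list 6 distinct scenes", call. = FALSE)
  }
  types <- scene_type(ord)
  if (!identical(types, rep(c("Active", "Neutral"), 3))) {
    stop("scene_order must alternate Active/Neutral starting with Active",
         call. = FALSE)
  }
  if (length(x$sessions) == 0) {
    stop("sessions mapping must be non-empty", call. = FALSE)
  }
  if (!all(names(x$sessions) %in% ALL_SCENES)) {
    stop("sessions keyed by unknown scene name", call. = FALSE)
  }
  for (s in x$sessions) validate_scene_session(s)
  invisible(x)
}

sample_columns <- c("t_ms", "gx", "gy", "gz", "hx", "hy", "hz",
                    "fx", "fy", "fz", "pupil_l_mm", "pupil_r_mm",
                    "open_l", "open_r", "object")

#' Write a participant log to disk
#'
#' One directory per participant: `manifest.json` (id, scene order, file paths,
#' baseline surveys), per scene a `<scene>_samples.csv` timeseries (missing
#' pupil/openness encoded as -1.0, no gazed object as an empty field) and a
#' `<scene>_events.jsonl` event stream (one JSON object per line).
#'
#' @param log A valid `participant_log`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  validate_participant_log(log)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create log directory: ", path, call. = FALSE)
  scene_files <- list()
  for (nm in names(log$sessions)) {
    ses <- log$sessions[[nm]]
    s <- ses$samples
    for (col in c("pupil_l_mm", "pupil_r_mm", "open_l", "open_r")) {
      s[[col]][is.na(s[[col]])] <- MISSING_SENTINEL
    }
    samples_file <- paste0(nm, "_samples.csv")
    events_file <- paste0(nm, "_events.jsonl")
    readr::write_csv(s[sample_columns], file.path(path, samples_file),
                     progress = FALSE)
    lines <- vapply(seq_len(nrow(ses$events)), function(i) {
      jsonlite::toJSON(
        list(t_ms = ses$events$t_ms[i],
             kind = ses$events$kind[i],
             payload = ses$events$payload[[i]]),
        auto_unbox = TRUE, digits = NA, null = "null")
    }, character(1))
    writeLines(lines, file.path(path, events_file))
    scene_files[[nm]] <- list(scene = nm,
                              type = ses$scene_type,
                              duration_ms = ses$duration_ms,
                              samples = samples_file,
                              events = events_file)
  }
  manifest <- list(
    participant_id = log$participant_id,
    scene_order = log$scene_order,
    scenes = unname(scene_files),
    baseline_surveys = as.list(log$baseline_surveys)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a participant log from disk
#'
#' Inverse of [write_session_log()]. The missing-value sentinel (-1.0, an empty
#' field, or JSON null) in pupil-diameter and eye-openness columns is
#' normalised to `NA`. The returned log passes all type invariants; malformed
#' rows and non-monotone timestamps raise errors naming the offending file.
#'
#' @param path Directory previously produced by [write_session_log()].
#' @return A `participant_log`.
#' @export
read_session_log <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json under ", path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  sessions <- list()
  for (sc in man$scenes) {
    nm <- sc$scene
    if (!nm %in% ALL_SCENES) {
      stop("unknown scene name in manifest: ", nm, call. = FALSE)
    }
    sfile <- file.path(path, sc$samples)
    samples <- suppressWarnings(readr::read_csv(
      sfile,
      col_types = readr::cols(
        t_ms = readr::col_integer(),
        object = readr::col_character(),
        .default = readr::col_double()
      ),
      progress = FALSE, show_col_types = FALSE
    ))
    probs <- readr::problems(samples)
    if (nrow(probs) > 0) {
      stop("malformed row in ", sfile, " (line ", probs$row[1] + 1, "): ",
           probs$expected[1], call. = FALSE)
    }
    if (anyNA(samples$t_ms)) {
      bad <- which(is.na(samples$t_ms))[1]
      stop("malformed timestamp in ", sfile, " (line ", bad + 1, ")", call. = FALSE)
    }
    samples$object[is.na(samples$object)] <- ""
    for (col in c("pupil_l_mm", "pupil_r_mm", "open_l", "open_r")) {
      v <- samples[[col]]
      v[!is.na(v) & v == MISSING_SENTINEL] <- NA_real_
      samples[[col]] <- v
    }
    efile <- file.path(path, sc$events)
    lines <- readLines(efile)
    lines <- lines[nzchar(lines)]
    evs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$t_ms) || is.null(rec$kind)) {
        stop("malformed event in ", efile, " (line ", i, ")", call. = FALSE)
      }
      rec
    })
    events <- tibble::tibble(
      t_ms = vapply(evs, function(e) as.integer(e$t_ms), integer(1)),
      kind = vapply(evs, function(e) as.character(e$kind), character(1)),
      payload = lapply(evs, function(e) e$payload)
    )
    sessions[[nm]] <- scene_session(nm, samples, events,
                                    duration_ms = sc$duration_ms)
  }
  participant_log(
    participant_id = man$participant_id,
    scene_order = unlist(man$scene_order),
    sessions = sessions,
    baseline_surveys = unlist(man$baseline_surveys)
  )
}
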