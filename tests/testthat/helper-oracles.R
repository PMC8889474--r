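# Independent brute-force oracles and fixture builders used across tests.
# The oracles deliberately use naive explicit loops, independent of the
# vectorised implementations they check.

# Build a minimal valid sample frame on the 10-ms grid.
make_samples <- function(pupil_l, pupil_r, object = "x",
                         t0 = 0L) {
  n <- length(pupil_l)
  if (length(object) == 1) object <- rep(object, n)
  tibble::tibble(
    t_ms = t0 + seq(0L, by = 10L, length.out = n),
    gx = 0, gy = 1, gz = 2, hx = 0, hy = 1.6, hz = 0,
    fx = 0, fy = 0, fz = 1,
    pupil_l_mm = pupil_l, pupil_r_mm = pupil_r,
    open_l = ifelse(is.na(pupil_l), NA_real_, 0.95),
    open_r = ifelse(is.na(pupil_r), NA_real_, 0.95),
    object = object
  )
}

# Samples with missing runs at given tick indices (1-based), both eyes unless
# eye = "L"/"R".
samples_with_runs <- function(n, runs, value = 4) {
  pl <- rep(value, n)
  pr <- rep(value, n)
  for (r in runs) {
    idx <- r$start:(r$start + r$len - 1)
    if (is.null(r$eye) || r$eye %in% c("B", "L")) pl[idx] <- NA_real_
    if (is.null(r$eye) || r$eye %in% c("B", "R")) pr[idx] <- NA_real_
  }
  make_samples(pl, pr)
}

# Naive per-tick scan classifying missing runs; mirrors the blink rules
# by walking the trace one tick at a time.
oracle_blink_scan <- function(samples, mode = "BOTH_EYES") {
  ml <- is.na(samples$pupil_l_mm)
  mr <- is.na(samples$pupil_r_mm)
  miss <- if (mode == "BOTH_EYES") ml & mr else ml | mr
  n <- length(miss)
  out <- list()
  i <- 1
  while (i <= n) {
    if (!miss[i]) {
      i <- i + 1
      next
    }
    j <- i
    while (j < n && miss[j + 1]) j <- j + 1
    dur <- (j - i + 1) * 10
    cls <- if (j == n) "truncated"
    else if (dur < 50) "short"
    else if (dur > 500) "long"
    else "blink"
    obj <- "BACKGROUND"
    for (k in seq(i, 1)) {
      if (nzchar(samples$object[k])) {
        obj <- samples$object[k]
        break
      }
    }
    out[[length(out) + 1]] <- data.frame(
      onset_ms = as.integer(samples$t_ms[i]), duration_ms = as.integer(dur),
      n_ticks = as.integer(j - i + 1), class = cls, object_at_onset = obj,
      stringsAsFactors = FALSE
    )
    i <- j + 1
  }
  if (length(out) == 0) {
    return(data.frame(onset_ms = integer(), duration_ms = integer(),
                      n_ticks = integer(), class = character(),
                      object_at_onset = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Brute-force per-object interval summation for gaze-switch sequences.
oracle_fixation_sums <- function(times, objects, duration_ms) {
  out <- numeric(0)
  for (obj in unique(objects)) {
    tot <- 0
    for (i in seq_along(times)) {
      if (objects[i] == obj) {
        t_next <- if (i < length(times)) times[i + 1] else duration_ms
        tot <- tot + (t_next - times[i])
      }
    }
    out[obj] <- tot
  }
  out
}

# Exhaustive minimum-angle scan over a catalog (no gating shortcuts).
oracle_gaze_scan <- function(origin, direction, catalog, threshold_deg) {
  best <- NULL
  for (i in seq_len(nrow(catalog))) {
    v <- c(catalog$x[i] - origin[1], catalog$y[i] - origin[2],
           catalog$z[i] - origin[3])
    dist <- sqrt(sum(v^2))
    ang <- acos(min(1, max(-1, sum(v * direction) / dist)))
    sub <- if (dist <= catalog$radius[i]) pi else asin(catalog$radius[i] / dist)
    if (ang <= max(threshold_deg * pi / 180, sub)) {
      cand <- list(ang = ang, dist = dist, name = catalog$name[i])
      if (is.null(best) ||
          cand$ang < best$ang ||
          (cand$ang == best$ang && cand$dist < best$dist) ||
          (cand$ang == best$ang && cand$dist == best$dist &&
           cand$name < best$name)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) "BACKGROUND" else best$name
}

# Event tibble from parallel vectors of gaze switches.
gaze_events <- function(times, objects) {
  tibble::tibble(
    t_ms = as.integer(times), kind = "gaze_switch",
    payload = lapply(objects, function(o) list(object = o))
  )
}

# A scene_session with no samples and hand-crafted events (survey / gaze
# bookkeeping tests that do not need a timeseries).
bare_session <- function(scene_name, events, duration_ms) {
  empty <- make_samples(numeric(0), numeric(0), object = character(0))
  scene_session(scene_name, empty, events, duration_ms)
}

survey_event <- function(t_ms, scale, value) {
  tibble::tibble(t_ms = as.integer(t_ms), kind = "survey",
                 payload = list(list(scale = scale, value = as.integer(value))))
}

# Participant log whose six scenes carry only crafted events.
bare_log <- function(events_by_scene, durations) {
  order <- c("Patio", "Bus", "OutdoorBBQ", "WaitingRoom", "Driving", "Library")
  sessions <- lapply(names(events_by_scene), function(nm) {
    bare_session(nm, events_by_scene[[nm]], durations[[nm]])
  })
  names(sessions) <- names(events_by_scene)
  participant_log("p1", order, sessions)
}
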