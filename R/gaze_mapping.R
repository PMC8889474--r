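# Gaze-to-object mapping.
#
# The original paradigm used a proprietary machine-learned selector plus naive
# raycasting as fallback. Neither is reproducible, so this module provides a
# documented angular-proximity stand-in: the gazed object is the catalog entry
# with the smallest angle between the gaze direction and the eye-to-object
# vector, among entries whose angle is within max(angle threshold, angular
# radius subtended by the object's selection sphere). A manipulation "lock"
# overrides geometry entirely: while a participant holds an object, that object
# is always the selected one.

#' Create a gaze-selection state
#'
#' @param locked_object Name of the currently held object, or `NULL`.
#' @return A `selection_state` list.
#' @export
selection_state <- function(locked_object = NULL) {
  structure(list(locked_object = locked_object), class = "selection_state")
}

#' Update the object lock from a controller button event
#'
#' A `pickup` button event sets the lock to the manipulated object; a `release`
#' clears it (idempotently); any other button leaves the state unchanged.
#'
#' @param state A `selection_state`.
#' @param event A single event record (list with `kind = "button"` and a
#'   payload carrying `action` and, for pickups, `object`).
#' @return The updated `selection_state`.
#' @export
update_lock <- function(state, event) {
  stopifnot(inherits(state, "selection_state"))
  if (!identical(event$kind, "button")) return(state)
  action <- event$payload$action
  if (identical(action, "pickup")) {
    selection_state(locked_object = event$payload$object)
  } else if (identical(action, "release")) {
    selection_state(locked_object = NULL)
  } else {
    state
  }
}

#' Map a gaze ray to a scene object
#'
#' If the selection state carries a lock, the locked object is returned
#' unconditionally. Otherwise the catalog entry minimising the angular distance
#' between `direction` and the eye-to-object vector is returned, provided that
#' angle does not exceed `max(angle_threshold_deg, angular radius subtended by
#' the entry's selection sphere)`; ties are broken by smaller Euclidean
#' distance, then lexicographic name. If no entry is gated in, the constant
#' `"BACKGROUND"` is returned.
#'
#' @param origin Numeric length-3 eye position (m).
#' @param direction Numeric length-3 unit gaze direction.
#' @param catalog Scene catalog from [make_scene_catalog()].
#' @param state A `selection_state` (default: unlocked).
#' @param angle_threshold_deg Gating half-angle in degrees, in (0, 15].
#' @return An object name, or `"BACKGROUND"`.
#' @export
map_gaze_to_object <- function(origin, direction, catalog,
                               state = selection_state(),
                               angle_threshold_deg = 3) {
  if (!is.null(state$locked_object)) {
    return(state$locked_object)
  }
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    stop("gaze direction must be unit-norm", call. = FALSE)
  }
  if (angle_threshold_deg <= 0 || angle_threshold_deg > 15) {
    stop("angle_threshold_deg must lie in (0, 15]", call. = FALSE)
  }
  dx <- catalog$x - origin[1]
  dy <- catalog$y - origin[2]
  dz <- catalog$z - origin[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  cosang <- (dx * direction[1] + dy * direction[2] + dz * direction[3]) /
    pmax(dist, .Machine$double.eps)
  ang <- acos(pmin(pmax(cosang, -1), 1))
  # Angle subtended by the selection sphere; inside the sphere everything gates.
  subtended <- ifelse(dist <= catalog$radius, pi, asin(catalog$radius / dist))
  gate <- pmax(angle_threshold_deg * pi / 180, subtended)
  ok <- which(ang <= gate)
  if (length(ok) == 0) return(BACKGROUND)
  ord <- order(ang[ok], dist[ok], catalog$name[ok])
  catalog$name[ok[ord[1]]]
}
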