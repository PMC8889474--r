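# Scene object catalogs.
#
# Each catalog lists the gaze-selectable objects of one scene: name, cue
# category (Active / Neutral / Miscellaneous / Background), 3D position
# (right-handed, meters, y up, viewer near the origin at eye height ~1.6 m),
# selection-sphere radius (m), and a dwell attractiveness weight used by the
# session simulator (relative propensity to be fixated; 1 = typical object).

catalog_entry <- function(name, category, x, y, z, radius, weight = 1) {
  tibble::tibble(name = name, category = category,
                 x = x, y = y, z = z, radius = radius, weight = weight)
}

#' Build the object catalog for one scene
#'
#' Active scenes (Driving, Patio, OutdoorBBQ) contain nicotine-product cues
#' (ashtrays, lighters, JUUL devices, cigarettes and packs, Puffbars, hookahs,
#' smoking human models) alongside neutral objects (water bottles, cellphones,
#' pens, magazines, candies, ...); Neutral scenes (Bus, WaitingRoom, Library)
#' contain no Active-category objects. Every scene also has Miscellaneous
#' furniture and a large Background entry.
#'
#' The Driving scene includes a large `street_video` background panel. Under
#' `driving_reversal = TRUE` that panel is categorised Neutral and given a high
#' dwell attractiveness, emulating sessions in which an engaging street video
#' draws gaze away from the nicotine cues and reverses the attentional-bias
#' sign in that scene.
#'
#' @param scene_name One of the six scene names.
#' @param driving_reversal Logical; see above. Only affects `"Driving"`.
#' @return A tibble with columns `name, category, x, y, z, radius, weight`.
#' @export
make_scene_catalog <- function(scene_name, driving_reversal = FALSE) {
  key <- paste0(scene_name, if (driving_reversal) "_rev" else "")
  cached <- .catalog_cache[[key]]
  if (!is.null(cached)) return(cached)
  cat <- build_scene_catalog(scene_name, driving_reversal)
  .catalog_cache[[key]] <- cat
  cat
}

.catalog_cache <- new.env(parent = emptyenv())

build_scene_catalog <- function(scene_name, driving_reversal = FALSE) {
  cat <- switch(
    scene_name,
    Patio = dplyr::bind_rows(
      catalog_entry("ashtray",        "Active",  0.6, 1.0,  1.8, 0.08),
      catalog_entry("lighter",        "Active",  0.8, 1.0,  1.7, 0.04),
      catalog_entry("cigarette_pack", "Active", -0.5, 1.0,  1.9, 0.06),
      catalog_entry("juul",           "Active", -0.7, 1.0,  1.6, 0.04),
      catalog_entry("hookah",         "Active",  1.4, 0.8,  2.4, 0.25),
      catalog_entry("water_bottle",   "Neutral", 0.3, 1.0,  1.8, 0.06),
      catalog_entry("cellphone",      "Neutral", -0.2, 1.0, 1.7, 0.06),
      catalog_entry("magazine",       "Neutral", 0.0, 0.9,  2.1, 0.12),
      catalog_entry("candy_bowl",     "Neutral", -1.0, 1.0, 2.0, 0.10),
      catalog_entry("potted_plant",   "Neutral", 1.8, 0.5,  1.2, 0.30),
      catalog_entry("patio_table",    "Miscellaneous", 0.0, 0.8, 1.9, 0.60),
      catalog_entry("patio_chair",    "Miscellaneous", -1.5, 0.6, 1.0, 0.40),
      catalog_entry("patio_backdrop", "Background", 0.0, 2.0, 8.0, 5.0, weight = 20)
    ),
    OutdoorBBQ = dplyr::bind_rows(
      catalog_entry("cigarette",      "Active",  0.5, 1.1,  1.6, 0.03),
      catalog_entry("cigarette_pack", "Active",  0.7, 1.0,  1.8, 0.06),
      catalog_entry("puffbar",        "Active", -0.4, 1.0,  1.7, 0.04),
      catalog_entry("ashtray",        "Active", -0.8, 0.9,  2.0, 0.08),
      catalog_entry("smoking_person", "Active",  2.0, 1.2,  3.5, 0.50),
      catalog_entry("soda_can",       "Neutral", 0.2, 1.0,  1.7, 0.05),
      catalog_entry("grill_tongs",    "Neutral", 1.1, 1.0,  2.2, 0.10),
      catalog_entry("pen",            "Neutral", -0.1, 1.0, 1.6, 0.03),
      catalog_entry("candy_bowl",     "Neutral", -1.2, 0.9, 1.9, 0.10),
      catalog_entry("napkin_stack",   "Neutral", 0.9, 0.9,  1.9, 0.07),
      catalog_entry("grill",          "Miscellaneous", 1.6, 0.9, 2.8, 0.50),
      catalog_entry("picnic_table",   "Miscellaneous", -0.3, 0.7, 2.3, 0.70),
      catalog_entry("backyard_fence", "Background", 0.0, 1.5, 9.0, 6.0, weight = 20)
    ),
    Driving = dplyr::bind_rows(
      catalog_entry("cigarette",      "Active",  0.3, 1.0,  0.9, 0.03),
      catalog_entry("juul",           "Active", -0.3, 0.9,  0.8, 0.04),
      catalog_entry("ashtray",        "Active",  0.4, 0.8,  0.8, 0.07),
      catalog_entry("lighter",        "Active",  0.5, 0.9,  0.9, 0.04),
      catalog_entry("puffbar",        "Active", -0.4, 0.8,  0.9, 0.04),
      catalog_entry("water_bottle",   "Neutral", 0.2, 0.7,  0.8, 0.06),
      catalog_entry("cellphone",      "Neutral", -0.2, 0.8, 0.7, 0.06),
      catalog_entry("coffee_cup",     "Neutral", 0.6, 0.8,  0.7, 0.05),
      catalog_entry("magazine",       "Neutral", -0.6, 0.6, 0.9, 0.12),
      catalog_entry("gps_unit",       "Neutral", 0.0, 1.1,  0.9, 0.06),
      catalog_entry("steering_wheel", "Miscellaneous", 0.0, 1.0, 0.6, 0.20),
      catalog_entry("dashboard",      "Miscellaneous", 0.0, 0.9, 0.8, 0.40),
      catalog_entry("street_video",
                    if (driving_reversal) "Neutral" else "Background",
                    0.0, 1.6, 6.0, 5.0,
                    weight = if (driving_reversal) 40 else 20)
    ),
    Bus = dplyr::bind_rows(
      catalog_entry("water_bottle",  "Neutral", 0.3, 1.0,  1.2, 0.06),
      catalog_entry("cellphone",     "Neutral", -0.3, 1.0, 1.1, 0.06),
      catalog_entry("newspaper",     "Neutral", 0.5, 0.9,  1.5, 0.12),
      catalog_entry("backpack",      "Neutral", -0.8, 0.6, 1.6, 0.20),
      catalog_entry("candy_bag",     "Neutral", 0.0, 1.0,  1.3, 0.05),
      catalog_entry("bus_seat",      "Miscellaneous", 1.0, 0.8, 1.8, 0.40),
      catalog_entry("hand_rail",     "Miscellaneous", 0.0, 1.6, 1.0, 0.15),
      catalog_entry("bus_interior",  "Background", 0.0, 1.5, 5.0, 4.0, weight = 20)
    ),
    WaitingRoom = dplyr::bind_rows(
      catalog_entry("magazine",      "Neutral", 0.4, 0.9,  1.6, 0.12),
      catalog_entry("water_cooler",  "Neutral", 1.5, 1.1,  2.5, 0.30),
      catalog_entry("cellphone",     "Neutral", -0.3, 1.0, 1.4, 0.06),
      catalog_entry("pen",           "Neutral", 0.1, 0.9,  1.5, 0.03),
      catalog_entry("candy_bowl",    "Neutral", -0.8, 1.0, 1.8, 0.10),
      catalog_entry("reception_desk","Miscellaneous", 0.0, 0.9, 2.5, 0.80),
      catalog_entry("waiting_chair", "Miscellaneous", -1.4, 0.6, 1.2, 0.40),
      catalog_entry("room_walls",    "Background", 0.0, 1.5, 6.0, 5.0, weight = 20)
    ),
    Library = dplyr::bind_rows(
      catalog_entry("book",          "Neutral", 0.3, 1.0,  1.4, 0.08),
      catalog_entry("magazine",      "Neutral", -0.4, 1.0, 1.5, 0.12),
      catalog_entry("pen",           "Neutral", 0.1, 1.0,  1.3, 0.03),
      catalog_entry("water_bottle",  "Neutral", 0.6, 1.0,  1.6, 0.06),
      catalog_entry("laptop",        "Neutral", -0.7, 1.0, 1.7, 0.18),
      catalog_entry("reading_desk",  "Miscellaneous", 0.0, 0.8, 1.6, 0.60),
      catalog_entry("bookshelf",     "Miscellaneous", 2.0, 1.5, 3.0, 0.90),
      catalog_entry("library_hall",  "Background", 0.0, 1.6, 7.0, 5.0, weight = 20)
    ),
    stop("unknown scene name: ", scene_name, call. = FALSE)
  )
  stopifnot(anyDuplicated(cat$name) == 0, all(cat$radius > 0))
  cat
}

#' Catalogs for all six scenes
#'
#' @inheritParams make_scene_catalog
#' @return Named list of catalogs, one per scene.
#' @export
scene_catalogs <- function(driving_reversal = FALSE) {
  setNames(lapply(ALL_SCENES, make_scene_catalog,
                  driving_reversal = driving_reversal), ALL_SCENES)
}

#' Look up the cue category of object names in a catalog
#'
#' @param object Character vector of object names (may include `""` for
#'   "no object" and `"BACKGROUND"` for the no-catalog-hit fallback).
#' @param catalog A scene catalog.
#' @return Character vector of categories; `NA` for `""`, `"Background"` for
#'   the `BACKGROUND` fallback name.
#' @export
object_category <- function(object, catalog) {
  out <- catalog$category[match(object, catalog$name)]
  out[object == BACKGROUND] <- "Background"
  unknown <- !is.na(object) & nzchar(object) & object != BACKGROUND &
    is.na(out)
  if (any(unknown)) {
    stop("object(s) absent from catalog: ",
         paste(unique(object[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}
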