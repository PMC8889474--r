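# Per-cue-category pupillometry.
#
# Per sample the diameter is the binocular mean of the non-missing eye values
# (monocular when only one eye is present). Samples inside any missing-run
# candidate (blink, noise dropout, microsleep), or within +/- margin_ms of one,
# are excluded; each remaining sample contributes to the cue category of the
# object gazed at that tick. Raw millimeter means are reported; there is no
# baseline correction or luminance model.

#' Mean pupil diameter per cue category for one scene
#'
#' @param samples Scene timeseries on the 10-ms grid.
#' @param blink_events Output of [detect_blinks()] on the same samples (its
#'   `"candidates"` attribute supplies the exclusion intervals); if `NULL`,
#'   candidates are recomputed with `mode`.
#' @param catalog Scene catalog, for object-to-category lookup.
#' @param margin_ms Extra exclusion margin around every candidate run (ms,
#'   default 0: exclude exactly the missing runs).
#' @param mode Candidate mode used when recomputing (see [blink_candidates()]).
#' @return List with `by_category` (tibble `category`, `mean_mm`, `n_samples`;
#'   `mean_mm` is `NA` when a category has no valid sample) and
#'   `n_excluded_samples` (samples dropped for missing diameter or
#'   blink/candidate proximity).
#' @export
pupil_by_category <- function(samples, blink_events = NULL, catalog,
                              margin_ms = 0,
                              mode = c("BOTH_EYES", "EITHER_EYE")) {
  mode <- match.arg(mode)
  cand <- if (!is.null(blink_events)) attr(blink_events, "candidates") else NULL
  if (is.null(cand)) cand <- blink_candidates(samples, mode)
  n <- nrow(samples)
  excluded <- rep(FALSE, n)
  if (nrow(cand) > 0) {
    t0 <- samples$t_ms[1]
    lo <- cand$onset_ms - margin_ms
    hi <- cand$onset_ms + cand$duration_ms - SAMPLE_PERIOD_MS + margin_ms
    i_lo <- pmax(1L, as.integer(ceiling((lo - t0) / SAMPLE_PERIOD_MS)) + 1L)
    i_hi <- pmin(n, as.integer(floor((hi - t0) / SAMPLE_PERIOD_MS)) + 1L)
    keep <- i_hi >= i_lo
    idx <- sequence(nvec = i_hi[keep] - i_lo[keep] + 1L, from = i_lo[keep])
    excluded[idx] <- TRUE
  }
  pl <- samples$pupil_l_mm
  pr <- samples$pupil_r_mm
  diam <- ifelse(is.na(pl), pr, ifelse(is.na(pr), pl, (pl + pr) / 2))
  excluded <- excluded | is.na(diam)
  category <- object_category(samples$object, catalog)
  valid <- !excluded & !is.na(category)
  cat_f <- factor(category[valid], levels = CUE_CATEGORIES)
  sums <- as.numeric(tapply(diam[valid], cat_f, sum, default = 0))
  ns <- as.integer(table(cat_f))
  by_cat <- fast_tibble(
    category = CUE_CATEGORIES,
    mean_mm = ifelse(ns > 0, sums / ns, NA_real_),
    n_samples = ns
  )
  list(by_category = by_cat,
       n_excluded_samples = sum(excluded))
}
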