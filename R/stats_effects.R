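# Paired-contrast statistics and effect sizes.
#
# All condition contrasts are two-tailed paired-samples t tests with the
# paired effect size d_z = t / sqrt(n) (mean difference divided by the SD of
# the differences). 95% CIs for d_z use the normal-approximation standard
# error sqrt(1/n + d^2/(2n)), applied to d rounded to 2 decimals — the
# convention that reproduces the reported pilot intervals. Participants with
# either member of a pair absent are dropped pairwise, so degrees of freedom
# can differ across contrasts within one cohort.

#' Cohen's d_z from a paired t statistic
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (degrees of freedom + 1).
#' @return `t / sqrt(n)`.
#' @export
dz_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' Normal-approximation 95% CI for Cohen's d_z
#'
#' `d +/- 1.96 * sqrt(1/n + d^2/(2n))`.
#'
#' @param d Effect size d_z.
#' @param n Number of pairs.
#' @return Numeric length-2 vector `(ci_low, ci_high)`.
#' @export
dz_ci <- function(d, n) {
  stopifnot(n >= 2)
  half <- 1.96 * sqrt(1 / n + d^2 / (2 * n))
  c(d - half, d + half)
}

#' Paired-samples contrast with effect size
#'
#' Computes the two-tailed paired t test, Cohen's d_z, and its 95% CI for two
#' paired condition vectors. Pairs with a missing member are dropped
#' (pairwise deletion); the CI is computed from d_z rounded to 2 decimals
#' (see [dz_ci()]).
#'
#' @param x,y Numeric vectors of per-participant values under condition 1 and
#'   condition 2, same length.
#' @param label Optional contrast label carried into the result.
#' @return An `effect_size` list: `label`, `n`, `df`, `t`, `p`, `d`,
#'   `ci_low`, `ci_high`, `mean_1`, `sd_1`, `mean_2`, `sd_2`.
#' @export
paired_contrast <- function(x, y, label = NULL) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d_diff <- x - y
  sd_diff <- stats::sd(d_diff)
  if (sd_diff == 0) {
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  }
  t_stat <- mean(d_diff) / (sd_diff / sqrt(n))
  df <- n - 1
  d <- dz_from_t(t_stat, n)
  ci <- dz_ci(round(d, 2), n)
  structure(
    list(label = label, n = n, df = df, t = t_stat,
         p = 2 * stats::pt(-abs(t_stat), df = df),
         d = d, ci_low = ci[1], ci_high = ci[2],
         mean_1 = mean(x), sd_1 = stats::sd(x),
         mean_2 = mean(y), sd_2 = stats::sd(y)),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf(
    "%s: t(%d) = %.2f, p = %.3g, d_z = %.2f, 95%% CI [%.2f, %.2f]\n",
    x$label %||% "paired contrast", x$df, x$t, x$p, x$d, x$ci_low, x$ci_high))
  invisible(x)
}

#' Pearson correlation with two-tailed p-value
#'
#' Pairwise-complete product-moment correlation via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length.
#' @return List: `r`, `p`, `n`, `df`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, df = n - 2)
}

contrast_row <- function(es) {
  tibble::tibble(contrast = es$label, type = "paired_t", n = es$n,
                 t = es$t, df = es$df, p = es$p, d = es$d,
                 ci_low = es$ci_low, ci_high = es$ci_high,
                 mean_1 = es$mean_1, sd_1 = es$sd_1,
                 mean_2 = es$mean_2, sd_2 = es$sd_2,
                 r = NA_real_)
}

correlation_row <- function(label, x, y) {
  res <- tryCatch(pearson_r(x, y), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  tibble::tibble(contrast = label, type = "pearson", n = res$n,
                 t = NA_real_, df = res$df, p = res$p, d = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 mean_1 = NA_real_, sd_1 = NA_real_,
                 mean_2 = NA_real_, sd_2 = NA_real_,
                 r = res$r)
}

safe_contrast <- function(x, y, label) {
  es <- tryCatch(paired_contrast(x, y, label = label),
                 error = function(e) NULL)
  if (is.null(es)) NULL else contrast_row(es)
}

#' Full contrast battery over a processed cohort
#'
#' Emits the complete set of condition contrasts for a cohort's per-participant
#' metrics: Active-vs-Neutral craving; pooled and per-Active-scene
#' Active-vs-Neutral cue fixation time; pooled and per-scene cue pupil
#' diameter; Active-vs-Neutral spontaneous eye-blink rate plus the pairwise
#' EBR comparisons among the Active scenes; and exploratory correlations of
#' attentional bias, pupil-diameter difference and EBR with in-task craving
#' and (when supplied) past-90-day use episodes. Each contrast uses pairwise
#' deletion, so degrees of freedom are reported per row.
#'
#' @param participants Wide per-participant metric table from
#'   [cohort_metrics()].
#' @param covariates Optional tibble with columns `participant` and
#'   `use_episodes` (past 90-day nicotine-product use episode count).
#' @param holm If `TRUE`, append a Holm-adjusted p-value column `p_holm`
#'   (no adjustment is applied by default).
#' @return Tibble with one row per contrast: `contrast`, `type`, `n`, `t`,
#'   `df`, `p`, `d`, `ci_low`, `ci_high`, condition summaries, `r`.
#' @export
run_contrast_table <- function(participants, covariates = NULL, holm = FALSE) {
  p <- participants
  if (!is.null(covariates)) {
    p <- dplyr::left_join(p, covariates, by = "participant")
  }
  rows <- list(
    safe_contrast(p$craving_active, p$craving_neutral,
                  "craving: Active vs Neutral scenes"),
    safe_contrast(p$fix_active_pooled, p$fix_neutral_pooled,
                  "fixation: Active vs Neutral cues (pooled Active scenes)"),
    safe_contrast(p$fix_active_Patio, p$fix_neutral_Patio,
                  "fixation: Active vs Neutral cues (Patio)"),
    safe_contrast(p$fix_active_OutdoorBBQ, p$fix_neutral_OutdoorBBQ,
                  "fixation: Active vs Neutral cues (OutdoorBBQ)"),
    safe_contrast(p$fix_active_Driving, p$fix_neutral_Driving,
                  "fixation: Active vs Neutral cues (Driving)"),
    safe_contrast(p$pupil_active_pooled, p$pupil_neutral_pooled,
                  "pupil: Active vs Neutral cues (pooled Active scenes)"),
    safe_contrast(p$pupil_active_Patio, p$pupil_neutral_Patio,
                  "pupil: Active vs Neutral cues (Patio)"),
    safe_contrast(p$pupil_active_OutdoorBBQ, p$pupil_neutral_OutdoorBBQ,
                  "pupil: Active vs Neutral cues (OutdoorBBQ)"),
    safe_contrast(p$pupil_active_Driving, p$pupil_neutral_Driving,
                  "pupil: Active vs Neutral cues (Driving)"),
    safe_contrast(p$ebr_active, p$ebr_neutral,
                  "EBR: Active vs Neutral scenes"),
    safe_contrast(p$ebr_OutdoorBBQ, p$ebr_Patio,
                  "EBR: OutdoorBBQ vs Patio"),
    safe_contrast(p$ebr_Driving, p$ebr_OutdoorBBQ,
                  "EBR: Driving vs OutdoorBBQ"),
    safe_contrast(p$ebr_Driving, p$ebr_Patio,
                  "EBR: Driving vs Patio"),
    correlation_row("r: attentional bias ~ craving (Active scenes)",
                    p$bias_score, p$craving_active),
    correlation_row("r: pupil difference ~ craving (Active scenes)",
                    p$pupil_active_pooled - p$pupil_neutral_pooled,
                    p$craving_active),
    correlation_row("r: EBR ~ craving (Active scenes)",
                    p$ebr_active, p$craving_active)
  )
  if (!is.null(covariates)) {
    rows <- c(rows, list(
      correlation_row("r: attentional bias ~ 90-day use episodes",
                      p$bias_score, p$use_episodes),
      correlation_row("r: pupil difference ~ 90-day use episodes",
                      p$pupil_active_pooled - p$pupil_neutral_pooled,
                      p$use_episodes),
      correlation_row("r: EBR ~ 90-day use episodes",
                      p$ebr_active, p$use_episodes)
    ))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(contrast = character(), type = character(),
                          n = integer(), t = numeric(), df = numeric(),
                          p = numeric(), d = numeric(), ci_low = numeric(),
                          ci_high = numeric(), mean_1 = numeric(),
                          sd_1 = numeric(), mean_2 = numeric(),
                          sd_2 = numeric(), r = numeric())
  }
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
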