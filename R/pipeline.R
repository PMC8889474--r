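# End-to-end orchestration: simulate (or ingest) -> blink/fixation/pupil/survey
# metric extraction -> contrast battery -> report, with a run manifest.

write_tsv_stage <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate a cohort (or ingest participant logs from
#' `input_dir`), extract blink summaries, fixation indices, pupil means, and
#' survey aggregates, run the contrast battery, and write all result tables
#' plus a run manifest. Idempotent given the config seed: two runs with the
#' same config produce byte-identical tables.
#'
#' @param config A `sim_config` (its seed drives every random draw).
#' @param out_dir Output directory (created if needed).
#' @param input_dir Optional directory of participant log directories (each
#'   readable by [read_session_log()]); when given, the simulate stage is
#'   skipped and `config` supplies only catalog/processing options.
#' @param mode Blink candidate mode.
#' @param margin_ms Pupil exclusion margin (ms).
#' @param write_logs If `TRUE`, simulated participant logs are also written
#'   under `out_dir/logs/` in the documented on-disk format.
#' @return The run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, input_dir = NULL,
                         mode = "BOTH_EYES", margin_ms = 0,
                         write_logs = FALSE) {
  validate_sim_config(config)
  if (is.null(input_dir) && config$n_participants < 1) {
    stop("config with n_participants < 1: nothing to simulate", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()

  ## stage: simulate or ingest
  if (is.null(input_dir)) {
    cohort <- simulate_cohort(config)
    logs <- lapply(cohort, `[[`, "log")
    covariates <- tibble::tibble(
      participant = vapply(cohort, function(x) x$truth$participant_id, character(1)),
      use_episodes = vapply(cohort, function(x) x$truth$use_episodes, numeric(1))
    )
    if (write_logs) {
      for (x in cohort) {
        write_session_log(x$log, file.path(out_dir, "logs", x$log$participant_id))
      }
    }
    write_tsv_stage(covariates, file.path(out_dir, "covariates.tsv"))
  } else {
    dirs <- list.dirs(input_dir, recursive = FALSE)
    if (length(dirs) == 0) stop("no participant logs under ", input_dir, call. = FALSE)
    logs <- lapply(dirs, read_session_log)
    cov_path <- file.path(input_dir, "covariates.tsv")
    covariates <- if (file.exists(cov_path)) {
      readr::read_tsv(cov_path, show_col_types = FALSE, progress = FALSE)
    } else NULL
  }

  catalogs <- scene_catalogs(driving_reversal = config$driving_reversal)

  ## stage: metric extraction
  metrics <- cohort_metrics(logs, catalogs, mode = mode, margin_ms = margin_ms)
  blink_tbl <- metrics$scenes[, c("participant", "scene_name", "scene_type",
                                  "blink_count", "ebr_per_min",
                                  "discarded_short", "discarded_long",
                                  "discarded_truncated")]
  fix_tbl <- metrics$scenes[, c("participant", "scene_name", "scene_type",
                                "fix_active_ms", "fix_neutral_ms",
                                "fix_misc_ms", "fix_background_ms",
                                "fix_active_mean_ms", "fix_neutral_mean_ms",
                                "bias_ms")]
  pupil_tbl <- metrics$scenes[, c("participant", "scene_name", "scene_type",
                                  "pupil_active_mm", "pupil_neutral_mm",
                                  "pupil_excluded_samples")]
  survey_tbl <- metrics$scenes[, c("participant", "scene_name", "scene_type",
                                   "craving", "relevance")]
  files <- c(
    blinks = write_tsv_stage(blink_tbl, file.path(out_dir, "blinks.tsv")),
    fixations = write_tsv_stage(fix_tbl, file.path(out_dir, "fixations.tsv")),
    pupils = write_tsv_stage(pupil_tbl, file.path(out_dir, "pupils.tsv")),
    surveys = write_tsv_stage(survey_tbl, file.path(out_dir, "surveys.tsv")),
    participants = write_tsv_stage(metrics$participants,
                                   file.path(out_dir, "participants.tsv"))
  )

  ## stage: analyze
  contrasts <- run_contrast_table(metrics$participants, covariates = covariates)
  files["contrasts"] <- write_tsv_stage(contrasts,
                                        file.path(out_dir, "contrasts.tsv"))

  manifest <- list(
    seed = config$seed,
    n_participants = length(logs),
    config = config[setdiff(names(config), "blink_dur_ms_range")],
    blink_dur_ms_range = config$blink_dur_ms_range,
    mode = mode,
    margin_ms = margin_ms,
    files = as.list(files),
    rows = list(scenes = nrow(metrics$scenes),
                participants = nrow(metrics$participants),
                contrasts = nrow(contrasts)),
    warnings = warnings_log
  )
  for (f in files) {
    if (!file.exists(f) || file.size(f) == 0) {
      stop("pipeline output missing or empty: ", f, call. = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render the contrast battery as a markdown report
#'
#' @param contrasts Tibble from [run_contrast_table()] (or the
#'   `contrasts.tsv` written by [run_pipeline()], re-read).
#' @param path Output markdown file.
#' @return `path`, invisibly.
#' @export
report_markdown <- function(contrasts, path) {
  fmt <- function(x, d = 2) ifelse(is.na(x), "", formatC(x, digits = d, format = "f"))
  tt <- contrasts[contrasts$type == "paired_t", ]
  rr <- contrasts[contrasts$type == "pearson", ]
  lines <- c(
    "# Contrast battery",
    "",
    "## Paired contrasts (Cohen's d_z, 95% CI)",
    "",
    "| contrast | n | t(df) | p | d_z | 95% CI |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %s (%d) | %s | %s | [%s, %s] |",
            tt$contrast, tt$n, fmt(tt$t), tt$df, fmt(tt$p, 3),
            fmt(tt$d), fmt(tt$ci_low), fmt(tt$ci_high)),
    "",
    "## Exploratory correlations",
    "",
    "| correlation | n | r | p |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %s | %s |", rr$contrast, rr$n, fmt(rr$r), fmt(rr$p, 3))
  )
  writeLines(lines, path)
  invisible(path)
}
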