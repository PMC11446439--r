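#' Pipeline configuration
#'
#' One object that fixes every stage of the end-to-end analysis: cohort
#' simulation, conditioning, segmentation, entropy estimation and inference.
#' A single root seed governs all stage seeds, so two runs with an identical
#' configuration produce byte-identical outputs.
#'
#' @param seed Root seed for the whole run.
#' @param n_subjects,fs,duration,channels,effects,subject_sd,artifact_rate
#'   Passed to [cohort_spec()].
#' @param n_pieces Segments per recording.
#' @param entropy An [entropy_config()]; its seed is derived from `seed`
#'   unless supplied explicitly.
#' @param z_thresh,window Artifact screening parameters
#'   (see [detect_jump_artifacts()]).
#' @param exclusion_level `"subject"` (exclude a subject whose any recording
#'   is flagged, mirroring the study's exclusion of whole individuals) or
#'   `"recording"`.
#' @param apply_335_to_all Apply the 3-35 Hz band-pass to every state rather
#'   than only cycling (symmetric-preprocessing sensitivity analysis).
#' @param n_perm Permutations per test.
#' @param holm Add Holm-corrected p-values across regions.
#' @param null Calibration mode: zeroes all condition effects
#'   ([null_effects()]) and switches to symmetric preprocessing, so that the
#'   four conditions of each subject are exchangeable draws from one process.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 24, fs = 1000,
                            duration = 120, channels = eeg_montage(),
                            effects = effect_sizes(), subject_sd = 0.1,
                            artifact_rate = 0.07, n_pieces = 100,
                            entropy = NULL, z_thresh = 8, window = 100,
                            exclusion_level = c("subject", "recording"),
                            apply_335_to_all = FALSE, n_perm = 10000,
                            holm = FALSE, null = FALSE) {
  exclusion_level <- match.arg(exclusion_level)
  if (isTRUE(null)) {
    effects <- null_effects()
    apply_335_to_all <- TRUE
  }
  cohort <- cohort_spec(n_subjects = n_subjects, fs = fs, duration = duration,
                        channels = channels,
                        seed = derive_seed(seed, "cohort"),
                        effects = effects, subject_sd = subject_sd,
                        artifact_rate = artifact_rate)
  entropy <- entropy %||% entropy_config(seed = derive_seed(seed, "entropy"))
  stopifnot(inherits(entropy, "entropy_config"))
  structure(
    list(seed = as.integer(seed), cohort = cohort, n_pieces = n_pieces,
         entropy = entropy, z_thresh = z_thresh, window = window,
         exclusion_level = exclusion_level,
         apply_335_to_all = isTRUE(apply_335_to_all),
         n_perm = as.integer(n_perm), holm = isTRUE(holm),
         null = isTRUE(null),
         stats_seed = derive_seed(seed, "stats")),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> seed ", x$seed, if (x$null) " (null calibration)",
      "\n", sep = "")
  print(x$cohort)
  cat("  n_pieces ", x$n_pieces, ", z_thresh ", x$z_thresh, ", exclusion ",
      x$exclusion_level, ", 3-35 Hz on ",
      if (x$apply_335_to_all) "all states" else "cycling only",
      ", n_perm ", x$n_perm, "\n", sep = "")
  invisible(x)
}

#' Topographic summary of the entropy table
#'
#' Mean and median of `median_entropy` across subjects for each of the
#' 8 channel positions x 4 conditions (32 cells) -- the tabular content of a
#' topographic entropy map.
#'
#' @param entropy_tbl Output of [entropy_table()].
#' @return A tibble with columns `region`, `side`, `state`, `eyes`,
#'   `mean_entropy`, `median_entropy`, `n_subjects`.
#' @export
topo_summary <- function(entropy_tbl) {
  out <- entropy_tbl |>
    dplyr::summarise(
      mean_entropy = mean(.data$median_entropy),
      med_entropy = stats::median(.data$median_entropy),
      n_subjects = dplyr::n_distinct(.data$subject),
      .by = c("region", "side", "state", "eyes")
    ) |>
    dplyr::arrange(.data$region, .data$side, .data$state, .data$eyes)
  names(out)[names(out) == "med_entropy"] <- "median_entropy"
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulate (or take an ingested cohort) -> screen artifacts and apply the
#' exclusion rule -> condition -> entropy table -> inference -> topographic
#' summary. Every stage is deterministic given the configuration; failures
#' abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `entropy.csv`, `stats.csv`, `topo.csv` and `report.txt`.
#' @param cohort Optional pre-built `eeg_cohort` (e.g. from [ingest_edf()]);
#'   skips the simulation stage.
#' @return An object of class `rme_pipeline`: list with `entropy`, `stats`,
#'   `topo`, `excluded_subjects`, `manifest`, `report` (character lines) and
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- .stage("simulate", cohort %||% generate_cohort(config$cohort))
  subjects_in <- unique(cohort$manifest$subject)
  cohort <- .stage("artifact screening",
                   screen_artifacts(cohort, z_thresh = config$z_thresh,
                                    window = config$window,
                                    level = config$exclusion_level))
  excluded <- setdiff(subjects_in, unique(cohort$signals$subject))
  if (length(excluded)) {
    message("excluded ", length(excluded), " subject(s) with artifacts: ",
            paste(excluded, collapse = ", "))
  }
  cohort <- .stage("conditioning",
                   condition_recordings(cohort, config$apply_335_to_all))
  etbl <- .stage("entropy",
                 entropy_table(cohort, config$entropy, config$n_pieces))
  stats_tbl <- .stage("inference",
                      run_inference(etbl, n_perm = config$n_perm,
                                    seed = config$stats_seed,
                                    holm = config$holm))
  topo <- .stage("summary", topo_summary(etbl))

  report <- c(
    sprintf("recmicro pipeline report (root seed %d%s)", config$seed,
            if (config$null) ", null calibration" else ""),
    sprintf("subjects: %d simulated/ingested, %d retained, %d excluded (%s)",
            length(subjects_in), dplyr::n_distinct(etbl$subject),
            length(excluded), config$exclusion_level),
    "",
    "State (cycling - rest) contrasts by region-side:"
  )
  st <- dplyr::filter(stats_tbl, .data$term == "statecycling")
  for (i in seq_len(nrow(st))) {
    report <- c(report, sprintf(
      "  %s-%s: %s entropy under cycling (estimate %+0.4f nats, t = %0.3f, perm p = %0.4f)",
      st$region[i], st$side[i],
      ifelse(st$estimate[i] < 0, "lower", "higher"),
      st$estimate[i], st$t_value[i], st$p_perm[i]))
  }
  g1 <- dplyr::filter(stats_tbl, .data$model == "GLM1")
  report <- c(report, "",
              sprintf("GLM1 validation (occipital-right, rest): eyes closed - open estimate %+0.4f nats, t = %0.3f, perm p = %0.4f",
                      g1$estimate[1], g1$t_value[1], g1$p_perm[1]))

  out <- structure(
    list(entropy = etbl, stats = stats_tbl, topo = topo,
         excluded_subjects = excluded, manifest = cohort$manifest,
         report = report, config = config),
    class = "rme_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(etbl, file.path(out_dir, "entropy.csv"))
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
    readr::write_csv(topo, file.path(out_dir, "topo.csv"))
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  out
}

#' @export
print.rme_pipeline <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
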