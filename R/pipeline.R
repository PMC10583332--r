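#' Pipeline configuration
#'
#' One configuration object for the end-to-end analysis.  Exactly one
#' input mode is active: `"synthetic"` (generate a cohort from
#' `cohort`), `"csv"` (read participant and ROI tables from
#' `paths$participants` / `paths$roi_values`), or `"volumes"` (read the
#' participant table from CSV and extract the ROI table from per-subject
#' NIfTI volume directories named in `paths$volume_dirs`).  A root `seed`
#' overrides the cohort seed so all randomness flows from one integer.
#'
#' @param mode Input mode.
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param cutoffs A [cutoff_config()]; A/T status is (re)derived from the
#'   CSF analytes with these cutoffs.
#' @param norms A [norms_config()].
#' @param comparison List of options for [compare_groups()]: `alpha`,
#'   `family`.
#' @param models A [suite_config()].
#' @param paths List of input paths (csv / volumes modes).
#' @param output_dir Run directory (created by [run_pipeline()]).
#' @param seed Root integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv", "volumes"),
                            cohort = cohort_config(),
                            cutoffs = cutoff_config(),
                            norms = norms_config(),
                            comparison = list(alpha = 0.05,
                                              family = "metric_tissue"),
                            models = suite_config(),
                            paths = list(),
                            output_dir = tempfile("noddinorms_run_"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
  }
  structure(
    list(mode = mode, cohort = cohort, cutoffs = cutoffs, norms = norms,
         comparison = comparison, models = models, paths = paths,
         output_dir = output_dir, seed = cohort$seed),
    class = "pipeline_config"
  )
}

run_stage <- function(name, logfile, expr) {
  log_line(logfile, sprintf("stage %s: start", name))
  out <- tryCatch(expr, error = function(e) {
    log_line(logfile, sprintf("stage %s: FAILED (%s)", name,
                              conditionMessage(e)))
    nn_stop(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = if (inherits(e, "nn_numeric_error")) {
              "nn_numeric_error"
            } else {
              "nn_validation_error"
            })
  })
  log_line(logfile, sprintf("stage %s: done", name))
  out
}

log_line <- function(logfile, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = logfile, append = TRUE)
}

ingest_inputs <- function(config, logfile) {
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$cohort)
  } else if (config$mode == "csv") {
    cohort <- list(
      participants = read_participants(config$paths$participants),
      roi_values = read_roi_table(config$paths$roi_values)
    )
  } else {
    participants <- read_participants(config$paths$participants)
    dirs <- config$paths$volume_dirs
    if (is.null(names(dirs))) {
      nn_stop("paths$volume_dirs must be named by participant_id")
    }
    tabs <- lapply(names(dirs), function(id) {
      vols <- read_volume_set(dirs[[id]])
      spec <- config$paths$roi_spec
      if (is.null(spec)) nn_stop("volumes mode requires paths$roi_spec")
      extract_roi_table(vols, spec, participant_id = id)
    })
    cohort <- list(participants = participants,
                   roi_values = do.call(rbind, tabs))
  }
  # Re-derive A/T status from the analytes under the configured cutoffs.
  cohort$participants$at_status <- classify_at(
    cohort$participants$abeta42, cohort$participants$abeta40,
    cohort$participants$ptau, config$cutoffs
  )
  cohort
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: ingest -> analysis-sample selection -> robust norms
#' -> z-scores -> group comparisons (clinical CU vs MCI/AD and, within CU,
#' A/T status) -> Firth model suite.  Each stage's artifact is written to
#' the run directory: `participants.csv` and `roi_values.csv` (the
#' ingested tables), `exclusion_ledger.csv`, `norms.json`, `zscores.csv`,
#' `comparisons_clinical.csv`, `comparisons_at.csv`, `model_suite.csv`,
#' `provenance.json` and `pipeline.log`.  Reruns with an identical
#' configuration and seed reproduce all CSV outputs byte for byte.  Any
#' stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The run directory, invisibly; the parsed artifacts are attached
#'   as attribute `"artifacts"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$output_dir, "pipeline.log")
  cat("", file = logfile)

  cohort <- run_stage("ingest", logfile, ingest_inputs(config, logfile))
  write_csv_precise(cohort$participants,
                    file.path(config$output_dir, "participants.csv"))
  write_csv_precise(cohort$roi_values,
                    file.path(config$output_dir, "roi_values.csv"))

  sel <- run_stage("select", logfile,
                   select_analysis_sample(cohort$participants))
  write_csv_precise(sel$excluded,
                    file.path(config$output_dir, "exclusion_ledger.csv"))
  participants <- sel$retained
  roi_values <- cohort$roi_values[
    cohort$roi_values$participant_id %in% participants$participant_id, ,
    drop = FALSE
  ]

  norms <- run_stage("norms", logfile,
                     build_norms(roi_values, participants, config$norms))
  write_norms(norms$model, file.path(config$output_dir, "norms.json"))
  write_csv_precise(norms$zscores,
                    file.path(config$output_dir, "zscores.csv"))

  comparisons <- run_stage("compare", logfile, {
    clin <- setNames(
      ifelse(participants$diagnosis == "CU", "CU", "MCI/AD"),
      participants$participant_id
    )
    clinical <- compare_groups(norms$zscores, clin,
                               alpha = config$comparison$alpha,
                               family = config$comparison$family,
                               method = config$comparison$method %||% "BH",
                               level_order = c("CU", "MCI/AD"))
    cu <- participants[participants$diagnosis == "CU", , drop = FALSE]
    at_groups <- setNames(cu$at_status, cu$participant_id)
    at <- if (length(unique(at_groups)) >= 2L) {
      compare_groups(norms$zscores, at_groups,
                     alpha = config$comparison$alpha,
                     family = config$comparison$family,
                     method = config$comparison$method %||% "BH",
                     level_order = c("A-T-", "A+T-", "A+T+"))
    } else {
      log_line(logfile,
               "stage compare: A/T contrast skipped (fewer than two A/T levels among CU)")
      clinical[0, , drop = FALSE]
    }
    list(clinical = clinical, at = at)
  })
  write_csv_precise(comparisons$clinical,
                    file.path(config$output_dir, "comparisons_clinical.csv"))
  write_csv_precise(comparisons$at,
                    file.path(config$output_dir, "comparisons_at.csv"))

  suite <- run_stage("models", logfile,
                     run_model_suite(participants, roi_values,
                                     config$models))
  write_csv_precise(suite$results,
                    file.path(config$output_dir, "model_suite.csv"))

  cfg_json <- jsonlite::toJSON(strip_config(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(config$output_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = unname(tools::md5sum(cfg_file)),
         package = "noddinorms",
         version = as.character(utils::packageVersion("noddinorms")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(config$output_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  log_line(logfile, "pipeline complete")
  out <- config$output_dir
  attr(out, "artifacts") <- list(
    participants = participants, roi_values = roi_values,
    exclusion_ledger = sel$excluded, norms = norms,
    comparisons = comparisons, suite = suite
  )
  invisible(out)
}

# Serializable view of the configuration (drops functions/volumes paths
# that may not serialize cleanly, keeps everything that defines the run).
strip_config <- function(config) {
  list(
    mode = config$mode, seed = config$seed,
    cohort = list(
      n_per_group = config$cohort$n_per_group,
      age_mean = config$cohort$age_mean, age_sd = config$cohort$age_sd,
      female_fraction = config$cohort$female_fraction,
      age_center = config$cohort$age_center,
      age_slope = config$cohort$age_slope,
      sex_effect = config$cohort$sex_effect
    ),
    cutoffs = unclass(config$cutoffs),
    norms = unclass(config$norms),
    comparison = config$comparison,
    models = unclass(config$models)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys override the corresponding
#' [pipeline_config()] defaults (`mode`, `seed`, `output_dir`, `paths`,
#' `cutoffs`, `norms`, `comparison`, `models`; cohort cell counts via
#' `cohort: n_per_group` as a 3x4 row-major list).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- cohort_config()
  if (!is.null(y$cohort$n_per_group)) {
    m <- matrix(as.integer(unlist(y$cohort$n_per_group)), nrow = 3,
                byrow = TRUE,
                dimnames = list(c("CU", "MCI", "AD"), at_levels()))
    cohort <- cohort_config(n_per_group = m, seed = cohort$seed)
  }
  cutoffs <- do.call(cutoff_config, y$cutoffs %||% list())
  norms <- do.call(norms_config, y$norms %||% list())
  models <- do.call(suite_config, y$models %||% list())
  pipeline_config(
    mode = y$mode %||% "synthetic",
    cohort = cohort, cutoffs = cutoffs, norms = norms,
    comparison = utils::modifyList(
      list(alpha = 0.05, family = "metric_tissue"), y$comparison %||% list()
    ),
    models = models,
    paths = y$paths %||% list(),
    output_dir = y$output_dir %||% tempfile("noddinorms_run_"),
    seed = y$seed
  )
}
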