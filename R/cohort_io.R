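#' Write a cohort to CSV
#'
#' Writes the participant table (`participants.csv`) and ROI table
#' (`roi_values.csv`) to a directory as UTF-8, header-row, one-row-per-record
#' CSV.  Doubles are serialized with 17 significant digits so a read/write
#' cycle reproduces values exactly.  When a [cohort_config()] is supplied,
#' its seed is recorded in a `provenance.json` sidecar.
#'
#' @param participants,roi_values Tables as produced by
#'   [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config Optional [cohort_config()] for the provenance sidecar.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(participants, roi_values, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_precise(participants, file.path(dir, "participants.csv"))
  write_csv_precise(roi_values, file.path(dir, "roi_values.csv"))
  if (!is.null(config)) {
    jsonlite::write_json(
      list(seed = config$seed, n_participants = nrow(participants),
           package = "noddinorms",
           version = as.character(utils::packageVersion("noddinorms"))),
      file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(dir)
}

#' Read and validate a participant table
#'
#' @param path Path to a `participants.csv` written by [write_cohort()] (or
#'   any CSV with the same columns).
#' @return Validated participant data frame.
#' @export
read_participants <- function(path) {
  df <- read_csv_checked(path, c("participant_id", "age", "sex", "diagnosis",
                                 "abeta42", "abeta40", "ptau", "at_status"))
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup) > 0) {
    nn_stop(sprintf("duplicated participant_id: %s",
                    paste(unique(dup), collapse = ", ")))
  }
  for (nm in c("age", "abeta42", "abeta40", "ptau")) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))
      nn_stop(sprintf("non-numeric '%s' at line %s", nm,
                      paste(data_line(head(bad, 5L)), collapse = ", ")))
    }
  }
  if (nrow(df) > 0 && any(df$age <= 0)) {
    nn_stop(sprintf("non-positive age at line %s",
                    paste(data_line(which(df$age <= 0)), collapse = ", ")))
  }
  if (nrow(df) > 0 && !is_binary01(df$sex)) {
    nn_stop("sex must be coded 0 (male) / 1 (female)")
  }
  df
}

#' Read and validate an ROI table
#'
#' @param path Path to a `roi_values.csv` written by [write_cohort()].
#' @return Validated long ROI data frame.
#' @export
read_roi_table <- function(path) {
  df <- read_csv_checked(path, c("participant_id", "roi_name", "metric",
                                 "tissue_class", "value"))
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
    nn_stop(sprintf("non-numeric 'value' at line %s",
                    paste(data_line(head(bad, 5L)), collapse = ", ")))
  }
  out_of_range <- which(!is.na(df$value) & (df$value <= 0 | df$value >= 1))
  if (length(out_of_range) > 0) {
    nn_stop(sprintf("ROI value outside (0, 1) at line %s",
                    paste(data_line(head(out_of_range, 5L)), collapse = ", ")))
  }
  key <- cell_key(df$roi_name, df$metric, df$tissue_class)
  dup <- duplicated(paste(df$participant_id, key))
  if (any(dup)) {
    nn_stop(sprintf("duplicated (participant_id, roi, metric) at line %s",
                    paste(data_line(head(which(dup), 5L)), collapse = ", ")))
  }
  df
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `participants.csv` and `roi_values.csv`.
#' @return List with `participants` and `roi_values`.
#' @export
read_cohort <- function(dir) {
  list(
    participants = read_participants(file.path(dir, "participants.csv")),
    roi_values = read_roi_table(file.path(dir, "roi_values.csv"))
  )
}
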