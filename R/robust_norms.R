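#' Robust-norms configuration
#'
#' Options of the robust normative procedure.  The exclusion threshold is
#' in z units and one-sided: a normative participant is removed when any
#' metric-by-ROI z-score falls *at or below* minus the threshold ("1.5 or
#' more SD below expected" is inclusive).  The RMSE denominator defaults
#' to the residual degrees of freedom `n - 3` (intercept + age + sex); a
#' plain `n` denominator is available.  Exclusion is a single
#' remove-then-refit pass by default; `iterate = TRUE` repeats
#' flag-and-refit until no further removal.
#'
#' @param exclusion_threshold Positive z-unit threshold (default 1.5).
#' @param rmse_denominator `"n-3"` (residual df) or `"n"`.
#' @param iterate Repeat exclusion until stable (default `FALSE`).
#' @param min_n Minimum size of the reduced normative set.
#' @param metrics Metric families scanned by the flag rule (default both
#'   NDI and ODI).
#' @return An object of class `norms_config`.
#' @export
norms_config <- function(exclusion_threshold = 1.5,
                         rmse_denominator = c("n-3", "n"),
                         iterate = FALSE, min_n = 20L,
                         metrics = c("NDI", "ODI")) {
  if (!is.numeric(exclusion_threshold) || length(exclusion_threshold) != 1L ||
      is.na(exclusion_threshold) || exclusion_threshold <= 0) {
    nn_stop("exclusion_threshold must be a single positive number")
  }
  rmse_denominator <- match.arg(rmse_denominator)
  structure(
    list(exclusion_threshold = exclusion_threshold,
         rmse_denominator = rmse_denominator,
         iterate = isTRUE(iterate), min_n = as.integer(min_n),
         metrics = metrics),
    class = "norms_config"
  )
}

#' Fit one normative age/sex regression
#'
#' Ordinary least squares of a metric on centered age and sex
#' (`value = b0 + b_age * (age - age_center) + b_sex * sex`), returning the
#' coefficients and the root-mean-square residual used as the z-score
#' denominator.
#'
#' @param values Numeric metric values.
#' @param ages Ages in years.
#' @param sexes Binary sex (0 = male, 1 = female); both levels must be
#'   present for `b_sex` to be identifiable.
#' @param age_center Centering constant in years.
#' @param rmse_denominator `"n-3"` (default) or `"n"`.
#' @return List with `b0`, `b_age`, `b_sex`, `rmse`, `n_fit`.
#' @export
fit_metric_regression <- function(values, ages, sexes, age_center,
                                  rmse_denominator = "n-3") {
  n <- length(values)
  if (length(ages) != n || length(sexes) != n) {
    nn_stop("values, ages and sexes must have equal length")
  }
  if (n < 10L) nn_stop("normative regression needs at least 10 observations")
  if (anyNA(values) || anyNA(ages) || anyNA(sexes)) {
    nn_stop("missing values in regression inputs")
  }
  if (!is_binary01(sexes)) nn_stop("sexes must be coded 0/1")
  if (length(unique(sexes)) < 2L) {
    nn_stop("b_sex unidentifiable: only one sex present in the fitting set")
  }
  x <- cbind(1, ages - age_center, sexes)
  if (qr(x)$rank < 3L) {
    nn_stop("rank-deficient design: age/sex regression unidentifiable")
  }
  fit <- lm.fit(x, values)
  denom <- if (rmse_denominator == "n") n else n - 3L
  rmse <- sqrt(sum(fit$residuals^2) / denom)
  list(b0 = unname(fit$coefficients[1]),
       b_age = unname(fit$coefficients[2]),
       b_sex = unname(fit$coefficients[3]),
       rmse = rmse, n_fit = n)
}

fit_all_cells <- function(roi_table, participants, ids, rmse_denominator) {
  sub <- participants[participants$participant_id %in% ids, , drop = FALSE]
  age_center <- mean(sub$age)
  rt <- roi_table[roi_table$participant_id %in% ids, , drop = FALSE]
  keys <- unique(cell_key(rt$roi_name, rt$metric, rt$tissue_class))
  idx <- match(rt$participant_id, sub$participant_id)
  rt$age <- sub$age[idx]
  rt$sex <- sub$sex[idx]
  rows <- lapply(keys, function(k) {
    cell <- rt[cell_key(rt$roi_name, rt$metric, rt$tissue_class) == k, ]
    f <- fit_metric_regression(cell$value, cell$age, cell$sex, age_center,
                               rmse_denominator)
    data.frame(roi_name = cell$roi_name[1], metric = cell$metric[1],
               tissue_class = cell$tissue_class[1],
               b0 = f$b0, b_age = f$b_age, b_sex = f$b_sex,
               rmse = f$rmse, n_fit = f$n_fit, stringsAsFactors = FALSE)
  })
  list(coefficients = do.call(rbind, rows), age_center = age_center)
}

#' Compute robust z-scores from a frozen normative model
#'
#' `z = (observed - (b0 + b_age * (age - age_center) + b_sex * sex)) / rmse`
#' for every row of the ROI table, using the model's frozen coefficients.
#'
#' @param model A `normative_model` from [build_norms()] (or the same
#'   structure read back by [read_norms()]).
#' @param roi_table Long ROI table; every (roi, metric, tissue) cell must
#'   be covered by the model.
#' @param participants Participant table supplying `age` and `sex`.
#' @return Data frame `participant_id`, `roi_name`, `metric`,
#'   `tissue_class`, `z`.
#' @export
compute_zscores <- function(model, roi_table, participants) {
  stopifnot(inherits(model, "normative_model"))
  co <- model$coefficients
  if (any(co$rmse <= 0)) {
    nn_stop_numeric("degenerate normative model: rmse must be > 0")
  }
  idx <- match(roi_table$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    nn_stop(sprintf("ROI rows reference unknown participant(s): %s",
                    paste(unique(roi_table$participant_id[is.na(idx)]),
                          collapse = ", ")))
  }
  age <- participants$age[idx]
  sex <- participants$sex[idx]
  if (anyNA(age) || anyNA(sex)) {
    bad <- unique(roi_table$participant_id[is.na(age) | is.na(sex)])
    nn_stop(sprintf("participant(s) missing age/sex: %s",
                    paste(bad, collapse = ", ")))
  }
  mk <- match(cell_key(roi_table$roi_name, roi_table$metric,
                       roi_table$tissue_class),
              cell_key(co$roi_name, co$metric, co$tissue_class))
  if (anyNA(mk)) {
    miss <- unique(cell_key(roi_table$roi_name, roi_table$metric,
                            roi_table$tissue_class)[is.na(mk)])
    nn_stop(sprintf("no normative fit for cell(s): %s",
                    paste(miss, collapse = ", ")))
  }
  predicted <- co$b0[mk] + co$b_age[mk] * (age - model$age_center) +
    co$b_sex[mk] * sex
  data.frame(
    participant_id = roi_table$participant_id,
    roi_name = roi_table$roi_name,
    metric = roi_table$metric,
    tissue_class = roi_table$tissue_class,
    z = (roi_table$value - predicted) / co$rmse[mk],
    stringsAsFactors = FALSE
  )
}

#' Flag low-outlying participants
#'
#' A participant is flagged when `z <= -threshold` for *any* metric-by-ROI
#' cell.  The rule is one-sided: only scores below expectation count, so
#' large positive scores never trigger exclusion.
#'
#' @param ztable Z-score table from [compute_zscores()].
#' @param threshold Positive z-unit threshold (inclusive).
#' @return List with `flagged_ids` (character vector) and `triggers`
#'   (data frame of the (participant, roi, metric, z) triples at or below
#'   the threshold).
#' @export
flag_outliers <- function(ztable, threshold = 1.5) {
  if (threshold <= 0) nn_stop("threshold must be positive")
  hit <- ztable$z <= -threshold
  triggers <- ztable[hit, c("participant_id", "roi_name", "metric",
                            "tissue_class", "z"), drop = FALSE]
  rownames(triggers) <- NULL
  list(flagged_ids = unique(triggers$participant_id), triggers = triggers)
}

#' Build robust norms and z-score the full sample
#'
#' The robust normative procedure: (1) the normative set is the cognitively
#' unimpaired, biomarker-negative (CU and A-T-) participants; (2) per
#' metric-by-ROI age/sex regressions are fit on that set; (3) initial
#' z-scores are computed for the normative set; (4) participants scoring at
#' or below minus the exclusion threshold in any cell are removed (one
#' pass by default); (5) the regressions are refit on the reduced set and
#' their coefficients, RMSE and age-centering constant frozen; (6) every
#' participant (CU, MCI, AD) is z-scored against the frozen model.
#'
#' @param roi_table Long ROI table.
#' @param participants Participant table with `diagnosis` and `at_status`.
#' @param config A [norms_config()].
#' @return List with `model` (class `normative_model`) and `zscores` (the
#'   full-sample z-score table).
#' @export
build_norms <- function(roi_table, participants, config = norms_config()) {
  stopifnot(inherits(config, "norms_config"))
  need <- c("participant_id", "age", "sex", "diagnosis", "at_status")
  missing <- setdiff(need, names(participants))
  if (length(missing) > 0) {
    nn_stop(sprintf("participants lacks column(s): %s",
                    paste(missing, collapse = ", ")))
  }
  roi_table <- roi_table[roi_table$metric %in% config$metrics, , drop = FALSE]
  if (nrow(roi_table) == 0L) nn_stop("ROI table has no rows for the configured metrics")
  normative_ids <- participants$participant_id[
    participants$diagnosis == "CU" & participants$at_status == "A-T-"
  ]
  normative_ids <- intersect(normative_ids, unique(roi_table$participant_id))
  if (length(normative_ids) == 0L) {
    nn_stop("no CU A-T- participants available for the normative set")
  }
  current_ids <- normative_ids
  excluded <- list()
  repeat {
    fit <- fit_all_cells(roi_table, participants, current_ids,
                         config$rmse_denominator)
    model <- structure(
      list(coefficients = fit$coefficients, age_center = fit$age_center,
           exclusion_threshold = config$exclusion_threshold,
           rmse_denominator = config$rmse_denominator),
      class = "normative_model"
    )
    znorm <- compute_zscores(
      model,
      roi_table[roi_table$participant_id %in% current_ids, , drop = FALSE],
      participants
    )
    flags <- flag_outliers(znorm, config$exclusion_threshold)
    if (length(flags$flagged_ids) == 0L) break
    excluded[[length(excluded) + 1L]] <- flags$triggers
    current_ids <- setdiff(current_ids, flags$flagged_ids)
    if (length(current_ids) < config$min_n) {
      nn_stop_numeric(sprintf(
        "reduced normative set (n = %d) below minimum (%d): a larger normative sample is required",
        length(current_ids), config$min_n
      ))
    }
    if (!config$iterate) break
  }
  # Freeze the final fit on the reduced set.
  fit <- fit_all_cells(roi_table, participants, current_ids,
                       config$rmse_denominator)
  triggers <- if (length(excluded) > 0) {
    do.call(rbind, excluded)
  } else {
    data.frame(participant_id = character(0), roi_name = character(0),
               metric = character(0), tissue_class = character(0),
               z = numeric(0), stringsAsFactors = FALSE)
  }
  model <- structure(
    list(coefficients = fit$coefficients, age_center = fit$age_center,
         exclusion_threshold = config$exclusion_threshold,
         rmse_denominator = config$rmse_denominator,
         excluded = triggers,
         normative_ids_initial = normative_ids,
         normative_ids_final = current_ids),
    class = "normative_model"
  )
  list(model = model, zscores = compute_zscores(model, roi_table, participants))
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Robust normative model\n")
  cat(sprintf("  cells fitted: %d (age-centered at %.2f years)\n",
              nrow(x$coefficients), x$age_center))
  if (!is.null(x$normative_ids_initial)) {
    cat(sprintf("  normative set: %d initial, %d excluded (z <= -%.2f), %d final\n",
                length(x$normative_ids_initial),
                length(x$normative_ids_initial) - length(x$normative_ids_final),
                x$exclusion_threshold,
                length(x$normative_ids_final)))
  }
  invisible(x)
}

#' Serialize / restore a normative model
#'
#' The frozen model (coefficients, RMSE, age-centering constant, excluded
#' ids) is written as JSON so norms can be applied to new cohorts.
#'
#' @param model A `normative_model`.
#' @param path JSON file path.
#' @return `write_norms()` returns `path` invisibly; `read_norms()`
#'   returns the restored `normative_model`.
#' @export
write_norms <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  payload <- unclass(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- as.data.frame(raw$coefficients,
                                    stringsAsFactors = FALSE)
  raw$excluded <- as.data.frame(raw$excluded, stringsAsFactors = FALSE)
  structure(raw, class = "normative_model")
}
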