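#' Model-suite configuration
#'
#' Options for the ten-model Firth logistic comparison.  The outcome is
#' cognitively unimpaired (CU) versus an impaired group — the combined
#' MCI/AD group by default, or MCI or AD alone.  A/T status enters model 1
#' as a single ordinal covariate coded 1 = A-T-, 2 = A+T-, 3 = A+T+
#' (dummy coding available behind a flag); NODDI covariates are the six
#' raw bilateral ROI means per metric-by-tissue block (a z-score variant
#' is available for exploration).  The PLR reference defaults to model 0
#' (age + sex only).
#'
#' @param outcome `"MCI/AD"` (default), `"MCI"`, or `"AD"`.
#' @param covariate_source `"raw"` ROI values (default) or `"zscore"`.
#' @param at_coding `"ordinal"` (default) or `"dummy"`.
#' @param plr_reference Model id (`"0"`–`"9"`) used as PLR reference.
#' @param tol,max_iter,conf.level Passed to [fit_firth_logistic()] /
#'   [delong_auc_ci()].
#' @return An object of class `suite_config`.
#' @export
suite_config <- function(outcome = c("MCI/AD", "MCI", "AD"),
                         covariate_source = c("raw", "zscore"),
                         at_coding = c("ordinal", "dummy"),
                         plr_reference = "0",
                         tol = 1e-8, max_iter = 150L, conf.level = 0.95) {
  structure(
    list(outcome = match.arg(outcome),
         covariate_source = match.arg(covariate_source),
         at_coding = match.arg(at_coding),
         plr_reference = as.character(plr_reference),
         tol = tol, max_iter = as.integer(max_iter),
         conf.level = conf.level),
    class = "suite_config"
  )
}

# Wide covariate matrix of ROI values: one column per metric-by-ROI cell,
# named <tissue>_<metric>_<roi>.
roi_wide <- function(roi_table, value_col = "value") {
  ids <- unique(roi_table$participant_id)
  keys <- unique(paste(roi_table$tissue_class, roi_table$metric,
                       roi_table$roi_name, sep = "_"))
  mat <- matrix(NA_real_, length(ids), length(keys),
                dimnames = list(ids, keys))
  mat[cbind(match(roi_table$participant_id, ids),
            match(paste(roi_table$tissue_class, roi_table$metric,
                        roi_table$roi_name, sep = "_"), keys))] <-
    roi_table[[value_col]]
  mat
}

suite_model_specs <- function() {
  blocks <- c("WM_NDI", "WM_ODI", "GM_NDI", "GM_ODI")
  specs <- list(
    "0" = list(label = "age + sex", at = FALSE, block = NULL),
    "1" = list(label = "CSF A/T status", at = TRUE, block = NULL)
  )
  for (i in seq_along(blocks)) {
    specs[[as.character(i + 1L)]] <-
      list(label = gsub("_", " ", blocks[i]), at = FALSE, block = blocks[i])
  }
  for (i in seq_along(blocks)) {
    specs[[as.character(i + 5L)]] <-
      list(label = paste("CSF A/T status +", gsub("_", " ", blocks[i])),
           at = TRUE, block = blocks[i])
  }
  specs
}

#' Run the ten-model Firth logistic suite
#'
#' Fits models 0–9 predicting clinical status (CU vs the configured
#' impaired group), each controlling for age and sex: (0) age + sex only;
#' (1) + A/T status; (2)–(5) + the six ROI values of one metric-by-tissue
#' block (WM NDI, WM ODI, GM NDI, GM ODI); (6)–(9) A/T status + each ROI
#' block.  Each model reports the Firth fit, in-sample AUC with DeLong
#' confidence interval, AIC on the penalized log-likelihood, and the
#' penalized likelihood ratio against the configured reference model.
#'
#' @param participants Analysis-sample participant table (after
#'   [select_analysis_sample()]); must contain CU and impaired rows.
#' @param roi_table Long ROI table of raw bilateral means (or z-scores
#'   when `covariate_source = "zscore"`; the value column is then `z`).
#' @param config A [suite_config()].
#' @return An object of class `model_suite`: `results` (one row per
#'   model) and `fits` (named list of `firth_fit`s).
#' @export
run_model_suite <- function(participants, roi_table,
                            config = suite_config()) {
  stopifnot(inherits(config, "suite_config"))
  case_levels <- switch(config$outcome,
    "MCI/AD" = c("MCI", "AD"), MCI = "MCI", AD = "AD"
  )
  keep <- participants$diagnosis %in% c("CU", case_levels)
  pt <- participants[keep, , drop = FALSE]
  y <- as.integer(pt$diagnosis %in% case_levels)
  if (length(unique(y)) < 2L) {
    nn_stop("suite needs both outcome classes after selection")
  }
  if (any(pt$at_status == "A-T+")) {
    nn_stop("A-T+ participants present: run select_analysis_sample() first")
  }
  at_ord <- match(pt$at_status, c("A-T-", "A+T-", "A+T+"))
  value_col <- if (config$covariate_source == "zscore") "z" else "value"
  wide <- roi_wide(roi_table, value_col)
  widx <- match(pt$participant_id, rownames(wide))
  if (anyNA(widx)) {
    nn_stop(sprintf("ROI values missing for participant(s): %s",
                    paste(pt$participant_id[is.na(widx)], collapse = ", ")))
  }
  wide <- wide[widx, , drop = FALSE]
  if (anyNA(wide)) nn_stop("incomplete ROI table: NA covariate values")

  at_cols <- if (config$at_coding == "ordinal") {
    matrix(at_ord, ncol = 1, dimnames = list(NULL, "at_status"))
  } else {
    cbind(at_pos_tneg = as.integer(at_ord == 2L),
          at_pos_tpos = as.integer(at_ord == 3L))
  }
  base <- cbind(`(Intercept)` = 1, age = pt$age, sex = pt$sex)
  specs <- suite_model_specs()
  fits <- list()
  rows <- list()
  for (id in names(specs)) {
    sp <- specs[[id]]
    x <- base
    if (sp$at) x <- cbind(x, at_cols)
    if (!is.null(sp$block)) {
      cols <- grep(paste0("^", sp$block, "_"), colnames(wide), value = TRUE)
      if (length(cols) == 0L) {
        nn_stop(sprintf("no ROI columns found for block %s", sp$block))
      }
      x <- cbind(x, wide[, cols, drop = FALSE])
    }
    fit <- fit_firth_logistic(x, y, tol = config$tol,
                              max_iter = config$max_iter,
                              conf.level = config$conf.level)
    fits[[id]] <- fit
    auc <- roc_auc(fit$fitted, y)
    ci <- delong_auc_ci(fit$fitted, y, conf.level = config$conf.level)
    rows[[id]] <- data.frame(
      model_id = id, label = sp$label, n = length(y),
      n_covariates = length(fit$coefficients),
      auc = auc, auc_ci_low = ci$ci_low, auc_ci_high = ci$ci_high,
      aic = NA_real_, plr = NA_real_, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  }
  ref <- fits[[config$plr_reference]]
  if (is.null(ref)) nn_stop("plr_reference must name one of models 0-9")
  for (id in names(rows)) {
    stats <- model_fit_stats(fits[[id]],
                             if (id != config$plr_reference) ref else NULL)
    rows[[id]]$aic <- stats$aic
    rows[[id]]$plr <- if (id == config$plr_reference) 0 else stats$plr
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, fits = fits, config = config),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("Firth logistic model suite (outcome CU vs %s, n = %d)\n",
              x$config$outcome, x$results$n[1]))
  df <- x$results[, c("model_id", "label", "auc", "auc_ci_low",
                      "auc_ci_high", "aic", "plr")]
  df[, 3:7] <- round(df[, 3:7], 3)
  print(df, row.names = FALSE)
  invisible(x)
}
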