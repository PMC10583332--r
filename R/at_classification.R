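#' CSF biomarker cutoff configuration
#'
#' Cutoffs dichotomizing CSF analytes into amyloid (A) and tau (T) status.
#' Amyloid positivity is defined by an Abeta42/Abeta40 ratio *strictly below*
#' the ratio cutoff; tau positivity by p-Tau181 *at or above* the p-Tau
#' cutoff.  Defaults are the published Elecsys/NeuroToolKit values
#' (ratio < 0.046, p-Tau >= 24.8 pg/mL); both are configurable for
#' sensitivity analyses.
#'
#' @param abeta_ratio_cutoff Dimensionless Abeta42/Abeta40 ratio cutoff.
#' @param ptau_cutoff p-Tau181 concentration cutoff (pg/mL semantics).
#' @param abeta42_cutoff Optional secondary cutoff on raw Abeta42: when
#'   set, amyloid positivity is defined by `abeta42 < abeta42_cutoff`
#'   instead of the ratio rule.  Unconfigured (`NULL`) by default — both
#'   rules gave identical classifications in the validation cohorts the
#'   cutoffs come from, so the ratio rule is the primary definition.
#' @return An object of class `cutoff_config`.
#' @export
cutoff_config <- function(abeta_ratio_cutoff = 0.046, ptau_cutoff = 24.8,
                          abeta42_cutoff = NULL) {
  check_scalar_number(abeta_ratio_cutoff, "abeta_ratio_cutoff", positive = TRUE)
  check_scalar_number(ptau_cutoff, "ptau_cutoff", positive = TRUE)
  if (!is.null(abeta42_cutoff)) {
    check_scalar_number(abeta42_cutoff, "abeta42_cutoff", positive = TRUE)
  }
  structure(
    list(abeta_ratio_cutoff = abeta_ratio_cutoff, ptau_cutoff = ptau_cutoff,
         abeta42_cutoff = abeta42_cutoff),
    class = "cutoff_config"
  )
}

#' A/T status levels
#'
#' @return Character vector of the four A/T states in canonical order.
#' @export
at_levels <- function() c("A-T-", "A+T-", "A+T+", "A-T+")

#' Classify CSF A/T biomarker status
#'
#' Assigns each participant to one of the four A/T cells from raw CSF
#' analyte concentrations.  A+ iff `abeta42/abeta40 < abeta_ratio_cutoff`
#' (strict); T+ iff `ptau >= ptau_cutoff` (inclusive).  The joint (Abeta42,
#' Abeta40) classification is scale-invariant: multiplying both analytes by
#' the same positive constant leaves A status unchanged.
#'
#' @param abeta42,abeta40,ptau Numeric vectors of CSF concentrations
#'   (recycling is not performed; lengths must match).
#' @param cutoffs A [cutoff_config()].
#' @return Character vector with values among [at_levels()].
#' @export
#' @examples
#' classify_at(800, 20000, 30)  # ratio 0.040 -> "A+T+"
classify_at <- function(abeta42, abeta40, ptau, cutoffs = cutoff_config()) {
  stopifnot(inherits(cutoffs, "cutoff_config"))
  n <- length(abeta42)
  if (length(abeta40) != n || length(ptau) != n) {
    nn_stop("abeta42, abeta40 and ptau must have equal length")
  }
  if (n == 0L) return(character(0))
  if (anyNA(abeta42) || anyNA(abeta40) || anyNA(ptau)) {
    bad <- which(is.na(abeta42) | is.na(abeta40) | is.na(ptau))
    nn_stop(sprintf(
      "missing CSF analyte value(s) at row(s): %s",
      paste(head(bad, 10L), collapse = ", ")
    ))
  }
  if (any(!is.finite(abeta42) | !is.finite(abeta40) | !is.finite(ptau))) {
    nn_stop("CSF analyte values must be finite")
  }
  if (any(abeta40 <= 0)) {
    bad <- which(abeta40 <= 0)
    nn_stop(sprintf(
      "abeta40 <= 0 at row(s) %s: Abeta42/Abeta40 ratio undefined",
      paste(head(bad, 10L), collapse = ", ")
    ))
  }
  a_pos <- if (is.null(cutoffs$abeta42_cutoff)) {
    (abeta42 / abeta40) < cutoffs$abeta_ratio_cutoff
  } else {
    abeta42 < cutoffs$abeta42_cutoff
  }
  t_pos <- ptau >= cutoffs$ptau_cutoff
  ifelse(a_pos,
    ifelse(t_pos, "A+T+", "A+T-"),
    ifelse(t_pos, "A-T+", "A-T-")
  )
}

#' Apply the analysis-sample selection filter
#'
#' Retains participants on the AD A/T continuum: cognitively unimpaired (CU)
#' participants with A-T-, A+T- or A+T+ status, and impaired (MCI or AD)
#' participants only when amyloid-positive (A+T- or A+T+).  A-T+
#' participants fall outside the AD A/T criteria and are excluded regardless
#' of diagnosis.  Every dropped row is returned in an exclusion ledger with
#' a reason; retained and excluded rows partition the input exactly.
#'
#' @param participants Data frame with at least `participant_id`,
#'   `diagnosis` (one of CU/MCI/AD) and `at_status` columns.
#' @return A list with elements `retained` (data frame of kept rows) and
#'   `excluded` (ledger with `participant_id`, `diagnosis`, `at_status`,
#'   `reason`).
#' @export
select_analysis_sample <- function(participants) {
  req <- c("participant_id", "diagnosis", "at_status")
  missing <- setdiff(req, names(participants))
  if (length(missing) > 0) {
    nn_stop(sprintf("participants lacks column(s): %s",
                    paste(missing, collapse = ", ")))
  }
  bad_diag <- setdiff(unique(participants$diagnosis), c("CU", "MCI", "AD"))
  if (length(bad_diag) > 0) {
    nn_stop(sprintf("unknown diagnosis label(s): %s",
                    paste(bad_diag, collapse = ", ")))
  }
  bad_at <- setdiff(unique(participants$at_status), at_levels())
  if (length(bad_at) > 0) {
    nn_stop(sprintf("unknown at_status label(s): %s",
                    paste(bad_at, collapse = ", ")))
  }
  dg <- participants$diagnosis
  at <- participants$at_status
  keep <- (dg == "CU" & at %in% c("A-T-", "A+T-", "A+T+")) |
    (dg %in% c("MCI", "AD") & at %in% c("A+T-", "A+T+"))
  reason <- rep(NA_character_, nrow(participants))
  reason[!keep & at == "A-T+"] <- "A-T+ outside AD A/T criteria"
  reason[!keep & is.na(reason)] <- "impaired without amyloid positivity"
  list(
    retained = participants[keep, , drop = FALSE],
    excluded = data.frame(
      participant_id = participants$participant_id[!keep],
      diagnosis = dg[!keep],
      at_status = at[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}
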