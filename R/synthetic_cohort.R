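#' Default per-ROI NODDI baselines and residual scales
#'
#' Field-plausible baseline NDI/ODI values per region together with the
#' residual standard deviation of the generative model.  Gray-matter values
#' come from a GM-optimized NODDI fit (lower intrinsic diffusivity), white
#' matter from the standard fit; all values are dimensionless fractions in
#' (0, 1).
#'
#' @return Data frame with columns `roi_name`, `tissue_class`, `metric`,
#'   `baseline`, `residual_sd`.
#' @export
default_roi_baselines <- function() {
  cells <- noddi_cells()
  gm_ndi <- c(0.47, 0.44, 0.45, 0.48, 0.50, 0.49)
  gm_odi <- c(0.42, 0.46, 0.44, 0.45, 0.40, 0.43)
  wm_ndi <- c(0.62, 0.58, 0.64, 0.60, 0.57, 0.66)
  wm_odi <- c(0.28, 0.30, 0.26, 0.24, 0.29, 0.20)
  base <- numeric(nrow(cells))
  base[cells$tissue_class == "GM" & cells$metric == "NDI"] <- gm_ndi
  base[cells$tissue_class == "GM" & cells$metric == "ODI"] <- gm_odi
  base[cells$tissue_class == "WM" & cells$metric == "NDI"] <- wm_ndi
  base[cells$tissue_class == "WM" & cells$metric == "ODI"] <- wm_odi
  cells$baseline <- base
  cells$residual_sd <- 0.03
  cells
}

#' Default planted group effects
#'
#' Group-level shifts, in residual-SD units, that emulate the published
#' pattern of disease effects: lower GM ODI across cortical regions and
#' lower NDI in medial-temporal/posterior regions for impaired (MCI/AD)
#' participants; bidirectional WM ODI effects (uncinate and hippocampal
#' cingulum *higher*, inferior longitudinal fasciculus *lower* in MCI/AD);
#' and a milder preclinical decrease in posterior GM ODI for cognitively
#' unimpaired A+T+ participants.
#'
#' @return Data frame with columns `group_var` (`"diagnosis"` or
#'   `"at_status"`), `level`, `roi_name`, `metric`, `shift_sd`.
#' @export
default_group_effects <- function() {
  gm <- noddi_rois()$roi_name[1:6]
  eff <- rbind(
    # MCI/AD clinical effects, GM
    data.frame(level = "MCI/AD", roi_name = gm, metric = "ODI",
               shift_sd = -0.9, stringsAsFactors = FALSE),
    data.frame(level = "MCI/AD",
               roi_name = c("hippocampus", "parahippocampus",
                            "posterior_cingulate_gyrus"),
               metric = "NDI", shift_sd = -0.8, stringsAsFactors = FALSE),
    # MCI/AD clinical effects, WM NDI
    data.frame(level = "MCI/AD",
               roi_name = c("inferior_longitudinal_fasciculus",
                            "cingulum_hippocampus", "cingulum_cingulate"),
               metric = "NDI", shift_sd = -0.7, stringsAsFactors = FALSE),
    # Bidirectional WM ODI pattern
    data.frame(level = "MCI/AD",
               roi_name = c("uncinate_fasciculus", "cingulum_hippocampus",
                            "inferior_longitudinal_fasciculus"),
               metric = "ODI", shift_sd = c(0.9, 0.8, -0.6),
               stringsAsFactors = FALSE)
  )
  # The clinical shift applies to both impaired diagnosis levels.
  eff <- do.call(rbind, lapply(c("MCI", "AD"), function(lv) {
    out <- eff
    out$level <- lv
    out
  }))
  eff$group_var <- "diagnosis"
  # Preclinical A+T+ effect within CU: posterior GM ODI and forceps major.
  pre <- data.frame(
    group_var = "at_status", level = "A+T+",
    roi_name = c("posterior_cingulate_gyrus", "inf_parietal_precuneus",
                 "forceps_major"),
    metric = "ODI", shift_sd = c(-0.5, -0.45, -0.55),
    stringsAsFactors = FALSE
  )
  rbind(eff[, names(pre)], pre)
}

default_csf_params <- function() {
  list(
    abeta40 = list(meanlog = log(15000), sdlog = 0.25),
    ratio_neg = list(meanlog = log(0.075), sdlog = 0.25),
    ratio_pos = list(meanlog = log(0.032), sdlog = 0.30),
    ptau_neg = list(meanlog = log(17), sdlog = 0.30),
    ptau_pos = list(meanlog = log(34), sdlog = 0.30)
  )
}

#' Synthetic cohort configuration
#'
#' Configuration for the cohort generator.  Defaults mirror the study
#' demographics: 296 participants split as CU 231/26/28, MCI 0/1/5 and
#' AD 0/1/4 across the A-T-/A+T-/A+T+ cells, CU mean age 65.1 (SD 7.8),
#' MCI 71.8 (SD 9.7), AD 71.4 (SD 2.5), female fractions 65%/83%/40%.
#' CSF analytes are drawn from within-cell truncated log-normals so that
#' the assigned A/T cell is reproduced by [classify_at()] with probability
#' one.  An `A-T+` column is present (default zero counts) solely so the
#' analysis-sample exclusion filter can be exercised.
#'
#' @param n_per_group 3x4 integer matrix of counts, rows `CU`/`MCI`/`AD`,
#'   columns [at_levels()].
#' @param age_mean,age_sd Named numeric vectors (per diagnosis) in years.
#' @param age_range Truncation bounds for ages, years.
#' @param female_fraction Named numeric vector (per diagnosis) in \[0, 1\].
#' @param csf_params Location/scale (log scale) for Abeta40, the
#'   Abeta42/Abeta40 ratio conditional on A status, and p-Tau conditional
#'   on T status; see [default_csf_params()] source for the layout.
#' @param cutoffs A [cutoff_config()] used both for truncated sampling and
#'   for the consistency check.
#' @param roi_baselines Data frame as returned by
#'   [default_roi_baselines()].
#' @param age_slope,sex_effect Named numeric vectors (per metric): linear
#'   age effect (metric units per year, ages centered at `age_center`) and
#'   additive female-vs-male effect (metric units).
#' @param age_center Reference age (years) of the generative model.
#' @param group_effects Data frame of planted shifts in residual-SD units,
#'   see [default_group_effects()].
#' @param seed Integer seed governing the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = NULL,
                          age_mean = c(CU = 65.10, MCI = 71.77, AD = 71.36),
                          age_sd = c(CU = 7.81, MCI = 9.73, AD = 2.52),
                          age_range = c(45, 95),
                          female_fraction = c(CU = 186 / 285, MCI = 5 / 6,
                                              AD = 2 / 5),
                          csf_params = default_csf_params(),
                          cutoffs = cutoff_config(),
                          roi_baselines = default_roi_baselines(),
                          age_slope = c(NDI = -0.001, ODI = 0.0005),
                          sex_effect = c(NDI = 0.005, ODI = -0.003),
                          age_center = 65,
                          group_effects = default_group_effects(),
                          seed = 1234L) {
  if (is.null(n_per_group)) {
    n_per_group <- matrix(
      c(231L, 26L, 28L, 0L,
        0L, 1L, 5L, 0L,
        0L, 1L, 4L, 0L),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("CU", "MCI", "AD"), at_levels())
    )
  }
  cfg <- structure(
    list(
      n_per_group = n_per_group, age_mean = age_mean, age_sd = age_sd,
      age_range = age_range, female_fraction = female_fraction,
      csf_params = csf_params, cutoffs = cutoffs,
      roi_baselines = roi_baselines, age_slope = age_slope,
      sex_effect = sex_effect, age_center = age_center,
      group_effects = group_effects, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) nn_stop("not a cohort_config")
  npg <- config$n_per_group
  if (!is.matrix(npg) || !identical(rownames(npg), c("CU", "MCI", "AD")) ||
      !identical(colnames(npg), at_levels())) {
    nn_stop("n_per_group must be a 3x4 matrix with rows CU/MCI/AD and columns A-T-/A+T-/A+T+/A-T+")
  }
  if (any(npg < 0) || any(npg != round(npg))) {
    nn_stop("n_per_group: counts must be non-negative integers")
  }
  for (nm in c("age_mean", "age_sd", "female_fraction")) {
    v <- config[[nm]]
    if (!all(c("CU", "MCI", "AD") %in% names(v))) {
      nn_stop(sprintf("%s must be named per diagnosis (CU, MCI, AD)", nm))
    }
  }
  if (any(config$age_sd <= 0)) nn_stop("age_sd: must be > 0")
  if (any(config$female_fraction < 0 | config$female_fraction > 1)) {
    nn_stop("female_fraction: must lie in [0, 1]")
  }
  rb <- config$roi_baselines
  req <- c("roi_name", "tissue_class", "metric", "baseline", "residual_sd")
  if (!all(req %in% names(rb))) {
    nn_stop(sprintf("roi_baselines must have columns %s",
                    paste(req, collapse = ", ")))
  }
  if (any(rb$residual_sd <= 0)) nn_stop("residual_sd: must be > 0")
  if (any(rb$baseline <= 0 | rb$baseline >= 1)) {
    nn_stop("roi baselines must lie strictly in (0, 1)")
  }
  for (p in config$csf_params) {
    if (p$sdlog <= 0) nn_stop("csf_params: sdlog scale must be > 0")
  }
  if (!is.finite(config$seed)) nn_stop("seed must be a finite integer")
  invisible(config)
}

sample_csf_cell <- function(n, cell, csf, cutoffs) {
  # Sample strictly on the cutoff side of the assigned cell.  An epsilon
  # guards the inverse-CDF against landing exactly on the boundary through
  # floating-point rounding.
  eps <- 1e-9
  rc <- cutoffs$abeta_ratio_cutoff
  pc <- cutoffs$ptau_cutoff
  a_pos <- grepl("A\\+", cell, fixed = FALSE)
  t_pos <- grepl("T\\+", cell, fixed = FALSE)
  abeta40 <- rlnorm_trunc(n, csf$abeta40$meanlog, csf$abeta40$sdlog)
  ratio <- if (a_pos) {
    rlnorm_trunc(n, csf$ratio_pos$meanlog, csf$ratio_pos$sdlog,
                 upper = rc * (1 - eps))
  } else {
    rlnorm_trunc(n, csf$ratio_neg$meanlog, csf$ratio_neg$sdlog,
                 lower = rc * (1 + eps))
  }
  ptau <- if (t_pos) {
    rlnorm_trunc(n, csf$ptau_pos$meanlog, csf$ptau_pos$sdlog,
                 lower = pc * (1 + eps))
  } else {
    rlnorm_trunc(n, csf$ptau_neg$meanlog, csf$ptau_neg$sdlog,
                 upper = pc * (1 - eps))
  }
  data.frame(abeta42 = ratio * abeta40, abeta40 = abeta40, ptau = ptau)
}

#' Generate a synthetic participant table
#'
#' Draws exactly the configured number of participants per diagnosis-by-A/T
#' cell, with truncated-normal ages, Bernoulli sex (1 = female, 0 = male)
#' and truncated log-normal CSF analytes constrained to the cutoff side of
#' the assigned cell.  The derived `at_status` column is verified against
#' [classify_at()] before the table is returned.  The same seed always
#' yields the identical table.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `participant_id`, `age`, `sex`,
#'   `diagnosis`, `abeta42`, `abeta40`, `ptau`, `at_status`.
#' @export
generate_participants <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  cols <- c("participant_id", "age", "sex", "diagnosis",
            "abeta42", "abeta40", "ptau", "at_status")
  total <- sum(config$n_per_group)
  if (total == 0L) {
    out <- data.frame(
      participant_id = character(0), age = numeric(0), sex = integer(0),
      diagnosis = character(0), abeta42 = numeric(0), abeta40 = numeric(0),
      ptau = numeric(0), at_status = character(0), stringsAsFactors = FALSE
    )
    return(out[, cols])
  }
  pieces <- list()
  for (dg in rownames(config$n_per_group)) {
    for (cell in colnames(config$n_per_group)) {
      n <- config$n_per_group[dg, cell]
      if (n == 0L) next
      age <- rnorm_trunc(n, config$age_mean[[dg]], config$age_sd[[dg]],
                         config$age_range[1], config$age_range[2])
      sex <- rbinom(n, 1L, config$female_fraction[[dg]])
      csf <- sample_csf_cell(n, cell, config$csf_params, config$cutoffs)
      pieces[[length(pieces) + 1L]] <- data.frame(
        age = age, sex = sex, diagnosis = dg,
        abeta42 = csf$abeta42, abeta40 = csf$abeta40, ptau = csf$ptau,
        at_status = cell, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pieces)
  out$participant_id <- sprintf("P%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  derived <- classify_at(out$abeta42, out$abeta40, out$ptau, config$cutoffs)
  if (!all(derived == out$at_status)) {
    nn_stop_numeric("internal error: sampled CSF values contradict the assigned A/T cell")
  }
  out[, cols]
}

#' Generate ROI-level NODDI values for a participant table
#'
#' Produces the long ROI table `value = baseline + age_slope * (age -
#' age_center) + sex_effect * sex + shift_sd * residual_sd + noise`,
#' truncated to (0, 1).  The planted (noiseless) means and shifts are
#' attached as `attr(, "planted")` so recovery tests can compare against
#' ground truth.
#'
#' @param participants Data frame from [generate_participants()].
#' @param config A [cohort_config()].
#' @return Long data frame with columns `participant_id`, `roi_name`,
#'   `metric`, `tissue_class`, `value` (24 rows per participant).
#' @export
generate_roi_values <- function(participants, config = cohort_config()) {
  validate_cohort_config(config)
  if (nrow(participants) == 0L) nn_stop("participants table is empty")
  need <- c("participant_id", "age", "sex", "diagnosis", "at_status")
  missing <- setdiff(need, names(participants))
  if (length(missing) > 0) {
    nn_stop(sprintf("participants lacks column(s): %s",
                    paste(missing, collapse = ", ")))
  }
  bad <- !complete.cases(participants[, c("age", "sex")])
  if (any(bad)) {
    nn_stop(sprintf("participant(s) missing demographics: %s",
                    paste(participants$participant_id[bad], collapse = ", ")))
  }
  set.seed(config$seed + 1L)
  cells <- config$roi_baselines
  np <- nrow(participants)
  nc <- nrow(cells)
  pi_idx <- rep(seq_len(np), each = nc)
  ci_idx <- rep(seq_len(nc), times = np)
  grid <- data.frame(
    participant_id = participants$participant_id[pi_idx],
    roi_name = cells$roi_name[ci_idx],
    metric = cells$metric[ci_idx],
    tissue_class = cells$tissue_class[ci_idx],
    stringsAsFactors = FALSE
  )
  baseline <- cells$baseline[ci_idx]
  resid_sd <- cells$residual_sd[ci_idx]
  age <- participants$age[pi_idx]
  sex <- participants$sex[pi_idx]
  dg <- participants$diagnosis[pi_idx]
  at <- participants$at_status[pi_idx]
  shift <- numeric(nrow(grid))
  ge <- config$group_effects
  if (!is.null(ge) && nrow(ge) > 0) {
    for (i in seq_len(nrow(ge))) {
      hit <- grid$roi_name == ge$roi_name[i] & grid$metric == ge$metric[i] &
        (if (ge$group_var[i] == "diagnosis") dg else at) == ge$level[i]
      shift[hit] <- shift[hit] + ge$shift_sd[i]
    }
  }
  mu <- baseline +
    config$age_slope[grid$metric] * (age - config$age_center) +
    config$sex_effect[grid$metric] * sex +
    shift * resid_sd
  value <- mu + rnorm(nrow(grid), 0, resid_sd)
  eps <- 1e-6
  value <- pmin(pmax(value, eps), 1 - eps)
  grid$value <- unname(value)
  planted <- grid[, c("participant_id", "roi_name", "metric", "tissue_class")]
  planted$mu <- unname(mu)
  planted$shift_sd <- shift
  planted$residual_sd <- resid_sd
  attr(grid, "planted") <- planted
  grid
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_participants()] and
#' [generate_roi_values()] under the single configured seed.
#'
#' @param config A [cohort_config()].
#' @return List with elements `participants` and `roi_values`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  participants <- generate_participants(config)
  roi_values <- if (nrow(participants) > 0) {
    generate_roi_values(participants, config)
  } else {
    data.frame(participant_id = character(0), roi_name = character(0),
               metric = character(0), tissue_class = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  }
  list(participants = participants, roi_values = roi_values)
}
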