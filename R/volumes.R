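#' Co-registered volume set
#'
#' Container for the voxel-level inputs of ROI extraction: white-matter and
#' CSF fraction maps, NODDI metric maps (named; separate GM- and
#' WM-optimized fits are distinguished by name, e.g. `NDI_GM`, `ODI_WM`),
#' an integer gray-matter label map (0 = background, left/right parcels
#' coded separately) and per-tract probability maps.  All volumes must
#' share one grid (dimensions and affine); registration is out of scope and
#' replaced by this grid-equality requirement.
#'
#' @param wm_fraction,csf_fraction 3D arrays with values in \[0, 1\].
#' @param metric_maps Named list of 3D arrays with values in \[0, 1\].
#' @param gm_labels 3D array of non-negative integer labels.
#' @param tract_probability Named list (by tract key) of 3D arrays with
#'   values in \[0, 1\].
#' @param affine 4x4 voxel-to-world matrix (honored on NIfTI I/O; no
#'   reorientation is performed).
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(wm_fraction, csf_fraction, metric_maps, gm_labels,
                       tract_probability, affine = diag(4)) {
  dims <- dim(wm_fraction)
  if (length(dims) != 3L) nn_stop("volumes must be 3D arrays")
  all_vols <- c(list(csf_fraction = csf_fraction, gm_labels = gm_labels),
                metric_maps, tract_probability)
  for (nm in names(all_vols)) {
    if (!identical(dim(all_vols[[nm]]), dims)) {
      nn_stop(sprintf("grid mismatch: '%s' does not share the common shape", nm))
    }
  }
  for (fr in list(wm_fraction = wm_fraction, csf_fraction = csf_fraction)) {
    if (any(fr < 0 | fr > 1)) nn_stop("fraction maps must lie in [0, 1]")
  }
  if (any(gm_labels < 0) || any(gm_labels != round(gm_labels))) {
    nn_stop("gm_labels must be non-negative integers")
  }
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L))) {
    nn_stop("affine must be a 4x4 matrix")
  }
  structure(
    list(dim = dims, affine = affine, wm_fraction = wm_fraction,
         csf_fraction = csf_fraction, metric_maps = metric_maps,
         gm_labels = gm_labels, tract_probability = tract_probability),
    class = "volume_set"
  )
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    nn_stop(sprintf("grid mismatch: %s do not share a common shape", what))
  }
  invisible(TRUE)
}

#' Synthesize a gray-matter fraction map
#'
#' `gm = clamp(1 - wm - csf, 0, 1)` voxelwise.  The raw subtraction can go
#' negative where `wm + csf > 1`; fractions are physically bounded, so the
#' result is clamped to \[0, 1\].
#'
#' @param wm_fraction,csf_fraction 3D arrays (or numeric vectors) on one
#'   grid with values in \[0, 1\].
#' @return Array of gray-matter fractions in \[0, 1\].
#' @export
#' @examples
#' compute_gm_fraction(0.3, 0.2)  # 0.5
compute_gm_fraction <- function(wm_fraction, csf_fraction) {
  check_same_grid(wm_fraction, csf_fraction, "wm_fraction and csf_fraction")
  if (any(wm_fraction < 0 | wm_fraction > 1) ||
      any(csf_fraction < 0 | csf_fraction > 1)) {
    nn_stop("fraction maps must lie in [0, 1]")
  }
  pmin(pmax(1 - wm_fraction - csf_fraction, 0), 1)
}

#' Build a pseudo-T1 contrast volume
#'
#' Tissue fraction maps are multiplied by their class values (CSF = 0,
#' WM = 1, GM = 2) and summed, giving a volume in \[0, 2\] with T1-like
#' contrast that supports registration between diffusion and structural
#' space (the registration itself is outside this package's scope).
#'
#' @param gm_fraction,wm_fraction,csf_fraction 3D arrays on one grid.
#' @return Pseudo-T1 array with values in \[0, 2\].
#' @export
#' @examples
#' build_pseudo_t1(0.5, 0.3, 0.2)  # 1.3
build_pseudo_t1 <- function(gm_fraction, wm_fraction, csf_fraction) {
  check_same_grid(gm_fraction, wm_fraction, "gm_fraction and wm_fraction")
  check_same_grid(gm_fraction, csf_fraction, "gm_fraction and csf_fraction")
  0 * csf_fraction + 1 * wm_fraction + 2 * gm_fraction
}

#' GM-fraction-masked ROI mean
#'
#' Unweighted mean of a metric map over voxels that carry one of the ROI's
#' label codes *and* have gray-matter fraction at or above the threshold
#' (the boundary is inclusive: a voxel at exactly the threshold counts).
#'
#' @param metric_map,gm_fraction,gm_labels 3D arrays on one grid.
#' @param label_codes Integer label code(s) of the ROI (e.g. one
#'   hemisphere's code).
#' @param threshold GM-fraction threshold in (0, 1); default 0.7.
#' @param roi_name Name used in error messages.
#' @return Scalar mean metric value.
#' @export
gm_masked_roi_mean <- function(metric_map, gm_fraction, gm_labels,
                               label_codes, threshold = 0.7,
                               roi_name = "ROI") {
  check_same_grid(metric_map, gm_fraction, "metric_map and gm_fraction")
  check_same_grid(metric_map, gm_labels, "metric_map and gm_labels")
  if (threshold <= 0 || threshold >= 1) nn_stop("threshold must lie in (0, 1)")
  mask <- (gm_labels %in% label_codes) & (gm_fraction >= threshold)
  if (!any(mask)) {
    nn_stop_numeric(sprintf(
      "empty ROI '%s': no voxel passes label and GM-fraction >= %g", roi_name,
      threshold
    ))
  }
  mean(metric_map[mask])
}

#' Tract-probability-weighted mean
#'
#' `sum(p * v) / sum(p)` over voxels with positive probability, weighting
#' the tract core more heavily than its partial-volume-prone borders.
#' Zero-probability voxels contribute nothing.
#'
#' @param metric_map,probability_map 3D arrays on one grid; probabilities
#'   in \[0, 1\].
#' @param roi_name Name used in error messages.
#' @return Scalar weighted mean.
#' @export
tract_weighted_mean <- function(metric_map, probability_map,
                                roi_name = "tract") {
  check_same_grid(metric_map, probability_map,
                  "metric_map and probability_map")
  if (any(probability_map < 0 | probability_map > 1)) {
    nn_stop("probabilities must lie in [0, 1]")
  }
  pos <- probability_map > 0
  total <- sum(probability_map[pos])
  if (!any(pos) || total <= 0) {
    nn_stop_numeric(sprintf("empty tract '%s': all probabilities are zero",
                            roi_name))
  }
  sum(probability_map[pos] * metric_map[pos]) / total
}

#' ROI extraction specification
#'
#' Maps each gray-matter ROI to its (left, right) label codes and each
#' white-matter ROI to one or two tract-probability keys (a left/right pair
#' is averaged after extraction; a single key is treated as already
#' bilateral), and names the metric map used per tissue class.
#'
#' @param gm_rois Named list: `roi_name -> c(left_code, right_code)`.
#' @param wm_rois Named list: `roi_name -> tract key(s)`.
#' @param gm_threshold GM-fraction threshold in (0, 1).
#' @param metric_keys List with elements `GM` and `WM`, each a named vector
#'   mapping metric (`NDI`, `ODI`) to a metric-map name.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(gm_rois, wm_rois, gm_threshold = 0.7,
                     metric_keys = list(
                       GM = c(NDI = "NDI_GM", ODI = "ODI_GM"),
                       WM = c(NDI = "NDI_WM", ODI = "ODI_WM")
                     )) {
  if (gm_threshold <= 0 || gm_threshold >= 1) {
    nn_stop("gm_threshold must lie in (0, 1)")
  }
  structure(list(gm_rois = gm_rois, wm_rois = wm_rois,
                 gm_threshold = gm_threshold, metric_keys = metric_keys),
            class = "roi_spec")
}

#' Read an ROI extraction spec from YAML
#'
#' YAML layout: `gm_rois:` maps each ROI name to `[left_code, right_code]`;
#' `wm_rois:` maps each tract to one or two probability-map keys;
#' optional `gm_threshold` and `metric_keys` (per tissue class) override
#' the defaults.
#'
#' @param path YAML file path.
#' @return An [roi_spec()].
#' @export
read_roi_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    gm_rois = lapply(y$gm_rois, function(v) as.integer(unlist(v))),
    wm_rois = lapply(y$wm_rois, function(v) as.character(unlist(v)))
  )
  if (!is.null(y$gm_threshold)) args$gm_threshold <- y$gm_threshold
  if (!is.null(y$metric_keys)) {
    args$metric_keys <- lapply(y$metric_keys, function(v) unlist(v))
  }
  do.call(roi_spec, args)
}

#' Extract a bilateral-mean ROI table from volumes
#'
#' Gray-matter entries are GM-fraction-masked means computed per hemisphere
#' and then averaged left/right; white-matter entries are
#' tract-probability-weighted means (averaged across per-side maps when the
#' spec lists a pair).  The gray-matter fraction map is synthesized from
#' the WM and CSF fractions via [compute_gm_fraction()].
#'
#' @param volumes A [volume_set()].
#' @param spec An [roi_spec()]; every configured ROI must be resolvable in
#'   `volumes`.
#' @param participant_id Id recorded in the output rows.
#' @return Long ROI data frame (one row per ROI x metric) with the same
#'   schema as [generate_roi_values()].
#' @export
extract_roi_table <- function(volumes, spec, participant_id = "subject") {
  stopifnot(inherits(volumes, "volume_set"), inherits(spec, "roi_spec"))
  gm_fraction <- compute_gm_fraction(volumes$wm_fraction,
                                     volumes$csf_fraction)
  rows <- list()
  get_map <- function(key) {
    m <- volumes$metric_maps[[key]]
    if (is.null(m)) nn_stop(sprintf("metric map '%s' not found in volumes", key))
    m
  }
  for (roi in names(spec$gm_rois)) {
    codes <- spec$gm_rois[[roi]]
    if (length(codes) != 2L) {
      nn_stop(sprintf("GM ROI '%s' needs (left, right) label codes", roi))
    }
    for (metric in names(spec$metric_keys$GM)) {
      map <- get_map(spec$metric_keys$GM[[metric]])
      left <- gm_masked_roi_mean(map, gm_fraction, volumes$gm_labels,
                                 codes[1], spec$gm_threshold,
                                 roi_name = paste0(roi, " (left)"))
      right <- gm_masked_roi_mean(map, gm_fraction, volumes$gm_labels,
                                  codes[2], spec$gm_threshold,
                                  roi_name = paste0(roi, " (right)"))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participant_id, roi_name = roi, metric = metric,
        tissue_class = "GM", value = (left + right) / 2,
        stringsAsFactors = FALSE
      )
    }
  }
  for (roi in names(spec$wm_rois)) {
    keys <- spec$wm_rois[[roi]]
    for (metric in names(spec$metric_keys$WM)) {
      map <- get_map(spec$metric_keys$WM[[metric]])
      vals <- vapply(keys, function(k) {
        prob <- volumes$tract_probability[[k]]
        if (is.null(prob)) {
          nn_stop(sprintf("tract probability map '%s' (ROI '%s') not found",
                          k, roi))
        }
        tract_weighted_mean(map, prob, roi_name = roi)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participant_id, roi_name = roi, metric = metric,
        tissue_class = "WM", value = mean(vals), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
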