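#' Region-of-interest panel
#'
#' The analysis operates on a fixed panel of twelve bilateral regions with
#' established vulnerability to Alzheimer's disease: six cortical gray-matter
#' regions (AAL-style parcels, with the inferior parietal lobe and precuneus
#' combined into one region) and six white-matter association tracts
#' (JHU-style tractography regions).  Both NODDI metrics (NDI, ODI) are
#' carried for every region.
#'
#' @return `noddi_rois()` returns a data frame with columns `roi_name` and
#'   `tissue_class` (`"GM"` or `"WM"`); `noddi_cells()` expands it by
#'   `metric` (`"NDI"`, `"ODI"`), giving the 24 metric-by-region cells.
#' @export
#' @examples
#' noddi_rois()
noddi_rois <- function() {
  data.frame(
    roi_name = c(
      "superior_frontal_gyrus", "parahippocampus", "hippocampus",
      "inferior_temporal", "posterior_cingulate_gyrus",
      "inf_parietal_precuneus",
      "cingulum_cingulate", "cingulum_hippocampus",
      "superior_longitudinal_fasciculus", "inferior_longitudinal_fasciculus",
      "uncinate_fasciculus", "forceps_major"
    ),
    tissue_class = rep(c("GM", "WM"), each = 6L),
    stringsAsFactors = FALSE
  )
}

#' @rdname noddi_rois
#' @export
noddi_cells <- function() {
  rois <- noddi_rois()
  out <- rois[rep(seq_len(nrow(rois)), each = 2L), , drop = FALSE]
  out$metric <- rep(c("NDI", "ODI"), times = nrow(rois))
  rownames(out) <- NULL
  out
}

# Canonical key used to match coefficient tables against ROI tables.
cell_key <- function(roi_name, metric, tissue_class) {
  paste(roi_name, metric, tissue_class, sep = "|")
}
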