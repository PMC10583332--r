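#' Write a volume set as NIfTI-1 files
#'
#' Emits `wm_fraction.nii.gz`, `csf_fraction.nii.gz`, `gm_labels.nii.gz`,
#' one `metric_<name>.nii.gz` per metric map and one `tract_<key>.nii.gz`
#' per tract-probability map, all carrying the set's affine.
#'
#' @param volumes A [volume_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_volume_set <- function(volumes, dir) {
  stopifnot(inherits(volumes, "volume_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    RNifti::sform(img) <- structure(volumes$affine, code = 2L)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(volumes$wm_fraction, "wm_fraction")
  wr(volumes$csf_fraction, "csf_fraction")
  wr(volumes$gm_labels, "gm_labels")
  for (nm in names(volumes$metric_maps)) {
    wr(volumes$metric_maps[[nm]], paste0("metric_", nm))
  }
  for (nm in names(volumes$tract_probability)) {
    wr(volumes$tract_probability[[nm]], paste0("tract_", nm))
  }
  invisible(dir)
}

#' Read a volume set from a directory of NIfTI-1 files
#'
#' Counterpart of [write_volume_set()]: loads every `metric_*` and
#' `tract_*` file plus the fraction and label volumes, checks the shared
#' grid, and rebuilds the [volume_set()].  Affines are honored as stored;
#' no reorientation is performed.
#'
#' @param dir Directory written by [write_volume_set()].
#' @return A [volume_set()].
#' @export
read_volume_set <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(path)) nn_stop(sprintf("missing volume file: %s", path))
    img <- RNifti::readNifti(path)
    list(data = array(as.numeric(img), dim(img)),
         affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
  }
  files <- list.files(dir, pattern = "\\.nii\\.gz$")
  metric_names <- sub("^metric_(.*)\\.nii\\.gz$", "\\1",
                      grep("^metric_", files, value = TRUE))
  tract_names <- sub("^tract_(.*)\\.nii\\.gz$", "\\1",
                     grep("^tract_", files, value = TRUE))
  wm <- rd("wm_fraction")
  csf <- rd("csf_fraction")
  labels <- rd("gm_labels")
  metric_maps <- lapply(setNames(metric_names, metric_names),
                        function(nm) rd(paste0("metric_", nm))$data)
  tract_probability <- lapply(setNames(tract_names, tract_names),
                              function(nm) rd(paste0("tract_", nm))$data)
  lab <- round(labels$data)
  storage.mode(lab) <- "integer"
  volume_set(wm$data, csf$data, metric_maps, lab, tract_probability,
             affine = wm$affine)
}
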