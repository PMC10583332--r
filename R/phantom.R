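#' Phantom configuration
#'
#' Geometry and planted signal for the synthetic imaging phantom used to
#' test ROI extraction end-to-end.  Six gray-matter ROIs are cubic blobs
#' mirrored left/right at distinct axial levels; six white-matter tracts
#' are smooth Gaussian-profile tubes (per-side pairs).  Planted per-ROI
#' metric means default to [default_roi_baselines()].
#'
#' @param grid_dim Integer length-3 grid shape; each dimension must be at
#'   least 8 and large enough to place all ROIs without overlap.
#' @param voxel_mm Isotropic voxel size (mm), used for the affine.
#' @param planted Data frame `roi_name`, `tissue_class`, `metric`, `value`
#'   of planted in-ROI metric means.
#' @param noise_sd Voxelwise Gaussian noise SD added to metric maps.
#' @param background Named list of background levels for `ndi`, `odi`,
#'   `wm`, `csf`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(32L, 32L, 32L), voxel_mm = 2,
                           planted = NULL, noise_sd = 0,
                           background = list(ndi = 0.45, odi = 0.35,
                                             wm = 0.3, csf = 0.2)) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L || any(grid_dim < 8L)) {
    nn_stop("grid_dim must be three integers, each >= 8")
  }
  if (is.null(planted)) {
    planted <- default_roi_baselines()[, c("roi_name", "tissue_class",
                                           "metric", "baseline")]
    names(planted)[names(planted) == "baseline"] <- "value"
  }
  if (noise_sd < 0) nn_stop("noise_sd must be >= 0")
  structure(list(grid_dim = grid_dim, voxel_mm = voxel_mm,
                 planted = planted, noise_sd = noise_sd,
                 background = background),
            class = "phantom_config")
}

# Cube of voxel indices around a center; clamped coordinates must stay in
# the grid or the caller treats the placement as failed.
blob_coords <- function(center, radius, dims) {
  rng <- lapply(1:3, function(ax) {
    (center[ax] - radius):(center[ax] + radius)
  })
  if (any(vapply(1:3, function(ax) {
    rng[[ax]][1] < 1L || rng[[ax]][length(rng[[ax]])] > dims[ax]
  }, logical(1)))) {
    return(NULL)
  }
  as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
}

# Each tissue class uses two y-rows of three ROIs; ROIs within a row sit at
# three z-levels; left/right hemispheres at two x-columns.  Spacings are
# checked so cubes of the chosen radius cannot overlap.
phantom_layout <- function(dims) {
  radius <- max(1L, floor(min(dims) / 16))
  size <- 2L * radius + 1L
  zstep <- floor((dims[3] - 2L * (radius + 1L)) / 2L)
  if (zstep < size) nn_stop("grid too small to place all ROIs")
  zs <- radius + 1L + (0:2) * zstep
  ys <- round(dims[2] * c(0.15, 0.38, 0.62, 0.85))
  lx <- round(dims[1] * 0.3)
  rx <- round(dims[1] * 0.7)
  if (any(diff(sort(ys)) < size) || rx - lx < size) {
    nn_stop("grid too small to place all ROIs")
  }
  list(radius = radius, zs = zs,
       gm_y = ys[1:2], wm_y = ys[3:4], lx = lx, rx = rx)
}

# y-row and z-level of the i-th ROI (1..6) of a tissue class.
layout_slot <- function(lay, ys, i) {
  c(y = ys[if (i <= 3L) 1L else 2L], z = lay$zs[((i - 1L) %% 3L) + 1L])
}

#' Generate phantom volumes with planted ROI means
#'
#' Deterministically (given `seed`) builds a [volume_set()] whose tissue
#' fractions sum to at most one everywhere, whose GM blobs pass a 0.7
#' GM-fraction threshold, and whose metric maps carry the configured
#' planted per-ROI means (plus optional Gaussian noise).  The matching
#' [roi_spec()] and the planted-truth table are attached as attributes
#' `"roi_spec"` and `"planted"`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return A [volume_set()] with attributes `roi_spec` and `planted`.
#' @export
generate_phantom_volumes <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(as.integer(seed))
  dims <- config$grid_dim
  lay <- phantom_layout(dims)
  bg <- config$background
  wm <- array(bg$wm, dims)
  csf <- array(bg$csf, dims)
  labels <- array(0L, dims)
  rois <- noddi_rois()
  gm_names <- rois$roi_name[rois$tissue_class == "GM"]
  wm_names <- rois$roi_name[rois$tissue_class == "WM"]
  gm_codes <- lapply(seq_along(gm_names), function(i) c(100L + i, 200L + i))
  names(gm_codes) <- gm_names

  used <- array(FALSE, dims)
  place <- function(center) {
    xyz <- blob_coords(center, lay$radius, dims)
    if (is.null(xyz)) nn_stop("grid too small to place all ROIs")
    idx <- xyz[, 1] + dims[1] * (xyz[, 2] - 1L) + dims[1] * dims[2] * (xyz[, 3] - 1L)
    if (any(used[idx])) nn_stop("grid too small: ROI placements overlap")
    used[idx] <<- TRUE
    idx
  }

  gm_idx <- list()
  for (i in seq_along(gm_names)) {
    slot <- layout_slot(lay, lay$gm_y, i)
    left <- place(c(lay$lx, slot["y"], slot["z"]))
    right <- place(c(lay$rx, slot["y"], slot["z"]))
    labels[left] <- gm_codes[[i]][1]
    labels[right] <- gm_codes[[i]][2]
    # High GM fraction inside cortical blobs (gm = 1 - wm - csf = 0.85).
    wm[c(left, right)] <- 0.10
    csf[c(left, right)] <- 0.05
    gm_idx[[gm_names[i]]] <- list(left = left, right = right)
  }

  tract_prob <- list()
  wm_idx <- list()
  for (i in seq_along(wm_names)) {
    sides <- list(left = lay$lx, right = lay$rx)
    slot <- layout_slot(lay, lay$wm_y, i)
    idx_both <- list()
    for (side in names(sides)) {
      center <- c(sides[[side]], slot["y"], slot["z"])
      core <- place(center)
      # Smooth probability profile: 1 at the tract core, decaying with
      # Chebyshev distance toward the border.
      xyz <- blob_coords(center, lay$radius, dims)
      cheb <- pmax(abs(xyz[, 1] - center[1]), abs(xyz[, 2] - center[2]),
                   abs(xyz[, 3] - center[3]))
      prob <- array(0, dims)
      prob[core] <- exp(-(cheb / max(1, lay$radius))^2)
      wm[core] <- 0.9
      csf[core] <- 0.05
      idx_both[[side]] <- core
      tract_prob[[paste(wm_names[i], side, sep = "_")]] <- prob
    }
    wm_idx[[wm_names[i]]] <- idx_both
  }

  planted <- config$planted
  pval <- function(roi, metric) {
    v <- planted$value[planted$roi_name == roi & planted$metric == metric]
    if (length(v) != 1L) {
      nn_stop(sprintf("planted mean missing for %s %s", roi, metric))
    }
    v
  }
  metric_maps <- list(
    NDI_GM = array(bg$ndi, dims), ODI_GM = array(bg$odi, dims),
    NDI_WM = array(bg$ndi, dims), ODI_WM = array(bg$odi, dims)
  )
  for (roi in gm_names) {
    idx <- c(gm_idx[[roi]]$left, gm_idx[[roi]]$right)
    metric_maps$NDI_GM[idx] <- pval(roi, "NDI")
    metric_maps$ODI_GM[idx] <- pval(roi, "ODI")
  }
  for (roi in wm_names) {
    idx <- c(wm_idx[[roi]]$left, wm_idx[[roi]]$right)
    metric_maps$NDI_WM[idx] <- pval(roi, "NDI")
    metric_maps$ODI_WM[idx] <- pval(roi, "ODI")
  }
  if (config$noise_sd > 0) {
    for (nm in names(metric_maps)) {
      noisy <- metric_maps[[nm]] + rnorm(prod(dims), 0, config$noise_sd)
      metric_maps[[nm]] <- array(pmin(pmax(noisy, 1e-6), 1 - 1e-6), dims)
    }
  }

  affine <- diag(c(rep(config$voxel_mm, 3), 1))
  vs <- volume_set(wm, csf, metric_maps, labels, tract_prob, affine)
  spec <- roi_spec(
    gm_rois = gm_codes,
    wm_rois = setNames(
      lapply(wm_names, function(r) paste0(r, c("_left", "_right"))),
      wm_names
    ),
    gm_threshold = 0.7
  )
  attr(vs, "roi_spec") <- spec
  attr(vs, "planted") <- planted
  vs
}
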