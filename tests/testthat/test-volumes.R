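test_that("GM fraction is the clamped complement of WM + CSF", {
  expect_equal(compute_gm_fraction(0.3, 0.2), 0.5)
  expect_equal(compute_gm_fraction(0.8, 0.4), 0)  # clamped at 0
  expect_equal(compute_gm_fraction(0, 0), 1)
  wm <- array(runif(27), c(3, 3, 3))
  csf <- array(runif(27) * (1 - wm), c(3, 3, 3))
  gm <- compute_gm_fraction(wm, csf)
  expect_true(all(gm >= 0 & gm <= 1))
  expect_equal(gm + wm + csf, array(1, c(3, 3, 3)))
  expect_error(compute_gm_fraction(array(0, c(3, 3, 3)), array(0, c(2, 3, 3))),
               "grid mismatch")
})

test_that("pseudo-T1 weights tissue classes as CSF=0, WM=1, GM=2", {
  expect_equal(build_pseudo_t1(0.5, 0.3, 0.2), 1.3)
  expect_equal(build_pseudo_t1(0, 0, 1), 0)   # pure CSF voxel
  expect_equal(build_pseudo_t1(1, 0, 0), 2)   # pure GM voxel
  # range [0, 2] and monotonicity in GM at fixed WM
  set.seed(1)
  wm <- runif(100)
  csf <- runif(100) * (1 - wm)
  gm <- 1 - wm - csf
  t1 <- build_pseudo_t1(gm, wm, csf)
  expect_true(all(t1 >= 0 & t1 <= 2))
  expect_true(all(build_pseudo_t1(gm + 0.01, wm, pmax(csf - 0.01, 0)) >= t1))
})

test_that("GM-masked ROI mean respects the inclusive threshold", {
  dims <- c(4, 1, 1)
  metric <- array(c(0.4, 0.6, 0.8, 0.9), dims)
  gmf <- array(c(0.9, 0.71, 0.5, 0.2), dims)
  labels <- array(c(1L, 1L, 1L, 0L), dims)
  expect_equal(gm_masked_roi_mean(metric, gmf, labels, 1L, 0.7), 0.5)
  # boundary: exactly 0.7 is included
  gmf2 <- array(c(0.7, 0.71, 0.5, 0.2), dims)
  expect_equal(gm_masked_roi_mean(metric, gmf2, labels, 1L, 0.7), 0.5)
  # empty mask is an explicit error carrying the ROI name
  gmf3 <- array(0.1, dims)
  expect_error(gm_masked_roi_mean(metric, gmf3, labels, 1L, 0.7,
                                  roi_name = "hippocampus"),
               "empty ROI 'hippocampus'")
})

test_that("tract-weighted mean is the probability-weighted average", {
  expect_equal(tract_weighted_mean(c(0.4, 0.6), c(0.25, 0.75)), 0.55)
  # uniform probabilities reduce to the unweighted mean
  v <- runif(10)
  expect_equal(tract_weighted_mean(v, rep(0.5, 10)), mean(v))
  # single-support degenerate case
  expect_equal(tract_weighted_mean(c(0.2, 0.9), c(0, 0.3)), 0.9)
  expect_error(tract_weighted_mean(c(0.2, 0.9), c(0, 0)), "empty tract")
  # bounded by the metric range on the support
  set.seed(2)
  for (i in 1:20) {
    v <- runif(30)
    p <- runif(30)
    p[sample(30, 10)] <- 0
    w <- tract_weighted_mean(v, p)
    expect_gte(w, min(v[p > 0]))
    expect_lte(w, max(v[p > 0]))
  }
})

test_that("phantom generation is deterministic and fully resolvable", {
  a <- generate_phantom_volumes(phantom_config(), seed = 9)
  b <- generate_phantom_volumes(phantom_config(), seed = 9)
  expect_identical(a$metric_maps, b$metric_maps)
  expect_identical(a$gm_labels, b$gm_labels)
  # every ROI non-empty under the 0.7 threshold on a 32^3 grid
  tab <- extract_roi_table(a, attr(a, "roi_spec"))
  expect_equal(nrow(tab), 24L)
  expect_true(all(tab$value > 0 & tab$value < 1))
  # fractions sum to <= 1 everywhere
  expect_true(all(a$wm_fraction + a$csf_fraction <= 1))
})

test_that("noiseless planted ROI means are recovered exactly", {
  ph <- generate_phantom_volumes(phantom_config(noise_sd = 0), seed = 4)
  tab <- extract_roi_table(ph, attr(ph, "roi_spec"), "phantom")
  m <- merge(tab, attr(ph, "planted"),
             by = c("roi_name", "tissue_class", "metric"))
  expect_equal(nrow(m), 24L)
  expect_equal(m$value.x, m$value.y, tolerance = 1e-12)
})

test_that("noisy planted means are recovered within sampling error", {
  sd <- 0.02
  ph <- generate_phantom_volumes(phantom_config(noise_sd = sd), seed = 6)
  spec <- attr(ph, "roi_spec")
  tab <- extract_roi_table(ph, spec, "phantom")
  m <- merge(tab, attr(ph, "planted"),
             by = c("roi_name", "tissue_class", "metric"))
  # each bilateral GM ROI mean pools 2 * (2r+1)^3 voxels
  r <- max(1, floor(32 / 16))
  nvox <- 2 * (2 * r + 1)^3
  gm <- m[m$tissue_class == "GM", ]
  expect_true(all(abs(gm$value.x - gm$value.y) < 3 * sd / sqrt(nvox)))
})

test_that("bilateral GM values average the two hemispheres", {
  ph <- generate_phantom_volumes(phantom_config(noise_sd = 0), seed = 5)
  spec <- attr(ph, "roi_spec")
  codes <- spec$gm_rois$hippocampus
  # plant asymmetric values in the two hippocampal blobs
  ph$metric_maps$NDI_GM[ph$gm_labels == codes[1]] <- 0.4
  ph$metric_maps$NDI_GM[ph$gm_labels == codes[2]] <- 0.6
  tab <- extract_roi_table(ph, spec)
  expect_equal(tab$value[tab$roi_name == "hippocampus" &
                           tab$metric == "NDI"], 0.5)
})

test_that("extraction is invariant to voxel storage order", {
  ph <- generate_phantom_volumes(phantom_config(noise_sd = 0.05), seed = 8)
  spec <- attr(ph, "roi_spec")
  tab <- extract_roi_table(ph, spec)
  # reverse every volume along all three axes: same voxel multisets
  flip <- function(a) {
    out <- a[dim(a)[1]:1, dim(a)[2]:1, dim(a)[3]:1]
    array(out, dim(a))
  }
  ph2 <- volume_set(flip(ph$wm_fraction), flip(ph$csf_fraction),
                    lapply(ph$metric_maps, flip), flip(ph$gm_labels),
                    lapply(ph$tract_probability, flip), ph$affine)
  tab2 <- extract_roi_table(ph2, spec)
  expect_equal(tab2$value, tab$value, tolerance = 1e-12)
})

test_that("a too-small grid raises a placement error", {
  expect_error(generate_phantom_volumes(phantom_config(grid_dim = c(8, 8, 8))),
               "grid too small")
  expect_error(phantom_config(grid_dim = c(4, 4, 4)), ">= 8")
})

test_that("NIfTI round-trip preserves the extraction result", {
  ph <- generate_phantom_volumes(phantom_config(grid_dim = c(16, 16, 16)),
                                 seed = 12)
  spec <- attr(ph, "roi_spec")
  dir <- withr::local_tempdir()
  write_volume_set(ph, dir)
  ph2 <- read_volume_set(dir)
  expect_equal(ph2$affine[1, 1], 2, tolerance = 1e-6)
  tab <- extract_roi_table(ph, spec)
  tab2 <- extract_roi_table(ph2, spec)
  expect_equal(tab2$value, tab$value, tolerance = 1e-6)
})
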