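# helper: an axis-aligned cube label on a 2 mm grid
cube_atlas <- function(dim = c(40L, 40L, 40L), spacing = 2, half_mm = 20,
                       thick_mm = NULL) {
  proto <- volume(array(0, dim), spacing = spacing)
  w <- striatr:::voxel_world_coords(proto)
  lab <- array(0L, dim)
  if (is.null(thick_mm)) {
    lab[abs(w[, 1]) <= half_mm & abs(w[, 2]) <= half_mm &
          abs(w[, 3]) <= half_mm] <- 1L
  } else {
    lab[abs(w[, 1]) <= thick_mm / 2 & abs(w[, 2]) <= half_mm &
          abs(w[, 3]) <= half_mm] <- 1L
  }
  label_volume(lab, c(cube = 1L), spacing = spacing)
}

test_that("a large cube's VOI boundary stays within one voxel of the edge", {
  atlas <- cube_atlas(half_mm = 20)            # 40 mm cube
  voi <- build_voi(atlas, voi_recipe("cube", 1L), fwhm_mm = 8)
  raw <- atlas$labels == 1L
  # voxels gained or lost relative to the raw support must touch the edge:
  # erode/dilate the raw support by one voxel and compare
  d <- dim(raw)
  sh <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    out[] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  grow <- raw
  shrink <- raw
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    grow <- grow | sh(raw, ax, by)
    shrink <- shrink & sh(raw, ax, by)
  }
  expect_true(all(voi$mask[shrink]))           # interior survives
  expect_true(!any(voi$mask[!grow]))           # no growth beyond 1 voxel
})

test_that("a 2 mm slab smooths below half maximum and errors as empty", {
  atlas <- cube_atlas(half_mm = 20, thick_mm = 2)
  expect_error(build_voi(atlas, voi_recipe("slab", 1L), fwhm_mm = 8),
               "empty")
  # oracle: 1D convolution of a 2 mm box with the 8 mm kernel peaks < 50
  sigma <- 8 / (2 * sqrt(2 * log(2)))
  peak <- 100 * (pnorm(1 / sigma) - pnorm(-1 / sigma))
  expect_lt(peak, 50)
})

test_that("VOI thresholding is strict and monotone", {
  atlas <- cube_atlas(half_mm = 16)
  v50 <- build_voi(atlas, voi_recipe("cube", 1L), threshold_pct = 50)
  v60 <- build_voi(atlas, voi_recipe("cube", 1L), threshold_pct = 60)
  expect_true(all(v60$mask <= v50$mask))       # 60% mask nested in 50%
  expect_gt(sum(v50$mask), sum(v60$mask))
})

test_that("smoothing at negligible width reproduces the raw support", {
  atlas <- cube_atlas(half_mm = 16)
  voi <- build_voi(atlas, voi_recipe("cube", 1L), fwhm_mm = 0.5)
  expect_equal(voi$mask, atlas$labels == 1L)
})

test_that("distant labels do not leak into each other's VOI", {
  dim <- c(40L, 40L, 40L)
  proto <- volume(array(0, dim), spacing = 2)
  w <- striatr:::voxel_world_coords(proto)
  lab <- array(0L, dim)
  lab[w[, 1] < -15 & w[, 1] > -30 & abs(w[, 2]) < 10 & abs(w[, 3]) < 10] <- 1L
  lab[w[, 1] > 15 & w[, 1] < 30 & abs(w[, 2]) < 10 & abs(w[, 3]) < 10] <- 2L
  atlas <- label_volume(lab, c(a = 1L, b = 2L), spacing = 2)
  voi <- build_voi(atlas, voi_recipe("a", 1L), fwhm_mm = 8)
  expect_false(any(voi$mask[lab == 2L]))
})

test_that("VOI volume of a large convex region stays within 5% of the label", {
  atlas <- cube_atlas(half_mm = 20)
  voi <- build_voi(atlas, voi_recipe("cube", 1L), fwhm_mm = 8)
  expect_lt(abs(sum(voi$mask) - sum(atlas$labels == 1L)) /
              sum(atlas$labels == 1L), 0.05)
})

test_that("standard_voi_set builds 7 nonempty region masks", {
  tpl <- template_set40()
  vois <- standard_voi_set(tpl$atlas)
  expect_setequal(names(vois),
                  c("caudate_left", "caudate_right", "putamen_left",
                    "putamen_right", "striatum_left", "striatum_right",
                    "occipital"))
  for (v in vois) expect_gt(sum(v$mask), 0)
  # laterality: left VOIs live at world x < 0
  wx <- striatr:::world_x_array(tpl$atlas)
  expect_true(all(wx[vois$caudate_left$mask] < 0))
  expect_true(all(wx[vois$putamen_right$mask] >= 0))
})

test_that("striatum is built from the union indicator before smoothing", {
  tpl <- template_set40()
  atlas <- tpl$atlas
  vois <- tpl$vois
  # oracle: smooth the union indicator directly and threshold
  ind <- array(0, dim(atlas$labels))
  wx <- striatr:::world_x_array(atlas)
  ind[atlas$labels %in% c(1L, 3L) & wx < 0] <- 100
  sm <- gaussian_smooth(volume(ind, spacing = atlas$spacing,
                               affine = atlas$affine), 8)
  expect_equal(vois$striatum_left$mask, sm$data > 50)
})

test_that("occipital VOI equals the smoothed-thresholded union of components", {
  tpl <- template_set40()
  atlas <- tpl$atlas
  ind <- array(0, dim(atlas$labels))
  ind[atlas$labels %in% c(5L, 6L)] <- 100
  sm <- gaussian_smooth(volume(ind, spacing = atlas$spacing,
                               affine = atlas$affine), 8)
  expect_equal(tpl$vois$occipital$mask, sm$data > 50)
})

test_that("missing required labels are reported", {
  lab <- array(0L, c(10, 10, 10)); lab[3:5, 3:5, 3:5] <- 1L
  atlas <- label_volume(lab, c(Caudate_L = 1L), spacing = 4)
  expect_error(standard_voi_set(atlas), "putamen")
  expect_error(build_voi(atlas, voi_recipe("x", 9L)), "9")
})
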