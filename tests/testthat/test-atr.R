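test_that("select_weight equals a literal brute-force template scan", {
  tpl <- template_set40()
  pair <- tpl$pair
  set.seed(17)
  base <- weighted_template(pair, 0.42)
  subject <- volume(base$data + rnorm(length(base$data),
                                      sd = 0.03 * max(base$data)),
                    spacing = base$spacing, affine = base$affine)
  mask <- brain_mask(pair$normal)
  # oracle: explicit zncc against each explicitly composed template
  ws <- seq.int(1L, 999L, by = 2L) / 1000
  brute <- vapply(ws, function(w)
    zncc_value(subject, weighted_template(pair, w), mask), numeric(1))
  sel <- select_weight(subject, pair, mask, grid_step = 0.002)
  expect_equal(sel$scan$zncc, brute, tolerance = 1e-12)
  expect_equal(sel$w, ws[which.max(brute)])
  expect_equal(sel$zncc, max(brute), tolerance = 1e-12)
})

test_that("noiseless mixture subjects are recovered exactly on the 0.1% grid", {
  pair <- template_set40()$pair
  for (w_true in c(0.05, 0.37, 0.81)) {
    sel <- select_weight(weighted_template(pair, w_true), pair)
    expect_equal(sel$w, w_true)
    expect_equal(sel$zncc, 1, tolerance = 1e-9)
  }
  # an endpoint subject pins the scan to the grid boundary
  sel_n <- select_weight(pair$normal, pair)
  expect_gte(sel_n$w, 0.99)
})

test_that("flat ZNCC profiles tie-break toward the more-normal template", {
  pair0 <- template_set40()$pair
  # identical parents make every mixture identical: a full 999-way tie
  pair <- template_pair(pair0$normal, pair0$normal)
  sel <- select_weight(pair$normal, pair)
  expect_equal(sel$w, 0.999)
})

test_that("the selected template correlates at least as well as both parents", {
  tpl <- template_set40()
  pair <- tpl$pair
  mask <- brain_mask(pair$normal)
  set.seed(23)
  for (i in 1:5) {
    w_true <- runif(1, 0.1, 0.9)
    base <- weighted_template(pair, w_true)
    subj <- volume(base$data + rnorm(length(base$data),
                                     sd = 0.05 * max(base$data)),
                   spacing = base$spacing, affine = base$affine)
    sel <- select_weight(subj, pair, mask)
    expect_gte(sel$zncc, zncc_value(subj, pair$normal, mask) - 1e-12)
    expect_gte(sel$zncc, zncc_value(subj, pair$egg, mask) - 1e-12)
  }
})

test_that("split selection recovers per-hemisphere weights", {
  pair <- template_set40()$pair
  # symmetric subject: both hemispheres agree within the grid step
  sym <- weighted_template(pair, 0.6)
  s <- select_weight_split(sym, pair)
  expect_lte(abs(s$w_left - s$w_right), 2 * 0.001)

  # hard-split asymmetric subject: exact recovery
  asym <- compose_split_template(pair, 0.8, 0.2, blend_fwhm_mm = 0)
  s2 <- select_weight_split(asym, pair)
  expect_equal(s2$w_left, 0.8)
  expect_equal(s2$w_right, 0.2)
  expect_equal(s2$mode, "split")

  # feathered construction still lands within one blend width of truth
  asym_b <- compose_split_template(pair, 0.8, 0.2, blend_fwhm_mm = 4)
  s3 <- select_weight_split(asym_b, pair)
  expect_lt(abs(s3$w_left - 0.8), 0.02)
  expect_lt(abs(s3$w_right - 0.2), 0.02)
})

test_that("an empty hemisphere under the mask is an error", {
  pair <- template_set40()$pair
  wx <- striatr:::world_x_array(pair$normal)
  right_only <- binary_voi(brain_mask(pair$normal)$mask & (wx > 0),
                           like = pair$normal)
  expect_error(select_weight_split(pair$normal, pair, right_only), "left")
})

test_that("the split composite fits asymmetric subjects at least as well", {
  pair <- template_set40()$pair
  mask <- brain_mask(pair$normal)
  set.seed(41)
  for (i in 1:3) {
    wl <- runif(1, 0.6, 0.95); wr <- runif(1, 0.05, 0.4)
    base <- compose_split_template(pair, wl, wr)
    subj <- volume(base$data + rnorm(length(base$data),
                                     sd = 0.03 * max(base$data)),
                   spacing = base$spacing, affine = base$affine)
    g <- select_weight(subj, pair, mask)
    s <- select_weight_split(subj, pair, mask)
    comp <- compose_split_template(pair, s$w_left, s$w_right)
    expect_gte(zncc_value(subj, comp, mask) + 1e-9,
               zncc_value(subj, weighted_template(pair, g$w), mask))
  }
})

test_that("fixed-mode normalization of the template itself is a fixed point", {
  tpl <- template_set40()
  fit <- atr(tpl$pair$normal, tpl$pair, mode = "fixed")
  rms <- sqrt(mean((fit$normalized$data - tpl$pair$normal$data)^2))
  expect_lt(rms, 0.02 * max(tpl$pair$normal$data))
  expect_null(fit$weights)
  expect_length(coef(fit), 0)
})

test_that("atr picks a disease-dominated weight for an egg-like phantom", {
  tpl <- template_set40()
  ph <- generate_phantom(phantom_spec(dim = grid40$dim,
                                      spacing = grid40$spacing,
                                      caudate_ratio = c(1.8, 1.8),
                                      putamen_ratio = c(1.4, 1.4),
                                      putamen_posterior_fraction =
                                        c(0.45, 0.45)),
                         seed = 51, compute_effective = FALSE)
  fit <- atr(ph$volume, tpl$pair, mode = "atr")
  expect_lt(coef(fit)[["w"]], 0.5)
  expect_s3_class(fit, "atr_fit")
})

test_that("split_atr weights straddle 0.5 for a mixed-pattern phantom", {
  tpl <- template_set40()
  ph <- generate_phantom(phantom_spec(dim = grid40$dim,
                                      spacing = grid40$spacing,
                                      caudate_ratio = c(4.2, 1.7),
                                      putamen_ratio = c(3.8, 1.4),
                                      putamen_posterior_fraction = c(1, 0.45)),
                         seed = 52, compute_effective = FALSE)
  fit <- atr(ph$volume, tpl$pair, mode = "split_atr")
  wts <- coef(fit)
  expect_gt(wts[["w_left"]], 0.5)
  expect_lt(wts[["w_right"]], 0.5)
})

test_that("the pipeline is deterministic given its inputs", {
  tpl <- template_set40()
  ph <- generate_phantom(phantom_spec(dim = grid40$dim,
                                      spacing = grid40$spacing,
                                      caudate_ratio = c(3, 2.4),
                                      putamen_ratio = c(2.8, 2)),
                         seed = 53, compute_effective = FALSE)
  f1 <- atr(ph$volume, tpl$pair, mode = "atr")
  f2 <- atr(ph$volume, tpl$pair, mode = "atr")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$normalized$data, f2$normalized$data)
})

test_that("stage failures carry the stage name", {
  tpl <- template_set40()
  flat <- volume(array(1, dim(tpl$pair$normal$data)),
                 spacing = tpl$pair$normal$spacing,
                 affine = tpl$pair$normal$affine)
  expect_error(atr(flat, tpl$pair, mode = "atr"), "affine")
})

test_that("fit methods print, summarize and expose the normalized volume", {
  tpl <- template_set40()
  fit <- atr(tpl$pair$egg, tpl$pair, mode = "atr")
  expect_output(print(fit), "mode: atr")
  s <- summary(fit)
  expect_output(print(s), "ZNCC")
  expect_true(is_volume(fitted(fit)))
  expect_lt(coef(fit)[["w"]], 0.35)   # the egg template is egg-dominated
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
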