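test_that("self-registration recovers the identity", {
  fx <- template_set40()$pair$normal
  a <- affine_register(fx, fx)
  p <- attr(a, "params")
  expect_lt(sqrt(sum(p[1:3]^2)), 0.5)            # translation < 0.5 mm
  expect_lt(max(abs(exp(p[7:9]) - 1)), 0.01)     # scale within 1%
  expect_gte(attr(a, "zncc"), attr(a, "zncc_initial"))
})

test_that("known translations and scales are recovered", {
  fx <- template_set64()$pair$normal
  tr <- affine_transform(translation = c(6, -4, 2))
  mv <- resample(fx, fx, tr)                     # mv(x) = fx(x + t)
  a <- affine_register(mv, fx)
  # registering back must find the inverse translation -t
  expect_lt(sqrt(sum((attr(a, "params")[1:3] + c(6, -4, 2))^2)), 1)

  sc <- affine_transform(scale = rep(1.1, 3))
  mvs <- resample(fx, fx, sc)
  a2 <- affine_register(mvs, fx)
  expect_lt(max(abs(exp(attr(a2, "params")[7:9]) - 1 / 1.1)) * 1.1, 0.02)
})

test_that("constant volumes cannot be registered", {
  flat <- volume(array(1, c(16, 16, 16)), spacing = 4)
  expect_error(affine_register(flat, flat), "constant")
})

test_that("nonlinear self-registration yields a near-zero field", {
  fx <- template_set40()$pair$normal
  f <- nonlinear_register(fx, fx)
  mag <- sqrt(f$displacement[, , , 1]^2 + f$displacement[, , , 2]^2 +
                f$displacement[, , , 3]^2)
  expect_lt(max(mag), 1)
})

test_that("the masked ZNCC trace never decreases and fields never fold", {
  tpl <- template_set40()
  ph <- generate_phantom(phantom_spec(dim = grid40$dim,
                                      spacing = grid40$spacing,
                                      caudate_ratio = c(3.5, 2),
                                      putamen_ratio = c(3, 1.6),
                                      deformation_amplitude_mm = 5),
                         seed = 31, compute_effective = FALSE)
  aff <- affine_register(ph$volume, tpl$pair$normal)
  aligned <- resample(ph$volume, tpl$pair$normal, aff)
  f <- nonlinear_register(aligned, tpl$pair$normal)
  for (lv in unique(f$trace$level))
    expect_true(all(diff(f$trace$zncc[f$trace$level == lv]) >= -1e-12))
  jac <- striatr:::jacobian_determinant(f$displacement,
                                        tpl$pair$normal$spacing)
  dm <- dim(jac)
  expect_true(all(jac[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)] > 0))
})

test_that("a 20% shortened structure is matched within 10%", {
  gs <- list(dim = c(48L, 48L, 48L), spacing = 4.6)
  full <- generate_phantom(phantom_spec(dim = gs$dim, spacing = gs$spacing),
                           seed = 3, compute_effective = FALSE)
  short <- generate_phantom(phantom_spec(dim = gs$dim, spacing = gs$spacing,
                                         putamen_posterior_fraction =
                                           c(0.8, 0.8)),
                            seed = 3, compute_effective = FALSE)
  mov <- full$standardized; tpl <- short$standardized
  f <- nonlinear_register(mov, tpl, iterations = c(25L, 15L),
                          field_fwhm_mm = 8, step_mm = 3, max_disp_mm = 12)
  warped <- apply_normalization(mov, NULL, f)
  # profile length above half maximum along the left putamen's long axis
  plen <- function(v) {
    i <- round((-28 - v$affine[1, 4]) / v$spacing[1]) + 1
    k <- round((2 - v$affine[3, 4]) / v$spacing[3]) + 1
    p <- v$data[i, , k]
    sum(p > 0.5 * (max(p) + 1)) * v$spacing[2]
  }
  expect_gt(plen(mov), plen(tpl))      # the premise: moving is longer
  expect_lt(abs(plen(warped) - plen(tpl)) / plen(tpl), 0.10)
})

test_that("the nonlinear stage halves the affine-only landmark error", {
  gs <- list(dim = c(48L, 48L, 48L), spacing = 4.6)
  ph <- generate_phantom(phantom_spec(dim = gs$dim, spacing = gs$spacing,
                                      caudate_ratio = c(4, 4),
                                      putamen_ratio = c(3.5, 3.5),
                                      deformation_amplitude_mm = 8),
                         seed = 21, compute_effective = FALSE)
  ref <- ph$standardized
  centroids <- function(v) {
    w <- striatr:::voxel_world_coords(v)
    sapply(1:4, function(id) {
      sel <- as.vector(ph$labels$labels == id)
      ctr <- colSums(w[sel, , drop = FALSE]) / sum(sel)
      near <- sqrt((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 +
                     (w[, 3] - ctr[3])^2) < 25
      wt <- pmax(as.vector(v$data) - 1, 0) * near
      colSums(w * wt) / sum(wt)
    })
  }
  truth_c <- centroids(ref)
  aff <- affine_register(ph$volume, ref)
  aligned <- resample(ph$volume, ref, aff)
  # richer schedule suited to this deformation scale
  f <- nonlinear_register(aligned, ref, iterations = c(20L, 12L),
                          field_fwhm_mm = 10, max_disp_mm = 12)
  warped <- apply_normalization(ph$volume, aff, f)
  err <- function(m) mean(sqrt(colSums((m - truth_c)^2)))
  expect_lt(err(centroids(warped)), 0.5 * err(centroids(aligned)))
})

test_that("apply_normalization composes into a single interpolation", {
  tpl <- template_set40()
  v <- tpl$pair$normal
  # identity affine + no field: unchanged
  out <- apply_normalization(v, diag(4), NULL, target_grid = v)
  expect_equal(out$data, v$data)

  # known affine + no field equals plain resampling
  tr <- affine_transform(translation = c(3, -2, 1), rotation = c(0, 0.03, 0))
  expect_equal(apply_normalization(v, tr, NULL, target_grid = v)$data,
               resample(v, v, tr)$data)

  # composed one-step warp is at least as faithful as two-step resampling
  ph <- generate_phantom(phantom_spec(dim = grid40$dim,
                                      spacing = grid40$spacing,
                                      deformation_amplitude_mm = 4),
                         seed = 13, compute_effective = FALSE)
  aff <- affine_register(ph$volume, v)
  aligned <- resample(ph$volume, v, aff)
  f <- nonlinear_register(aligned, v)
  one_step <- apply_normalization(ph$volume, aff, f)
  two_step <- apply_normalization(aligned, NULL, f)
  m <- brain_mask(v)
  expect_gte(zncc_value(one_step, ph$standardized, m) + 1e-9,
             zncc_value(two_step, ph$standardized, m))
})

test_that("grid mismatches are rejected", {
  tpl <- template_set40()
  small <- volume(array(1, c(10, 10, 10)), spacing = 2)
  expect_error(nonlinear_register(small, tpl$pair$normal), "grid-compatible")
  f <- nonlinear_register(tpl$pair$normal, tpl$pair$normal)
  expect_error(apply_normalization(small, diag(4), f,
                                   target_grid = small), "match")
})
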