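#' Affine pre-alignment of a subject to a template
#'
#' Multiresolution (3 levels by default) 12-parameter affine registration
#' maximizing masked ZNCC by Nelder-Mead search.  The recovered transform
#' maps fixed (template) world coordinates into moving (subject) world
#' coordinates, ready for [resample()] / [apply_normalization()].
#' Initialization translates the moving centre of intensity mass onto the
#' fixed one, so the search starts near the basin for ordinary head
#' repositioning.  The schedule is fixed and sampling deterministic:
#' identical inputs give identical transforms.
#'
#' @param moving,fixed nonconstant [volume()]s.
#' @param mask optional [binary_voi()] on the fixed grid restricting the
#'   metric; default is the fixed volume's [brain_mask()].
#' @param levels integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration budget per level (recycled).
#' @return An `atr_affine` matrix with attributes `zncc` (final metric)
#'   and `zncc_initial`.
#' @export
affine_register <- function(moving, fixed, mask = NULL,
                            levels = c(4L, 2L, 1L),
                            maxit = c(800L, 400L, 60L)) {
  stopifnot(is_volume(moving), is_volume(fixed))
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("cannot register constant volumes")
  if (is.null(mask)) mask <- brain_mask(fixed)
  maxit <- rep_len(maxit, length(levels))

  # centre-of-mass initialization (world mm)
  com <- function(v) {
    w <- pmax(v$data, 0)
    cw <- voxel_world_coords(v)
    colSums(cw * as.numeric(w)) / sum(w)
  }
  p <- numeric(12L)
  p[1:3] <- com(moving) - com(fixed)

  score_full <- function(par) {
    res <- resample(moving, fixed, params_to_affine(par))
    zncc_value(res, fixed, mask)
  }
  score0 <- score_full(p)
  trace <- score0
  best_p <- p
  best_score <- score0
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- coarsen(fixed, f)
    mk <- coarsen_mask(mask, f)
    if (sum(mk$mask) < 8L) next
    # smooth the moving image to the level's scale too, so both images see
    # the same resolution and the metric is unbiased
    mv <- if (f > 1L) gaussian_smooth(moving, f * min(moving$spacing))
          else moving
    wlev <- voxel_world_coords(fx)
    objective <- function(par) {
      tr <- try(params_to_affine(par), silent = TRUE)
      if (inherits(tr, "try-error")) return(1e6)
      res <- resample(mv, fx, tr, .world = wlev)
      if (stats::sd(res$data[mk$mask]) == 0) return(1e6)
      -zncc_value(res, fx, mk)
    }
    # chained Nelder-Mead runs: restarting with a fresh simplex escapes
    # the premature collapse 12-parameter simplices are prone to; the
    # cheap coarse levels get two runs, the full-resolution polish one
    for (restart in seq_len(if (f > 1L) 2L else 1L)) {
      opt <- stats::optim(p, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit[li], reltol = 1e-7,
                                         parscale = c(rep(8, 3), rep(0.08, 3),
                                                      rep(0.05, 3),
                                                      rep(0.05, 3))))
      if (opt$value <= objective(p)) p <- opt$par
    }
    sc <- score_full(p)
    trace <- c(trace, sc)
    if (sc > best_score) {
      best_score <- sc
      best_p <- p
    }
  }
  # keep the best level outcome by full-resolution metric (coarse-level
  # optima need not coincide exactly with the full-resolution optimum)
  p <- best_p
  final <- score_full(p)
  if (final < score0 - 1e-9)
    stop(sprintf("affine registration diverged (ZNCC trace: %s)",
                 paste(sprintf("%.4f", trace), collapse = " -> ")))
  out <- params_to_affine(p)
  attr(out, "zncc") <- final
  attr(out, "zncc_initial") <- score0
  attr(out, "params") <- p
  out
}

#' Nonlinear morphological standardization
#'
#' Small-deformation iterative registration of an affine-aligned subject
#' to its (weighted) template: a demons-style update driven by the local
#' intensity difference and image gradient, Gaussian regularization of
#' both the update and the accumulated field, and an accept-if-improved
#' rule on masked ZNCC, so the metric is non-decreasing over iterations by
#' construction.  Displacements are capped at `max_disp_mm` and the final
#' field is checked for folding (non-positive Jacobian determinant).
#'
#' @param moving [volume()] already affine-aligned onto the template grid.
#' @param template target [volume()] on the same grid.
#' @param mask optional metric mask; default [brain_mask()] of the
#'   template.
#' @param levels downsampling factors, coarse to fine.
#' @param iterations iterations per level (recycled).
#' @param field_fwhm_mm Gaussian FWHM regularizing the accumulated field.
#' @param update_fwhm_mm Gaussian FWHM smoothing each raw update.
#' @param step_mm maximum displacement increment per iteration (mm).
#' @param max_disp_mm cap on total displacement magnitude (mm).
#' @return An object of class `atr_deformation`: `displacement` (4D array,
#'   mm, on the template grid), grid geometry, and a `trace` of masked
#'   ZNCC per accepted iteration.
#' @export
nonlinear_register <- function(moving, template, mask = NULL,
                               levels = c(2L, 1L), iterations = c(10L, 6L),
                               field_fwhm_mm = 12, update_fwhm_mm = 5,
                               step_mm = 2, max_disp_mm = 10) {
  stopifnot(is_volume(moving), is_volume(template))
  stop_if_grid_mismatch(moving, template, "moving and template")
  if (is.null(mask)) mask <- brain_mask(template)
  iterations <- rep_len(iterations, length(levels))
  # gain/offset-match the moving image to the template under the mask so
  # the intensity-difference drive reflects shape, not scale (ZNCC itself
  # is gain-invariant, so the acceptance rule is unaffected)
  mm <- moving$data[mask$mask]; tt <- template$data[mask$mask]
  sdm <- stats::sd(mm)
  if (sdm > 0)
    moving <- volume((moving$data - mean(mm)) / sdm * stats::sd(tt) + mean(tt),
                     spacing = moving$spacing, affine = moving$affine)
  trace <- numeric(0)
  trace_level <- integer(0)
  disp <- NULL   # at current level resolution

  for (li in seq_along(levels)) {
    f <- levels[li]
    tp <- coarsen(template, f)
    mv <- coarsen(moving, f)
    mk <- coarsen_mask(mask, f)
    if (sum(mk$mask) < 8L) next
    dm <- dim(tp$data)
    disp <- if (is.null(disp)) array(0, c(dm, 3L))
            else upsample_field(disp, attr(disp, "grid"), tp)
    attr(disp, "grid") <- as_grid(tp)
    w <- voxel_world_coords(tp)

    warp_now <- function(d) {
      sw <- w
      sw[, 1] <- sw[, 1] + as.numeric(d[, , , 1])
      sw[, 2] <- sw[, 2] + as.numeric(d[, , , 2])
      sw[, 3] <- sw[, 3] + as.numeric(d[, , , 3])
      ijk <- world_to_index(mv$affine, sw)
      volume(array(interp_trilinear(mv$data, ijk), dm),
             spacing = tp$spacing, affine = tp$affine)
    }

    warped <- warp_now(disp)
    best <- zncc_value(warped, tp, mk)
    trace <- c(trace, best)
    trace_level <- c(trace_level, li)
    step <- step_mm
    fails <- 0L
    for (it in seq_len(iterations[li])) {
      diff <- tp$data - warped$data
      g <- image_gradient(warped)         # mm^-1 units
      gn2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
      denom <- gn2 + diff^2 / (mean(tp$spacing)^2 * 4) + 1e-8
      upd <- array(0, c(dm, 3L))
      for (c3 in 1:3) {
        u <- diff * g[, , , c3] / denom
        upd[, , , c3] <- smooth_component(u, update_fwhm_mm, tp$spacing)
      }
      # cap the per-iteration step
      un <- sqrt(upd[, , , 1]^2 + upd[, , , 2]^2 + upd[, , , 3]^2)
      mx <- max(un)
      if (mx > 0) upd <- upd * (step / mx)
      cand <- disp + upd
      for (c3 in 1:3)
        cand[, , , c3] <- smooth_component(cand[, , , c3], field_fwhm_mm,
                                           tp$spacing)
      cand <- cap_displacement(cand, max_disp_mm)
      wc <- warp_now(cand)
      sc <- zncc_value(wc, tp, mk)
      if (sc > best) {
        disp[] <- cand
        warped <- wc
        best <- sc
        trace <- c(trace, best)
        trace_level <- c(trace_level, li)
        fails <- 0L
      } else {
        step <- step / 2
        fails <- fails + 1L
        if (fails >= 3L) break
      }
    }
    attr(disp, "grid") <- as_grid(tp)
  }

  check_no_folding(disp, template)
  # metric values are only comparable within one resolution level
  structure(list(displacement = disp, spacing = template$spacing,
                 affine = template$affine,
                 trace = data.frame(level = trace_level, zncc = trace)),
            class = "atr_deformation")
}

#' @export
print.atr_deformation <- function(x, ...) {
  mag <- sqrt(x$displacement[, , , 1]^2 + x$displacement[, , , 2]^2 +
              x$displacement[, , , 3]^2)
  cat(sprintf("<atr_deformation> max |u| = %.2f mm, final ZNCC %.4f\n",
              max(mag), utils::tail(x$trace$zncc, 1)))
  invisible(x)
}

smooth_component <- function(arr, fwhm_mm, spacing) {
  sig <- fwhm_mm / FWHM_TO_SIGMA / spacing
  for (ax in 1:3) arr <- convolve_axis(arr, ax, sig[ax])
  arr
}

cap_displacement <- function(d, max_mm) {
  n <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  over <- n > max_mm
  if (any(over)) {
    sc <- ifelse(over, max_mm / n, 1)
    for (c3 in 1:3) d[, , , c3] <- d[, , , c3] * sc
  }
  d
}

# Central-difference spatial gradient in world mm^-1 (axis-aligned grids;
# general affines use the spacing norms, adequate for the metric drive).
image_gradient <- function(vol) {
  a <- vol$data
  dm <- dim(a)
  g <- array(0, c(dm, 3L))
  sp <- vol$spacing
  ix <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n))
  i1 <- ix(dm[1]); i2 <- ix(dm[2]); i3 <- ix(dm[3])
  g[, , , 1] <- (a[i1$hi, , ] - a[i1$lo, , ]) / (2 * sp[1])
  g[, , , 2] <- (a[, i2$hi, ] - a[, i2$lo, ]) / (2 * sp[2])
  g[, , , 3] <- (a[, , i3$hi] - a[, , i3$lo]) / (2 * sp[3])
  g
}

# Trilinearly upsample a coarse displacement field onto a finer grid.
upsample_field <- function(disp, coarse_grid, fine) {
  dmf <- dim(fine$data)
  out <- array(0, c(dmf, 3L))
  w <- voxel_world_coords(fine)
  ca <- coarse_grid$affine
  ijk <- world_to_index(ca, w)
  for (c3 in 1:3)
    out[, , , c3] <- array(interp_trilinear(disp[, , , c3], ijk), dmf)
  out
}

# Jacobian determinant of x + u(x) must stay positive (no folding).
check_no_folding <- function(disp, template) {
  dm <- dim(template$data)
  sp <- template$spacing
  jac <- jacobian_determinant(disp, sp)
  interior <- array(FALSE, dm)
  interior[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)] <- TRUE
  bad <- which(jac <= 0 & interior, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("deformation field folds at voxel (%d, %d, %d): Jacobian %.3g",
                 bad[1, 1], bad[1, 2], bad[1, 3],
                 jac[bad[1, 1], bad[1, 2], bad[1, 3]]))
  invisible(jac)
}

jacobian_determinant <- function(disp, spacing) {
  dm <- dim(disp)[1:3]
  ix <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n))
  i1 <- ix(dm[1]); i2 <- ix(dm[2]); i3 <- ix(dm[3])
  J <- vector("list", 9L)
  idx <- 1L
  for (c3 in 1:3) {
    u <- disp[, , , c3]
    du1 <- (u[i1$hi, , ] - u[i1$lo, , ]) / (2 * spacing[1])
    du2 <- (u[, i2$hi, ] - u[, i2$lo, ]) / (2 * spacing[2])
    du3 <- (u[, , i3$hi] - u[, , i3$lo]) / (2 * spacing[3])
    J[[idx]] <- du1 + (c3 == 1); J[[idx + 1L]] <- du2 + (c3 == 2)
    J[[idx + 2L]] <- du3 + (c3 == 3)
    idx <- idx + 3L
  }
  # rows of J are grad components of u_x+x, u_y+y, u_z+z
  J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
}

#' Apply the composed normalization to a subject volume
#'
#' Composes the affine and the deformation field into a single pull map,
#' so the subject is interpolated exactly once: for template-grid world
#' coordinate w the sampled subject position is
#' `affine %*% (w + u(w))`.
#'
#' @param subject original (unresampled) [volume()].
#' @param affine `atr_affine` from [affine_register()] (template world to
#'   subject world); `NULL` or `diag(4)` for identity.
#' @param field `atr_deformation` from [nonlinear_register()] on the
#'   template grid; `NULL` for a pure affine normalization.
#' @param target_grid grid to render into; defaults to the field's grid
#'   (or must be given when `field` is `NULL`).
#' @return The normalized `spect_volume` on the template grid.
#' @export
apply_normalization <- function(subject, affine = NULL, field = NULL,
                                target_grid = NULL) {
  stopifnot(is_volume(subject))
  if (is.null(target_grid)) {
    if (is.null(field))
      stop("need 'target_grid' when no deformation field is given")
    target_grid <- list(dim = dim(field$displacement)[1:3],
                        spacing = field$spacing, affine = field$affine)
  }
  tg <- as_grid(target_grid)
  if (!is.null(field) &&
      !isTRUE(all.equal(dim(field$displacement)[1:3], tg$dim,
                        check.attributes = FALSE)))
    stop("deformation field grid does not match the target grid")
  m <- if (is.null(affine)) diag(4) else unclass(as.matrix(affine))
  pull <- function(w) {
    if (!is.null(field)) {
      w[, 1] <- w[, 1] + as.numeric(field$displacement[, , , 1])
      w[, 2] <- w[, 2] + as.numeric(field$displacement[, , , 2])
      w[, 3] <- w[, 3] + as.numeric(field$displacement[, , , 3])
    }
    sw <- w %*% t(m[1:3, 1:3])
    sw[, 1] <- sw[, 1] + m[1, 4]
    sw[, 2] <- sw[, 2] + m[2, 4]
    sw[, 3] <- sw[, 3] + m[3, 4]
    sw
  }
  resample(subject, tg, pull)
}
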