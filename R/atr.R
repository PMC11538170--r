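#' Exhaustive template weight selection by ZNCC
#'
#' Scans the full 0.1 percent weight grid w in {0.001, 0.002, ..., 0.999}
#' (normal-template fraction), scoring the subject against each mixture
#' `w * normal + (1 - w) * egg` with masked [zncc()], and returns the
#' argmax.  Because the mixture is linear in `w`, each score is evaluated
#' exactly from six masked sufficient statistics; the result is
#' identically the brute-force scan over all 999 candidate templates (the
#' equality is asserted in the test suite).  Ties are broken toward larger
#' `w`, i.e. toward the more-normal template.
#'
#' @param subject_aligned [volume()] already affine-aligned onto the
#'   template grid.
#' @param pair a [template_pair()].
#' @param mask evaluation [binary_voi()]; default is the normal template's
#'   [brain_mask()].
#' @param grid_step weight grid step; must evenly divide [0.001, 0.999]
#'   (default 0.001, the 0.1 percent interval).
#' @return An object of class `atr_weights`: `mode = "global"`, `w`,
#'   `zncc` at the optimum, and the full `scan` data frame (w, zncc).
#' @export
select_weight <- function(subject_aligned, pair, mask = NULL,
                          grid_step = 0.001) {
  stopifnot(is_volume(subject_aligned), inherits(pair, "template_pair"))
  if (is.null(mask)) mask <- brain_mask(pair$normal)
  stop_if_grid_mismatch(subject_aligned, pair$normal, "subject and template")
  sel <- weight_scan(subject_aligned$data, pair, mask$mask, grid_step)
  structure(list(mode = "global", w = sel$w, zncc = sel$zncc,
                 scan = sel$scan),
            class = "atr_weights")
}

#' @rdname select_weight
#' @param hemisphere_mask optional [label_volume()] with labels 1 (left) /
#'   2 (right); default splits at world x = 0.
#' @return For `select_weight_split()`: `mode = "split"`, `w_left`,
#'   `w_right`, their ZNCC scores, and both scans.
#' @export
select_weight_split <- function(subject_aligned, pair, mask = NULL,
                                hemisphere_mask = NULL, grid_step = 0.001) {
  stopifnot(is_volume(subject_aligned), inherits(pair, "template_pair"))
  if (is.null(mask)) mask <- brain_mask(pair$normal)
  stop_if_grid_mismatch(subject_aligned, pair$normal, "subject and template")
  hemi <- if (is.null(hemisphere_mask)) hemisphere_arrays(pair$normal)
          else list(left = hemisphere_mask$labels == 1L,
                    right = hemisphere_mask$labels == 2L)
  out <- list(mode = "split")
  for (side in c("left", "right")) {
    m <- mask$mask & hemi[[side]]
    if (sum(m) < 2L)
      stop("fewer than 2 masked voxels in the ", side, " hemisphere")
    sel <- weight_scan(subject_aligned$data, pair, m, grid_step)
    out[[paste0("w_", side)]] <- sel$w
    out[[paste0("zncc_", side)]] <- sel$zncc
    out[[paste0("scan_", side)]] <- sel$scan
  }
  structure(out, class = "atr_weights")
}

# Exact ZNCC over the weight grid from masked sufficient statistics.
# For centered masked vectors s, n, e and T(w) = w n + (1-w) e:
#   cov(s, T) = w cov(s,n) + (1-w) cov(s,e)
#   var(T)    = w^2 var(n) + 2 w (1-w) cov(n,e) + (1-w)^2 var(e)
weight_scan <- function(subject_data, pair, mask_arr, grid_step) {
  step_i <- round(grid_step * 1000)
  if (!is.numeric(grid_step) || step_i < 1 ||
      abs(grid_step * 1000 - step_i) > 1e-9 || 998L %% step_i != 0L)
    stop("'grid_step' must evenly divide the interval [0.001, 0.999]")
  s <- subject_data[mask_arr]
  n <- pair$normal$data[mask_arr]
  e <- pair$egg$data[mask_arr]
  if (length(s) < 2L) stop("ZNCC needs at least 2 masked voxels")
  s <- s - mean(s); n <- n - mean(n); e <- e - mean(e)
  vs <- sum(s * s)
  if (vs <= 0) stop("ZNCC undefined: subject constant under mask")
  csn <- sum(s * n); cse <- sum(s * e); cne <- sum(n * e)
  vn <- sum(n * n); ve <- sum(e * e)
  w <- seq.int(1L, 999L, by = step_i) / 1000
  num <- w * csn + (1 - w) * cse
  den2 <- w^2 * vn + 2 * w * (1 - w) * cne + (1 - w)^2 * ve
  if (any(den2 <= 0)) stop("ZNCC undefined: a mixture is constant under mask")
  z <- num / sqrt(den2 * vs)
  best <- max(z)
  # tie-break toward larger w (the more-normal template); ties detected
  # with a 1e-12 slack so algebraically flat profiles count as tied
  i <- max(which(z >= best - 1e-12))
  list(w = w[i], zncc = z[i], scan = data.frame(w = w, zncc = z))
}

#' @export
print.atr_weights <- function(x, ...) {
  if (x$mode == "global")
    cat(sprintf("ATR weight selection: w = %.3f (ZNCC %.4f)\n", x$w, x$zncc))
  else
    cat(sprintf("split-ATR weights: left %.3f (ZNCC %.4f), right %.3f (ZNCC %.4f)\n",
                x$w_left, x$zncc_left, x$w_right, x$zncc_right))
  invisible(x)
}

#' Default ATR pipeline configuration
#'
#' @param grid_step weight grid step (0.001 = the 0.1 percent interval).
#' @param outer_iterations weight re-selection passes after nonlinear
#'   warping (convergence when the selected weight moves < `w_tol`).
#' @param w_tol convergence tolerance on the selected weight.
#' @param mask_frac brain-mask threshold as a fraction of template max.
#' @param blend_fwhm_mm split-template midline feather width (mm).
#' @param affine_levels,affine_maxit multiresolution schedule of the
#'   affine stage.
#' @param nl_levels,nl_iterations,field_fwhm_mm,update_fwhm_mm,step_mm,max_disp_mm
#'   nonlinear-stage controls (see [nonlinear_register()]).
#' @return A named list of class `atr_config`.
#' @export
atr_config <- function(grid_step = 0.001, outer_iterations = 2L,
                       w_tol = 0.005, mask_frac = 0.2, blend_fwhm_mm = 4,
                       affine_levels = c(4L, 2L, 1L),
                       affine_maxit = c(800L, 400L, 40L),
                       nl_levels = c(2L, 1L), nl_iterations = c(10L, 6L),
                       field_fwhm_mm = 12, update_fwhm_mm = 5,
                       step_mm = 2, max_disp_mm = 10) {
  structure(as.list(environment()), class = "atr_config")
}

#' Fit the adaptive template registration model to a subject
#'
#' The full MRI-free normalization pipeline, in the order: (1) affine
#' pre-alignment of the subject to the normal template; (2) unless
#' `mode = "fixed"`, exhaustive ZNCC weight selection over the 0.1 percent
#' template-mixture grid, globally (`"atr"`) or per hemisphere
#' (`"split_atr"`, composed into an asymmetric template); (3) nonlinear
#' morphological standardization against the selected template, with
#' weight re-selection after each nonlinear pass (outer loop); (4) a
#' single-interpolation composition of affine and deformation applied to
#' the original subject.
#'
#' @param subject the subject [volume()].
#' @param pair a [template_pair()].
#' @param mode `"atr"`, `"split_atr"` or `"fixed"` (normal template only).
#' @param mask optional evaluation mask; default [brain_mask()] of the
#'   normal template at `config$mask_frac`.
#' @param config an [atr_config()].
#' @return An object of class `atr_fit` with the normalized volume, the
#'   selected weights, both transforms and a provenance record (metric
#'   traces, weight history, configuration).  Methods: `print`, `summary`,
#'   `coef` (selected weights), `fitted` (the normalized volume), `plot`.
#' @examples
#' \donttest{
#' gs <- list(dim = c(40, 40, 40), spacing = 5.5)
#' tp <- phantom_template_pair(n_subjects = 4, seed = 100, spec_args = gs)
#' ph <- generate_phantom(phantom_spec(dim = gs$dim, spacing = gs$spacing,
#'                                     caudate_ratio = c(2, 2),
#'                                     putamen_ratio = c(1.6, 1.6),
#'                                     putamen_posterior_fraction = c(0.5, 0.5)),
#'                        seed = 1)
#' fit <- atr(ph$volume, tp$pair, mode = "atr")
#' coef(fit)
#' }
#' @export
atr <- function(subject, pair, mode = c("atr", "split_atr", "fixed"),
                mask = NULL, config = atr_config()) {
  mode <- match.arg(mode)
  stopifnot(is_volume(subject), inherits(pair, "template_pair"))
  if (is.null(mask)) mask <- brain_mask(pair$normal, config$mask_frac)

  stage <- "affine"
  prov <- list(mode = mode, config = config, weights_history = list())
  res <- try({
    aff <- affine_register(subject, pair$normal, mask = mask,
                           levels = config$affine_levels,
                           maxit = config$affine_maxit)
    aligned <- resample(subject, pair$normal, aff)
    prov$affine_zncc <- attr(aff, "zncc")

    weights <- NULL
    current <- aligned
    field <- NULL
    target <- pair$normal
    n_outer <- if (mode == "fixed") 1L else config$outer_iterations
    for (outer in seq_len(n_outer)) {
      if (mode != "fixed") {
        stage <- "weight selection"
        prev <- weights
        weights <- if (mode == "atr")
          select_weight(current, pair, mask, config$grid_step)
        else
          select_weight_split(current, pair, mask,
                              grid_step = config$grid_step)
        prov$weights_history <- c(prov$weights_history, list(weights))
        stage <- "template composition"
        target <- if (mode == "atr") weighted_template(pair, weights$w)
                  else compose_split_template(pair, weights$w_left,
                                              weights$w_right,
                                              config$blend_fwhm_mm)
        if (!is.null(prev)) {
          dw <- if (mode == "atr") abs(weights$w - prev$w)
                else max(abs(weights$w_left - prev$w_left),
                         abs(weights$w_right - prev$w_right))
          if (dw < config$w_tol) break
        }
      }
      stage <- "nonlinear registration"
      field <- nonlinear_register(aligned, target, mask = mask,
                                  levels = config$nl_levels,
                                  iterations = config$nl_iterations,
                                  field_fwhm_mm = config$field_fwhm_mm,
                                  update_fwhm_mm = config$update_fwhm_mm,
                                  step_mm = config$step_mm,
                                  max_disp_mm = config$max_disp_mm)
      current <- apply_normalization(subject, aff, field)
    }
    stage <- "resampling"
    normalized <- apply_normalization(subject, aff, field,
                                      target_grid = pair$normal)
    list(aff = aff, field = field, weights = weights, target = target,
         normalized = normalized)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("ATR pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)

  prov$nonlinear_trace <- if (!is.null(res$field)) res$field$trace
  prov$final_zncc <- zncc_value(res$normalized, res$target, mask)
  structure(list(normalized = res$normalized, weights = res$weights,
                 affine = res$aff, field = res$field, template = res$target,
                 pair = pair, mask = mask, mode = mode, provenance = prov),
            class = "atr_fit")
}

#' @export
print.atr_fit <- function(x, ...) {
  cat("Adaptive template registration fit\n")
  cat("  mode:", x$mode, "\n")
  if (!is.null(x$weights)) {
    if (x$weights$mode == "global")
      cat(sprintf("  selected weight: %.3f (normal fraction)\n", x$weights$w))
    else
      cat(sprintf("  selected weights: left %.3f, right %.3f\n",
                  x$weights$w_left, x$weights$w_right))
  }
  cat(sprintf("  final masked ZNCC vs template: %.4f\n",
              x$provenance$final_zncc))
  invisible(x)
}

#' @export
summary.atr_fit <- function(object, ...) {
  s <- list(mode = object$mode, weights = coef(object),
            affine_zncc = object$provenance$affine_zncc,
            final_zncc = object$provenance$final_zncc,
            outer_passes = length(object$provenance$weights_history),
            max_displacement_mm = if (!is.null(object$field))
              max(sqrt(object$field$displacement[, , , 1]^2 +
                       object$field$displacement[, , , 2]^2 +
                       object$field$displacement[, , , 3]^2)) else 0)
  class(s) <- "summary.atr_fit"
  s
}

#' @export
print.summary.atr_fit <- function(x, ...) {
  cat("ATR fit summary\n  mode:", x$mode, "\n")
  if (length(x$weights))
    cat("  weights:", paste(sprintf("%s = %.3f", names(x$weights), x$weights),
                            collapse = ", "), "\n")
  cat(sprintf("  ZNCC after affine: %.4f; after nonlinear: %.4f\n",
              x$affine_zncc, x$final_zncc))
  cat(sprintf("  outer weight-selection passes: %d\n", x$outer_passes))
  cat(sprintf("  max displacement: %.2f mm\n", x$max_displacement_mm))
  invisible(x)
}

#' @export
coef.atr_fit <- function(object, ...) {
  w <- object$weights
  if (is.null(w)) return(stats::setNames(numeric(0), character(0)))
  if (w$mode == "global") c(w = w$w)
  else c(w_left = w$w_left, w_right = w$w_right)
}

#' @export
fitted.atr_fit <- function(object, ...) object$normalized

#' @export
plot.atr_fit <- function(x, z = NULL, ...) {
  dm <- dim(x$normalized$data)
  if (is.null(z)) z <- ceiling(dm[3] / 2)
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  gr <- grDevices::gray.colors(128, 0, 1)
  graphics::image(x$normalized$data[, , z], col = gr, axes = FALSE,
                  main = "normalized subject", useRaster = TRUE)
  graphics::image(x$template$data[, , z], col = gr, axes = FALSE,
                  main = "selected template", useRaster = TRUE)
  invisible(x)
}
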