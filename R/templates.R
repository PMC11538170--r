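#' Build an occipital-normalized average template
#'
#' Each spatially standardized input is divided by its mean uptake in the
#' occipital reference VOI, then the normalized volumes are averaged
#' voxelwise.  The result has occipital mean exactly 1, the common
#' intensity scale that makes weighted template mixtures meaningful.
#'
#' @param normalized_subjects list of grid-compatible [volume()]s, already
#'   spatially standardized (at least one; typical templates average
#'   eight).
#' @param occipital_voi [binary_voi()] of the occipital reference region
#'   on the same grid.
#' @return A `spect_volume` template with occipital mean 1.
#' @export
build_template <- function(normalized_subjects, occipital_voi) {
  if (is_volume(normalized_subjects))
    normalized_subjects <- list(normalized_subjects)
  stopifnot(length(normalized_subjects) >= 1L,
            inherits(occipital_voi, "spect_voi"))
  ref <- normalized_subjects[[1]]
  acc <- array(0, dim(ref$data))
  for (i in seq_along(normalized_subjects)) {
    v <- normalized_subjects[[i]]
    stop_if_grid_mismatch(ref, v, "template inputs")
    m <- masked_mean(v, occipital_voi)
    if (m <= 0)
      stop("subject ", i, " has non-positive occipital mean (", signif(m, 4),
           "); cannot normalize")
    acc <- acc + v$data / m
  }
  volume(acc / length(normalized_subjects), spacing = ref$spacing,
         affine = ref$affine)
}

#' Normal/disease template pair
#'
#' Bundles the normal-type and egg-shape-type templates on a shared grid.
#' If `occipital_voi` is supplied, each template is (re)normalized so its
#' occipital mean is 1; otherwise both must already satisfy that
#' convention within `tol`.
#'
#' @param normal,egg [volume()]s on the same grid, strictly nonnegative.
#' @param occipital_voi optional occipital [binary_voi()] used to
#'   normalize; when omitted the templates are validated instead.
#' @param tol tolerance on the occipital-mean-1 check.
#' @return An object of class `template_pair`.
#' @export
template_pair <- function(normal, egg, occipital_voi = NULL, tol = 1e-6) {
  stopifnot(is_volume(normal), is_volume(egg))
  stop_if_grid_mismatch(normal, egg, "template pair")
  if (min(normal$data) < 0 || min(egg$data) < 0)
    stop("templates must be nonnegative")
  if (!is.null(occipital_voi)) {
    normal <- volume(normal$data / masked_mean(normal, occipital_voi),
                     spacing = normal$spacing, affine = normal$affine)
    egg <- volume(egg$data / masked_mean(egg, occipital_voi),
                  spacing = egg$spacing, affine = egg$affine)
    stopifnot(abs(masked_mean(normal, occipital_voi) - 1) <= tol,
              abs(masked_mean(egg, occipital_voi) - 1) <= tol)
  }
  structure(list(normal = normal, egg = egg), class = "template_pair")
}

#' @export
print.template_pair <- function(x, ...) {
  cat("<template_pair> normal + egg-shape templates,",
      paste(dim(x$normal$data), collapse = " x "), "grid\n")
  invisible(x)
}

#' Weighted mixture of the normal and egg-shape templates
#'
#' The subject-specific candidate template: voxelwise
#' `w * normal + (1 - w) * egg`.  `w` is the normal-template fraction and
#' must lie on the 0.1 percent grid's closed range [0.001, 0.999].
#' Because both parents are occipital-normalized, the mixture keeps
#' occipital mean 1 for every `w`.
#'
#' @param pair a [template_pair()].
#' @param w normal-template fraction in [0.001, 0.999].
#' @return A `spect_volume`.
#' @export
weighted_template <- function(pair, w) {
  stopifnot(inherits(pair, "template_pair"))
  if (!is.numeric(w) || length(w) != 1L || w < 0.001 || w > 0.999)
    stop("'w' must be a single value in [0.001, 0.999], got ", w)
  volume(w * pair$normal$data + (1 - w) * pair$egg$data,
         spacing = pair$normal$spacing, affine = pair$normal$affine)
}

#' Compose an asymmetric split template
#'
#' Left hemisphere voxels take the `w_left` mixture and right hemisphere
#' voxels the `w_right` mixture, blended across the mid-sagittal plane
#' (world x = 0) by a Gaussian-CDF feather of width `blend_fwhm_mm`
#' (default 4 mm; 0 gives a hard seam).  A hard seam would inject gradient
#' artifacts into the nonlinear registration, hence the feather.
#'
#' @param pair a [template_pair()].
#' @param w_left,w_right per-hemisphere normal fractions in [0.001,
#'   0.999].
#' @param blend_fwhm_mm feather width in mm across the midline.
#' @param hemisphere_mask optional [label_volume()] with labels 1 (left)
#'   and 2 (right) overriding the world-x split; must partition the grid.
#' @return A `spect_volume` asymmetric template.
#' @export
compose_split_template <- function(pair, w_left, w_right, blend_fwhm_mm = 4,
                                   hemisphere_mask = NULL) {
  stopifnot(inherits(pair, "template_pair"))
  tl <- weighted_template(pair, w_left)
  tr <- weighted_template(pair, w_right)
  if (is.null(hemisphere_mask)) {
    x <- world_x_array(pair$normal)
    fl <- if (blend_fwhm_mm > 0)
      stats::pnorm(-x / (blend_fwhm_mm / FWHM_TO_SIGMA))
    else (x < 0) + 0          # left = world x < 0 (RAS)
  } else {
    lab <- hemisphere_mask$labels
    if (!all(lab %in% c(1L, 2L)))
      stop("hemisphere mask must partition the grid into labels 1 and 2")
    fl <- (lab == 1L) + 0
    if (blend_fwhm_mm > 0) {
      fv <- gaussian_smooth(volume(fl, spacing = pair$normal$spacing,
                                   affine = pair$normal$affine),
                            blend_fwhm_mm)
      fl <- pmin(1, pmax(0, fv$data))
    }
  }
  volume(fl * tl$data + (1 - fl) * tr$data,
         spacing = pair$normal$spacing, affine = pair$normal$affine)
}

# Left/right hemisphere logical arrays at world x = 0 (RAS: left is x < 0).
hemisphere_arrays <- function(x) {
  wx <- world_x_array(x)
  list(left = wx < 0, right = wx >= 0)
}
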