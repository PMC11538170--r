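#' VOI recipes
#'
#' A recipe names a region, the atlas label ids composing it, and a
#' laterality restriction.  The striatum recipe is the union of the
#' caudate and putamen ids; the occipital reference merges its six
#' component regions bilaterally.
#'
#' @param name region name.
#' @param label_ids nonempty integer vector of atlas ids.
#' @param side `"both"`, `"left"` or `"right"` (split at world x = 0,
#'   applied before smoothing).
#' @return An object of class `voi_recipe`.
#' @export
voi_recipe <- function(name, label_ids, side = c("both", "left", "right")) {
  side <- match.arg(side)
  label_ids <- as.integer(label_ids)
  if (!length(label_ids)) stop("recipe '", name, "' has no label ids")
  structure(list(name = name, label_ids = label_ids, side = side),
            class = "voi_recipe")
}

#' Build a resolution-matched binary VOI from an atlas
#'
#' Implements the indicator / smooth / threshold rule: recipe voxels are
#' set to 100, a 3D Gaussian of `fwhm_mm` (default 8 mm) matches the VOI
#' edges to SPECT spatial resolution, and the mask keeps voxels whose
#' smoothed value is strictly greater than `threshold_pct` (default 50).
#' For a large region the half-maximum contour sits at the original
#' boundary; regions thinner than the resolution smooth below threshold
#' and raise an error naming the region.
#'
#' @param atlas a [label_volume()].
#' @param recipe a [voi_recipe()].
#' @param fwhm_mm Gaussian FWHM in mm.
#' @param threshold_pct binarization threshold (strict >) in percent of
#'   the indicator value.
#' @return A [binary_voi()] on the atlas grid.
#' @export
build_voi <- function(atlas, recipe, fwhm_mm = 8, threshold_pct = 50) {
  stopifnot(inherits(atlas, "spect_labels"), inherits(recipe, "voi_recipe"),
            fwhm_mm > 0, threshold_pct > 0, threshold_pct < 100)
  missing_ids <- setdiff(recipe$label_ids, atlas$label_map)
  if (length(missing_ids))
    stop("recipe '", recipe$name, "' references ids not in the atlas map: ",
         paste(missing_ids, collapse = ", "))
  ind <- array(0, dim(atlas$labels))
  ind[atlas$labels %in% recipe$label_ids] <- 100
  if (recipe$side != "both") {
    wx <- world_x_array(atlas)
    ind[if (recipe$side == "left") wx >= 0 else wx < 0] <- 0
  }
  sm <- gaussian_smooth(volume(ind, spacing = atlas$spacing,
                               affine = atlas$affine), fwhm_mm)
  mask <- sm$data > threshold_pct
  if (!any(mask))
    stop("VOI '", recipe$name, "' is empty after smoothing at ",
         fwhm_mm, " mm FWHM: region thinner than the SPECT resolution")
  binary_voi(mask, like = atlas)
}

#' Standard VOI set for striatal quantification
#'
#' Builds the seven masks used throughout quantification: left/right
#' caudate, left/right putamen, left/right striatum (union indicator of
#' caudate and putamen smoothed *before* thresholding, so feathered edges
#' are not double counted) and the merged bilateral occipital reference.
#' Atlas regions are matched by name, case-insensitively: `caudate`,
#' `putamen`, and the occipital components
#' (`occipital|lingual|cuneus|calcarine`), which covers both the bundled
#' phantom atlas and AAL-style label maps.
#'
#' @param atlas a [label_volume()] providing caudate, putamen and
#'   occipital labels.
#' @inheritParams build_voi
#' @return Named list of [binary_voi()]: `caudate_left`, `caudate_right`,
#'   `putamen_left`, `putamen_right`, `striatum_left`, `striatum_right`,
#'   `occipital`.
#' @export
standard_voi_set <- function(atlas, fwhm_mm = 8, threshold_pct = 50) {
  stopifnot(inherits(atlas, "spect_labels"))
  ids_matching <- function(pattern) {
    ids <- atlas$label_map[grepl(pattern, names(atlas$label_map),
                                 ignore.case = TRUE)]
    as.integer(ids)
  }
  caud <- ids_matching("caudate")
  put <- ids_matching("putamen")
  occ <- ids_matching("occipital|lingual|cuneus|calcarine")
  if (!length(caud)) stop("atlas lacks caudate labels")
  if (!length(put)) stop("atlas lacks putamen labels")
  if (!length(occ)) stop("atlas lacks occipital reference labels")
  out <- list()
  for (side in c("left", "right")) {
    out[[paste0("caudate_", side)]] <-
      build_voi(atlas, voi_recipe(paste0("caudate_", side), caud, side),
                fwhm_mm, threshold_pct)
    out[[paste0("putamen_", side)]] <-
      build_voi(atlas, voi_recipe(paste0("putamen_", side), put, side),
                fwhm_mm, threshold_pct)
    out[[paste0("striatum_", side)]] <-
      build_voi(atlas, voi_recipe(paste0("striatum_", side),
                                  c(caud, put), side),
                fwhm_mm, threshold_pct)
  }
  out$occipital <- build_voi(atlas, voi_recipe("occipital", occ, "both"),
                             fwhm_mm, threshold_pct)
  out
}
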