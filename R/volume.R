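#' 3D image volumes with grid geometry
#'
#' A `spect_volume` bundles a 3D scalar array with its voxel spacing (mm)
#' and a 4x4 affine mapping 0-based voxel indices to world coordinates in
#' RAS millimetres (+x right, +y anterior, +z superior).  It is the
#' universal currency of the pipeline: subject SPECT images, templates and
#' deformed phantoms are all `spect_volume` objects.
#'
#' When `affine` is omitted, a centred axis-aligned affine is used, placing
#' world (0, 0, 0) at the geometric centre of the grid so the mid-sagittal
#' plane is world x = 0.
#'
#' @param data numeric 3D array; all values must be finite.
#' @param spacing numeric length-3 vector of strictly positive voxel sizes
#'   in mm (recycled if length 1).
#' @param affine optional 4x4 voxel-index-to-world matrix; the upper-left
#'   3x3 block must be invertible.
#' @return An object of class `spect_volume` with fields `data`, `spacing`
#'   and `affine`.
#' @examples
#' v <- volume(array(0, c(8, 8, 8)), spacing = 1.72)
#' v$affine
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values (", sum(!is.finite(data)),
         " voxels); sanitize before construction")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel sizes in mm")
  if (is.null(affine)) affine <- centered_affine(dim(data), spacing)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("'affine' is not invertible")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "spect_volume")
}

#' @rdname volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "spect_volume")

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spect_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.spect_volume <- function(x) dim(x$data)

# Axis-aligned affine with world origin at the grid centre.
centered_affine <- function(dm, spacing) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spacing, 3L)
  a[1:3, 4] <- -spacing * (dm - 1) / 2
  a
}

#' Binary volumes of interest
#'
#' A `spect_voi` is a boolean mask sharing the grid geometry of a
#' [volume()].  VOIs produced by [build_voi()] live on the template grid.
#'
#' @param mask logical 3D array.
#' @param spacing,affine grid geometry as in [volume()]; alternatively pass
#'   `like` to copy the geometry of an existing volume.
#' @param like optional `spect_volume`/`spect_voi` supplying the geometry.
#' @return An object of class `spect_voi`.
#' @export
binary_voi <- function(mask, spacing = c(1, 1, 1), affine = NULL, like = NULL) {
  if (!is.null(like)) {
    spacing <- like$spacing
    affine <- like$affine
  }
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask contains NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- centered_affine(dim(mask), spacing)
  structure(list(mask = mask, spacing = spacing, affine = as.matrix(affine)),
            class = "spect_voi")
}

#' @export
print.spect_voi <- function(x, ...) {
  cat(sprintf("<spect_voi> %s voxels in mask (%.1f mL)\n",
              format(sum(x$mask), big.mark = ","),
              sum(x$mask) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Integer-labelled atlas volumes
#'
#' A `spect_labels` holds a non-negative integer label array (0 =
#' background) on a [volume()]-style grid together with a label map from
#' region names to label ids, mirroring AAL-style parcellations.
#'
#' @param labels integer 3D array of non-negative region ids.
#' @param label_map named integer vector, region name -> id.  Every
#'   distinct nonzero id in `labels` must appear in the map.
#' @param spacing,affine,like grid geometry as in [binary_voi()].
#' @return An object of class `spect_labels`.
#' @export
label_volume <- function(labels, label_map, spacing = c(1, 1, 1),
                         affine = NULL, like = NULL) {
  if (!is.null(like)) {
    spacing <- like$spacing
    affine <- like$affine
  }
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (max(abs(labels - round(labels))) > 1e-6)
    stop("label volume has non-integer voxel values")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("label ids must be non-negative")
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  label_map <- stats::setNames(as.integer(label_map), names(label_map))
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("'label_map' must be a named vector of region ids")
  orphans <- setdiff(ids, label_map)
  if (length(orphans))
    stop("atlas ids absent from label map: ", paste(orphans, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- centered_affine(dim(labels), spacing)
  structure(list(labels = labels, label_map = label_map,
                 spacing = spacing, affine = as.matrix(affine)),
            class = "spect_labels")
}

#' @export
print.spect_labels <- function(x, ...) {
  cat(sprintf("<spect_labels> %d named regions on a %s grid\n",
              length(x$label_map), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Test whether two gridded objects share a grid
#'
#' Two objects are grid-compatible iff their array dimensions agree exactly
#' and spacings and affines agree within `tol` (default 1e-6; strict
#' equality would reject files round-tripped through NIfTI headers).
#'
#' @param a,b `spect_volume`, `spect_voi` or `spect_labels` objects.
#' @param tol numeric tolerance on spacing and affine entries.
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  da <- dim(grid_array(a)); db <- dim(grid_array(b))
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

grid_array <- function(x) {
  if (inherits(x, "spect_voi")) x$mask
  else if (inherits(x, "spect_labels")) x$labels
  else x$data
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grid_compatible(a, b))
    stop(what, " are not grid-compatible (dim/spacing/affine differ)")
  invisible(TRUE)
}

# World coordinates (n x 3, mm) of every voxel centre, in array order.
voxel_world_coords <- function(x) {
  dm <- dim(grid_array(x))
  i <- rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3])
  j <- rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3])
  k <- rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  a <- x$affine
  cbind(a[1, 1] * i + a[1, 2] * j + a[1, 3] * k + a[1, 4],
        a[2, 1] * i + a[2, 2] * j + a[2, 3] * k + a[2, 4],
        a[3, 1] * i + a[3, 2] * j + a[3, 3] * k + a[3, 4])
}

# World x coordinate per voxel as a 3D array (for mid-sagittal splits).
world_x_array <- function(x) {
  dm <- dim(grid_array(x))
  array(voxel_world_coords(x)[, 1], dim = dm)
}
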