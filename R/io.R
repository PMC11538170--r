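#' Read and write volumes as NIfTI-1
#'
#' NIfTI-1 is the package's sole volume dialect.  The sform (or, failing
#' that, qform) affine is taken as the voxel-to-world map; spacing is
#' derived from the affine column norms so anisotropic grids survive the
#' round trip.  Readers reject 4D files and any non-finite voxel data, so
#' NaNs can never enter the pipeline from disk.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop(path, ": expected a single 3D frame, got ",
         if (length(d) >= 4L) paste(d[4], "frames") else paste0(length(d), "D data"))
  arr <- array(as.numeric(img), dim = d)
  if (!all(is.finite(arr)))
    stop(path, ": volume contains non-finite voxels; refusing to read")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(arr, spacing = sqrt(colSums(aff[1:3, 1:3]^2)), affine = aff)
}

#' @rdname read_volume
#' @param vol a [volume()] (or [binary_voi()]/[label_volume()], written as
#'   numeric/integer data).
#' @export
write_volume <- function(vol, path) {
  arr <- grid_array(vol)
  storage.mode(arr) <- if (inherits(vol, "spect_volume")) "double" else "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer atlas with its label map
#'
#' The label map is a two-column `name,id` CSV/TSV or a JSON object of
#' `name: id` pairs.  Every distinct nonzero id present in the voxel data
#' must be named in the map, otherwise the orphan ids are reported.
#'
#' @param path NIfTI path of the integer label image.
#' @param label_map_path path of the label map (`.json`, or delimited text
#'   with columns name and id).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_map_path) {
  vol <- read_volume(path)
  lm <- read_label_map(label_map_path)
  label_volume(vol$data, label_map = lm, spacing = vol$spacing,
               affine = vol$affine)
}

read_label_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    stats::setNames(as.integer(unlist(x)), names(x))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tb <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    names(tb) <- tolower(names(tb))
    if (!all(c("name", "id") %in% names(tb)))
      stop(path, ": label map needs 'name' and 'id' columns")
    stats::setNames(as.integer(tb$id), tb$name)
  }
}

#' @rdname read_label_volume
#' @param atlas a [label_volume()].
#' @param label_map_path destination for the JSON label map.
#' @export
write_label_volume <- function(atlas, path, label_map_path = NULL) {
  write_volume(atlas, path)
  if (!is.null(label_map_path))
    jsonlite::write_json(as.list(atlas$label_map), label_map_path,
                         auto_unbox = TRUE)
  invisible(path)
}

#' Serialize affine transforms and deformation fields
#'
#' Affines are stored as plain-text 4x4 matrices (one row per line);
#' deformation fields as 4D NIfTI with three volumes holding the x, y, z
#' displacement components in mm on the template grid.
#'
#' @param affine an affine matrix; `field` a deformation field from
#'   [nonlinear_register()].
#' @param path destination path.
#' @export
write_affine <- function(affine, path) {
  utils::write.table(unclass(as.matrix(affine)), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  as_affine(as.matrix(utils::read.table(path)))
}

#' @rdname write_affine
#' @param field an `atr_deformation`.
#' @export
write_deformation <- function(field, path) {
  img <- RNifti::asNifti(field$displacement)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_deformation <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop(path, ": deformation field must be 4D with 3 components")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  structure(list(displacement = array(as.numeric(img), dim = d),
                 spacing = sqrt(colSums(aff[1:3, 1:3]^2)),
                 affine = aff),
            class = "atr_deformation")
}

#' Write per-subject region ratios to CSV
#'
#' One row per subject, wide format with a fixed column order: for each
#' region (striatum, caudate, putamen) the left/right/high/low occipital
#' ratios, the asymmetry index (percent) and the left/right binding
#' ratios.  Values are written at 6 significant digits.
#'
#' @param results a named list of [quantify()] results (names are subject
#'   ids) or a single result.
#' @param path destination CSV path.
#' @return The written data frame, invisibly.
#' @export
write_ratios_table <- function(results, path) {
  if (inherits(results, "region_ratios")) results <- list(subject = results)
  if (is.null(names(results)))
    names(results) <- sprintf("subject%03d", seq_along(results))
  rows <- lapply(names(results), function(id) {
    rr <- results[[id]]
    out <- data.frame(subject = id, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rr))) {
      rg <- rr$region[i]
      for (fld in c("ratio_left", "ratio_right", "ratio_high", "ratio_low",
                    "ai", "binding_ratio_left", "binding_ratio_right"))
        out[[paste(rg, fld, sep = "_")]] <- signif(rr[[fld]][i], 6)
    }
    out
  })
  tb <- do.call(rbind, rows)
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(tb)
}

#' @rdname write_ratios_table
#' @export
read_ratios_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
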