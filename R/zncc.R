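#' Zero-mean normalized cross-correlation between two volumes
#'
#' The similarity metric driving template weight selection and both
#' registration stages: the Pearson correlation of the two images' voxel
#' values over an evaluation mask,
#' \deqn{\mathrm{ZNCC} = \frac{\sum (a-\bar a)(b-\bar b)}
#'   {\sqrt{\sum (a-\bar a)^2 \sum (b-\bar b)^2}},}
#' invariant to intensity gain and offset.  Correlating over the mostly
#' dark background would saturate the statistic, so callers normally pass
#' a brain mask (see [brain_mask()]).
#'
#' @param a,b grid-compatible [volume()]s.
#' @param mask optional [binary_voi()] restricting the evaluation; `NULL`
#'   uses every voxel.
#' @return An object of class `zncc_score`: list with `value` in [-1, 1]
#'   and `n_voxels`.  Use [zncc_value()] for the bare number.
#' @examples
#' v <- volume(array(rnorm(8^3), c(8, 8, 8)))
#' zncc(v, v)$value  # exactly 1
#' @export
zncc <- function(a, b, mask = NULL) {
  stopifnot(is_volume(a), is_volume(b))
  stop_if_grid_mismatch(a, b, "zncc inputs")
  if (is.null(mask)) {
    va <- as.numeric(a$data); vb <- as.numeric(b$data)
  } else {
    stop_if_grid_mismatch(a, mask, "volume and mask")
    va <- a$data[mask$mask]; vb <- b$data[mask$mask]
  }
  n <- length(va)
  if (n < 2L) stop("ZNCC needs at least 2 masked voxels, got ", n)
  va <- va - sum(va) / n
  vb <- vb - sum(vb) / n
  ssa <- sum(va * va); ssb <- sum(vb * vb)
  if (ssa <= 0 || ssb <= 0)
    stop("ZNCC undefined: zero variance under the evaluation mask")
  val <- sum(va * vb) / sqrt(ssa * ssb)
  structure(list(value = val, n_voxels = n), class = "zncc_score")
}

#' @rdname zncc
#' @export
zncc_value <- function(a, b, mask = NULL) zncc(a, b, mask)$value

#' @export
print.zncc_score <- function(x, ...) {
  cat(sprintf("ZNCC = %.6f over %d voxels\n", x$value, x$n_voxels))
  invisible(x)
}

#' Default evaluation mask: voxels above a fraction of the template max
#'
#' Excludes air/background, whose near-constant zeros would dominate a
#' whole-volume correlation.
#'
#' @param template a [volume()].
#' @param frac threshold as a fraction of the template maximum (default
#'   0.2).
#' @return A [binary_voi()] on the template grid.
#' @export
brain_mask <- function(template, frac = 0.2) {
  stopifnot(is_volume(template), frac > 0, frac < 1)
  binary_voi(template$data > frac * max(template$data), like = template)
}
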