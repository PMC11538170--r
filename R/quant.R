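#' Occipital-referenced uptake ratio
#'
#' Mean uptake under a target VOI divided by the mean under the reference
#' (occipital) VOI — the nonspecific-referenced accumulation ratio.
#'
#' @param vol a normalized [volume()] on the template grid.
#' @param region,reference [binary_voi()]s on the same grid.
#' @return The scalar ratio.
#' @export
uptake_ratio <- function(vol, region, reference) {
  ref <- masked_mean(vol, reference)
  if (ref <= 0)
    stop("reference (occipital) mean is non-positive (", signif(ref, 4), ")")
  masked_mean(vol, region) / ref
}

#' Left-right asymmetry index
#'
#' `|L - R| / (L + R) x 200`, in percent.  Scale-invariant, so it is the
#' same whether computed from raw means or occipital-referenced ratios.
#'
#' @param left,right positive uptake values (or ratios) for the left and
#'   right side.
#' @return The asymmetry index in percent, in [0, 200).
#' @examples
#' asymmetry_index(3, 1)  # 100
#' @export
asymmetry_index <- function(left, right) {
  stopifnot(is.numeric(left), is.numeric(right))
  if (any(left <= 0) || any(right <= 0))
    stop("asymmetry index needs strictly positive left/right values")
  abs(left - right) / (left + right) * 200
}

#' Quantify striatal uptake from a normalized volume
#'
#' For each of striatum, caudate and putamen: left and right
#' occipital-referenced ratios, the per-region high/low assignment
#' (`ratio_high = max(L, R)`; each region's own sides, not locked to one
#' hemisphere), the asymmetry index, and the binding ratios
#' (`ratio - 1`, the specific-binding scale used for Southampton-method
#' comparability).
#'
#' @param normalized a [volume()] on the template grid.
#' @param vois a [standard_voi_set()].
#' @return A data frame of class `region_ratios` with one row per region
#'   and columns `region`, `ratio_left`, `ratio_right`, `ratio_high`,
#'   `ratio_low`, `ai`, `binding_ratio_left`, `binding_ratio_right`.
#' @export
quantify <- function(normalized, vois) {
  stopifnot(is_volume(normalized), is.list(vois),
            "occipital" %in% names(vois))
  regions <- c("striatum", "caudate", "putamen")
  rows <- lapply(regions, function(rg) {
    L <- uptake_ratio(normalized, vois[[paste0(rg, "_left")]], vois$occipital)
    R <- uptake_ratio(normalized, vois[[paste0(rg, "_right")]], vois$occipital)
    if (L <= 0 || R <= 0)
      stop("non-positive uptake ratio in region '", rg, "'")
    data.frame(region = rg, ratio_left = L, ratio_right = R,
               ratio_high = max(L, R), ratio_low = min(L, R),
               ai = asymmetry_index(L, R),
               binding_ratio_left = L - 1, binding_ratio_right = R - 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("region_ratios", "data.frame")
  out
}

#' @export
print.region_ratios <- function(x, digits = 3, ...) {
  cat("Striatal uptake ratios (occipital reference)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
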