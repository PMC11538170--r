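#' Affine world-to-world transforms
#'
#' A 12-parameter affine built as translation . rotation . shear . scale,
#' the parameterization used by the linear registration stage.  The matrix
#' maps world coordinates (mm, RAS) of the *fixed* (template) space into
#' world coordinates of the *moving* (subject) space, which is the pull
#' direction [resample()] expects.
#'
#' @param translation length-3 translation in mm.
#' @param rotation length-3 rotations about x, y, z in radians.
#' @param scale length-3 scale factors (strictly positive).
#' @param shear length-3 shear coefficients (xy, xz, yz).
#' @return A 4x4 matrix of class `atr_affine`.
#' @examples
#' affine_transform(translation = c(6, -4, 2))
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             shear = c(0, 0, 0)) {
  stopifnot(length(translation) == 3L, length(rotation) == 3L,
            length(scale) == 3L, length(shear) == 3L, all(scale > 0))
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  sh <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  m3 <- rz %*% ry %*% rx %*% sh %*% diag(scale, 3L)
  m <- diag(4)
  m[1:3, 1:3] <- m3
  m[1:3, 4] <- translation
  structure(m, class = c("atr_affine", "matrix", "array"))
}

as_affine <- function(m) {
  m <- unclass(as.matrix(m))
  stopifnot(identical(dim(m), c(4L, 4L)))
  d <- det(m[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) stop("affine transform is singular")
  if (d < 0.2^3 || d > 5^3)
    stop(sprintf("affine determinant %.3g outside sanity bounds", d))
  structure(m, class = c("atr_affine", "matrix", "array"))
}

# 12-vector <-> matrix for the optimizer: t (mm), rot (rad), log-scale, shear.
params_to_affine <- function(p) {
  affine_transform(translation = p[1:3], rotation = p[4:6],
                   scale = exp(p[7:9]), shear = p[10:12])
}

#' Resample a volume onto a target grid through a spatial transform
#'
#' Pull-style resampling: for every voxel of the target grid its world
#' coordinate is pushed through `transform` (target world -> source world),
#' converted to a continuous source voxel index, and interpolated.
#' Positions outside the source support read as 0, matching the dark
#' background of SPECT.  Use `"linear"` interpolation for intensity
#' volumes and `"nearest"` for label or mask volumes.
#'
#' @param vol source [volume()].
#' @param target_grid a `spect_volume`/`spect_voi`/`spect_labels` (its
#'   geometry is used) or a list with `dim`, `spacing`, `affine`.
#' @param transform 4x4 affine (target world to source world), or a
#'   function taking an n x 3 matrix of world mm and returning the mapped
#'   n x 3 matrix (used for deformation fields).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param .world optional precomputed target world-coordinate matrix (an
#'   internal fast path for optimizers that resample onto one grid many
#'   times).
#' @return A `spect_volume` on the target grid.
#' @export
resample <- function(vol, target_grid = vol, transform = diag(4),
                     interpolation = c("linear", "nearest"),
                     .world = NULL) {
  stopifnot(is_volume(vol))
  interpolation <- match.arg(interpolation)
  tg <- as_grid(target_grid)
  if (any(tg$dim < 1L)) stop("degenerate target grid (zero-length axis)")
  w <- if (is.null(.world)) grid_world_coords(tg) else .world
  if (is.function(transform)) {
    sw <- transform(w)
  } else {
    m <- unclass(as.matrix(transform))
    if (abs(det(m[1:3, 1:3])) < 1e-12) stop("non-invertible transform affine")
    sw <- w %*% t(m[1:3, 1:3])
    sw[, 1] <- sw[, 1] + m[1, 4]
    sw[, 2] <- sw[, 2] + m[2, 4]
    sw[, 3] <- sw[, 3] + m[3, 4]
  }
  ijk <- world_to_index(vol$affine, sw)
  vals <- if (interpolation == "linear") interp_trilinear(vol$data, ijk)
          else interp_nearest(vol$data, ijk)
  volume(array(vals, dim = tg$dim), spacing = tg$spacing, affine = tg$affine)
}

as_grid <- function(g) {
  if (inherits(g, c("spect_volume", "spect_voi", "spect_labels")))
    list(dim = dim(grid_array(g)), spacing = g$spacing, affine = g$affine)
  else if (is.list(g) && all(c("dim", "spacing", "affine") %in% names(g)))
    list(dim = as.integer(g$dim), spacing = as.numeric(g$spacing),
         affine = as.matrix(g$affine))
  else stop("cannot interpret 'target_grid'")
}

grid_world_coords <- function(tg) {
  voxel_world_coords(list(affine = tg$affine,
                          data = array(0, tg$dim)) |> structure(class = "spect_volume"))
}

world_to_index <- function(affine, w) {
  inv <- solve(affine)
  ijk <- w %*% t(inv[1:3, 1:3])
  ijk[, 1] <- ijk[, 1] + inv[1, 4]
  ijk[, 2] <- ijk[, 2] + inv[2, 4]
  ijk[, 3] <- ijk[, 3] + inv[3, 4]
  ijk
}

# Vectorized trilinear interpolation at continuous 0-based indices;
# outside the array reads as 0.  The array is padded with one zero layer
# so every in-support cell can be gathered without per-corner bounds
# tests; cells fully outside are redirected to the zero border.
interp_trilinear <- function(arr, ijk) {
  dm <- dim(arr)
  dp <- dm + 2L
  pad <- array(0, dp)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- arr
  i0 <- floor(ijk[, 1]); j0 <- floor(ijk[, 2]); k0 <- floor(ijk[, 3])
  fi <- ijk[, 1] - i0; fj <- ijk[, 2] - j0; fk <- ijk[, 3] - k0
  # padded 0-based cell origin; anything outside [-1, dm] reads border zeros
  ip <- pmin.int(pmax.int(i0 + 1, 0), dp[1] - 2L)
  jp <- pmin.int(pmax.int(j0 + 1, 0), dp[2] - 2L)
  kp <- pmin.int(pmax.int(k0 + 1, 0), dp[3] - 2L)
  out_of_cell <- i0 < -1 | i0 > dm[1] - 1 | j0 < -1 | j0 > dm[2] - 1 |
                 k0 < -1 | k0 > dm[3] - 1
  base <- ip + dp[1] * (jp + dp[2] * kp) + 1
  sx <- 1L; sy <- dp[1]; sz <- dp[1] * dp[2]
  gi <- 1 - fi; gj <- 1 - fj; gk <- 1 - fk
  v <- pad[base]                * gi * gj * gk +
       pad[base + sx]           * fi * gj * gk +
       pad[base + sy]           * gi * fj * gk +
       pad[base + sx + sy]      * fi * fj * gk +
       pad[base + sz]           * gi * gj * fk +
       pad[base + sx + sz]      * fi * gj * fk +
       pad[base + sy + sz]      * gi * fj * fk +
       pad[base + sx + sy + sz] * fi * fj * fk
  if (any(out_of_cell)) v[out_of_cell] <- 0
  v
}

interp_nearest <- function(arr, ijk) {
  dm <- dim(arr)
  ii <- round(ijk[, 1]); jj <- round(ijk[, 2]); kk <- round(ijk[, 3])
  ok <- ii >= 0 & ii < dm[1] & jj >= 0 & jj < dm[2] & kk >= 0 & kk < dm[3]
  v <- numeric(nrow(ijk))
  v[ok] <- arr[ii[ok] + dm[1] * (jj[ok] + dm[2] * kk[ok]) + 1]
  v
}

# Downsample a volume by integer factor f per axis (with light pre-smoothing
# as an anti-alias step).  Voxel (i2) centres sit at original continuous
# index f*i2 + (f-1)/2, so the world extent is preserved.
coarsen <- function(vol, f) {
  if (f == 1L) return(vol)
  sm <- gaussian_smooth(vol, fwhm_mm = f * min(vol$spacing))
  dm2 <- pmax(1L, dim(vol$data) %/% f)
  shift <- diag(4)
  diag(shift)[1:3] <- f
  shift[1:3, 4] <- (f - 1) / 2
  aff2 <- vol$affine %*% shift
  resample(sm, list(dim = dm2, spacing = vol$spacing * f, affine = aff2))
}

coarsen_mask <- function(voi, f) {
  if (f == 1L) return(voi)
  v <- volume(voi$mask + 0, spacing = voi$spacing, affine = voi$affine)
  cv <- coarsen(v, f)
  binary_voi(cv$data > 0.5, like = cv)
}
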