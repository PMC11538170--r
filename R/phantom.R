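#' Specification of a synthetic DAT-SPECT phantom
#'
#' Parametric-analytic digital phantom: a brain-shaped ellipsoidal
#' background at nonspecific uptake 1 (which defines the occipital
#' reference level), bilateral occipital reference regions, spherical
#' caudate heads and elongated putamen ellipsoids with configurable
#' specific uptake per side, optional posterior truncation of the putamen
#' (emulating the egg-shape pattern where posterior putamen signal is
#' lost), a smooth random geometric deformation, Gaussian blur at the
#' scanner resolution, and optional noise.  Geometry is defined in world
#' mm on a centred grid, so structure sizes are independent of the voxel
#' grid chosen.
#'
#' The default grid is 128 x 128 x 128 at 1.72 mm, the in-plane matrix
#' and pixel size of the triple-head SPECT acquisition the pipeline
#' targets; the default blur is the collimator resolution, 8.5 mm FWHM.
#'
#' @param dim integer length-3 grid size.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param background_uptake nonspecific (cortex/occipital) uptake level.
#' @param scalp_uptake uptake of the scalp/cranial rim relative to
#'   `background_uptake`; whole-head standardization leans on scalp and
#'   cranial accumulation, so the rim anchors the affine stage the way it
#'   does in clinical images (set to 1 to disable).
#' @param caudate_ratio,putamen_ratio length-2 (left, right) specific
#'   uptake as true occipital ratios, >= 1.
#' @param putamen_posterior_fraction length-2 (left, right) fraction of
#'   the putamen length retained from its anterior end (1 = full).
#' @param deformation_amplitude_mm peak displacement of the smooth random
#'   deformation (0 disables it).
#' @param deformation_fwhm_mm smoothness scale of the random field.
#' @param noise `"none"`, `"gaussian"` (sd = `noise_sigma_pct` percent of
#'   the image max) or `"poisson"` (counts at `poisson_scale` per
#'   intensity unit).
#' @param noise_sigma_pct,poisson_scale noise parameters.
#' @param blur_fwhm_mm imaging blur FWHM in mm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(128L, 128L, 128L), spacing = 1.72,
                         background_uptake = 1, scalp_uptake = 1.5,
                         caudate_ratio = c(4, 4), putamen_ratio = c(4, 4),
                         putamen_posterior_fraction = c(1, 1),
                         deformation_amplitude_mm = 0,
                         deformation_fwhm_mm = 40,
                         noise = c("none", "gaussian", "poisson"),
                         noise_sigma_pct = 5, poisson_scale = 100,
                         blur_fwhm_mm = 8.5) {
  noise <- match.arg(noise)
  dim <- as.integer(rep_len(dim, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(dim >= 8L), all(spacing > 0), background_uptake > 0,
            all(caudate_ratio >= 1), all(putamen_ratio >= 1),
            all(putamen_posterior_fraction > 0),
            all(putamen_posterior_fraction <= 1),
            deformation_amplitude_mm >= 0, blur_fwhm_mm > 0)
  stopifnot(scalp_uptake > 0)
  structure(list(dim = dim, spacing = spacing,
                 background_uptake = background_uptake,
                 scalp_uptake = scalp_uptake,
                 caudate_ratio = rep_len(caudate_ratio, 2L),
                 putamen_ratio = rep_len(putamen_ratio, 2L),
                 putamen_posterior_fraction =
                   rep_len(putamen_posterior_fraction, 2L),
                 deformation_amplitude_mm = deformation_amplitude_mm,
                 deformation_fwhm_mm = deformation_fwhm_mm,
                 noise = noise, noise_sigma_pct = noise_sigma_pct,
                 poisson_scale = poisson_scale,
                 blur_fwhm_mm = blur_fwhm_mm),
            class = "phantom_spec")
}

# Fixed world-mm geometry (left = x < 0 in RAS).
PHANTOM_GEOM <- list(
  head = list(center = c(0, 0, 0), semi = c(72, 88, 66)),
  occipital = list(center_abs_x = 22, center_yz = c(-55, -2),
                   semi = c(20, 22, 24)),
  caudate = list(center_abs_x = 13, center_yz = c(16, 8), radius = 9),
  putamen = list(center_abs_x = 28, center_yz = c(-6, 2),
                 semi = c(9, 19, 10))
)

# Label ids of the phantom atlas
PHANTOM_LABELS <- c(Caudate_L = 1L, Caudate_R = 2L, Putamen_L = 3L,
                    Putamen_R = 4L, Occipital_L = 5L, Occipital_R = 6L)

#' Generate a synthetic DAT-SPECT phantom
#'
#' Deterministic given `spec` and `seed`.  The imaging chain is: uptake
#' map (labels are emitted at this stage, on the undeformed template-like
#' grid) -> geometric deformation -> Gaussian blur -> noise.  The truth
#' record carries both the *nominal* generating ratios and the
#' *effective* measurable ratios, obtained by quantifying the blurred,
#' undeformed, noiseless volume with the atlas VOIs on the generation
#' grid: blur moves counts across VOI boundaries (partial-volume effect),
#' so effective ratios are the ceiling any registration-based measurement
#' can reach, and they are the reference the pipeline is validated
#' against.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed controlling deformation and noise.
#' @param compute_effective compute effective (measurable) truth ratios;
#'   disable to save the VOI construction when only the volume is needed.
#' @return List of class `spect_phantom`: `volume` (deformed, blurred,
#'   noisy subject), `standardized` (blurred, undeformed, noiseless),
#'   `labels` (undeformed [label_volume()] atlas), `truth` (nominal and
#'   effective ratios, AI, deformation summary, flags), `spec`, `seed`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L,
                             compute_effective = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  g <- PHANTOM_GEOM
  proto <- volume(array(0, spec$dim), spacing = spec$spacing)
  w <- voxel_world_coords(proto)
  dm <- spec$dim

  inside_ellipsoid <- function(center, semi) {
    array(((w[, 1] - center[1]) / semi[1])^2 +
          ((w[, 2] - center[2]) / semi[2])^2 +
          ((w[, 3] - center[3]) / semi[3])^2 <= 1, dm)
  }
  head <- inside_ellipsoid(g$head$center, g$head$semi)
  inner <- inside_ellipsoid(g$head$center, 0.92 * g$head$semi)

  labels <- array(0L, dm)
  uptake <- array(0, dm)
  uptake[head] <- spec$background_uptake
  # scalp/cranial rim: the whole-head feature the affine stage anchors on
  uptake[head & !inner] <- spec$background_uptake * spec$scalp_uptake

  for (si in 1:2) {                     # 1 = left (x < 0), 2 = right
    sgn <- if (si == 1L) -1 else 1
    occ <- inside_ellipsoid(c(sgn * g$occipital$center_abs_x,
                              g$occipital$center_yz), g$occipital$semi) & head
    labels[occ] <- if (si == 1L) PHANTOM_LABELS[["Occipital_L"]]
                   else PHANTOM_LABELS[["Occipital_R"]]

    cc <- c(sgn * g$caudate$center_abs_x, g$caudate$center_yz)
    caud <- inside_ellipsoid(cc, rep(g$caudate$radius, 3L)) & head
    labels[caud] <- if (si == 1L) PHANTOM_LABELS[["Caudate_L"]]
                    else PHANTOM_LABELS[["Caudate_R"]]
    uptake[caud] <- spec$background_uptake * spec$caudate_ratio[si]

    pc <- c(sgn * g$putamen$center_abs_x, g$putamen$center_yz)
    put <- inside_ellipsoid(pc, g$putamen$semi) & head & !caud
    f <- spec$putamen_posterior_fraction[si]
    if (f < 1) {
      # retain the anterior (larger-y) fraction of the putamen's length
      ycut <- (pc[2] + g$putamen$semi[2]) - f * 2 * g$putamen$semi[2]
      put <- put & array(w[, 2] > ycut, dm)
    }
    labels[put] <- if (si == 1L) PHANTOM_LABELS[["Putamen_L"]]
                   else PHANTOM_LABELS[["Putamen_R"]]
    uptake[put] <- spec$background_uptake * spec$putamen_ratio[si]
  }

  resolvable <- all(spec$putamen_posterior_fraction * 2 * g$putamen$semi[2] >=
                      spec$blur_fwhm_mm) &&
                2 * g$caudate$radius >= spec$blur_fwhm_mm
  if (!resolvable)
    warning("a striatal structure is below the resolvable size for blur ",
            spec$blur_fwhm_mm, " mm FWHM")

  uptake_vol <- volume(uptake, spacing = spec$spacing, affine = proto$affine)
  atlas <- label_volume(labels, PHANTOM_LABELS, spacing = spec$spacing,
                        affine = proto$affine)

  # standardized (undeformed) image: blur only
  standardized <- gaussian_smooth(uptake_vol, spec$blur_fwhm_mm)

  # subject image: deform, blur, noise
  deformed <- uptake_vol
  def_max <- 0
  if (spec$deformation_amplitude_mm > 0) {
    u <- random_smooth_field(dm, spec$spacing, proto$affine,
                             spec$deformation_fwhm_mm,
                             spec$deformation_amplitude_mm)
    def_max <- max(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
    pull <- function(ww) {
      ww[, 1] <- ww[, 1] + as.numeric(u[, , , 1])
      ww[, 2] <- ww[, 2] + as.numeric(u[, , , 2])
      ww[, 3] <- ww[, 3] + as.numeric(u[, , , 3])
      ww
    }
    deformed <- resample(uptake_vol, uptake_vol, pull)
  }
  img <- gaussian_smooth(deformed, spec$blur_fwhm_mm)
  if (spec$noise == "gaussian") {
    img <- volume(pmax(img$data + stats::rnorm(length(img$data),
                                               sd = spec$noise_sigma_pct / 100 *
                                                 max(img$data)), 0),
                  spacing = img$spacing, affine = img$affine)
  } else if (spec$noise == "poisson") {
    counts <- stats::rpois(length(img$data),
                           pmax(img$data, 0) * spec$poisson_scale)
    img <- volume(array(counts / spec$poisson_scale, dm),
                  spacing = img$spacing, affine = img$affine)
  }

  truth <- phantom_truth(spec, atlas, standardized, compute_effective)
  truth$resolvable <- resolvable
  truth$deformation_max_mm <- def_max

  structure(list(volume = img, standardized = standardized, labels = atlas,
                 truth = truth, spec = spec, seed = seed),
            class = "spect_phantom")
}

#' @export
print.spect_phantom <- function(x, ...) {
  cat(sprintf("<spect_phantom> seed %d, %s grid\n", x$seed,
              paste(x$spec$dim, collapse = " x ")))
  cat(sprintf("  nominal striatal ratios L/R: %.2f / %.2f\n",
              x$truth$nominal$ratio_left[x$truth$nominal$region == "striatum"],
              x$truth$nominal$ratio_right[x$truth$nominal$region == "striatum"]))
  invisible(x)
}

# Nominal ratios from the generating parameters (striatum = voxel-count
# weighted mix of its caudate and putamen compartments) plus, optionally,
# effective measurable ratios from the blurred undeformed volume.
phantom_truth <- function(spec, atlas, standardized, compute_effective) {
  lab <- atlas$labels
  nom <- lapply(1:2, function(si) {
    cid <- if (si == 1L) 1L else 2L
    pid <- if (si == 1L) 3L else 4L
    nc <- sum(lab == cid); np <- sum(lab == pid)
    striatum <- (nc * spec$caudate_ratio[si] + np * spec$putamen_ratio[si]) /
      max(nc + np, 1L)
    c(striatum = striatum, caudate = spec$caudate_ratio[si],
      putamen = spec$putamen_ratio[si])
  })
  nominal <- data.frame(
    region = c("striatum", "caudate", "putamen"),
    ratio_left = nom[[1]], ratio_right = nom[[2]],
    stringsAsFactors = FALSE)
  nominal$ratio_high <- pmax(nominal$ratio_left, nominal$ratio_right)
  nominal$ratio_low <- pmin(nominal$ratio_left, nominal$ratio_right)
  nominal$ai <- asymmetry_index(nominal$ratio_left, nominal$ratio_right)
  out <- list(nominal = nominal)
  if (compute_effective) {
    vois <- standard_voi_set(atlas)
    out$effective <- quantify(standardized, vois)
  }
  out
}

# Smooth random 3-vector displacement field (mm), peak magnitude = amplitude.
random_smooth_field <- function(dm, spacing, affine, fwhm_mm, amplitude_mm) {
  u <- array(stats::rnorm(prod(dm) * 3L), c(dm, 3L))
  sig <- fwhm_mm / FWHM_TO_SIGMA / spacing
  for (c3 in 1:3) {
    comp <- u[, , , c3]
    for (ax in 1:3) comp <- convolve_axis(comp, ax, sig[ax])
    u[, , , c3] <- comp
  }
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  u * (amplitude_mm / max(mag))
}

# Documented per-type parameter ranges for cohort generation; these are
# the generator's own conventions for the five visual uptake patterns.
PHANTOM_TYPE_RANGES <- list(
  normal = list(caudate = c(3.5, 5.0), putamen = c(3.2, 4.8),
                fraction = c(1, 1), asym = c(0.95, 1.05)),
  eagle_wing = list(caudate = c(2.8, 4.0), putamen = c(1.6, 2.6),
                    fraction = c(0.65, 0.85), asym = c(0.80, 1.0)),
  egg_shape = list(caudate = c(1.4, 2.2), putamen = c(1.2, 1.8),
                   fraction = c(0.3, 0.6), asym = c(0.80, 1.0)),
  mixed = list(caudate = c(2.6, 4.0), putamen = c(2.2, 3.6),
               fraction = c(0.9, 1.0), asym = c(0.45, 0.65)),
  burst = list(caudate = c(1.05, 1.35), putamen = c(1.05, 1.25),
               fraction = c(0.2, 0.4), asym = c(0.85, 1.0))
)

#' Generate a seeded phantom cohort
#'
#' Draws per-subject phantom parameters from documented per-type ranges
#' and generates each phantom with a derived seed, so a cohort is fully
#' reproducible from (`n`, `type_mix`, `seed`).  The default type mix is
#' the clinical prevalence of the five visual uptake patterns
#' (normal 136, eagle-wing 42, egg-shape 86, mixed 23, burst 13 per 300).
#'
#' @param n number of subjects.
#' @param type_mix named proportions over
#'   `c("normal", "eagle_wing", "egg_shape", "mixed", "burst")`; must sum
#'   to 1.
#' @param seed integer master seed.
#' @param spec_args list of arguments forwarded to [phantom_spec()]
#'   (grid, deformation, noise, ...).
#' @return List with `phantoms` (list of `spect_phantom`) and `truth`
#'   (data frame of per-subject nominal and effective values).
#' @export
generate_cohort <- function(n,
                            type_mix = c(normal = 136, eagle_wing = 42,
                                         egg_shape = 86, mixed = 23,
                                         burst = 13) / 300,
                            seed = 1L, spec_args = list()) {
  stopifnot(n >= 0)
  if (abs(sum(type_mix) - 1) > 1e-8) stop("type_mix must sum to 1")
  if (n == 0L) return(list(phantoms = list(), truth = data.frame()))
  set.seed(seed)
  types <- sample(names(type_mix), n, replace = TRUE, prob = type_mix)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rg <- PHANTOM_TYPE_RANGES[[types[i]]]
    asym <- stats::runif(1, rg$asym[1], rg$asym[2])
    flip <- sample(c(1L, 2L), 1L)       # which side is the worse one
    caud <- rep(stats::runif(1, rg$caudate[1], rg$caudate[2]), 2L)
    put <- rep(stats::runif(1, rg$putamen[1], rg$putamen[2]), 2L)
    frac <- rep(stats::runif(1, rg$fraction[1], rg$fraction[2]), 2L)
    caud[flip] <- 1 + (caud[flip] - 1) * asym
    put[flip] <- 1 + (put[flip] - 1) * asym
    if (types[i] == "mixed") frac[flip] <- stats::runif(1, 0.4, 0.6)
    args <- c(list(caudate_ratio = caud, putamen_ratio = put,
                   putamen_posterior_fraction = frac), spec_args)
    ph <- generate_phantom(do.call(phantom_spec, args), seed = seeds[i])
    phantoms[[i]] <- ph
    eff <- ph$truth$effective[ph$truth$effective$region == "striatum", ]
    nomst <- ph$truth$nominal[ph$truth$nominal$region == "striatum", ]
    rows[[i]] <- data.frame(
      subject = sprintf("phantom%03d", i), type = types[i], seed = seeds[i],
      striatum_nominal_left = nomst$ratio_left,
      striatum_nominal_right = nomst$ratio_right,
      striatum_effective_high = eff$ratio_high,
      striatum_effective_low = eff$ratio_low,
      striatum_effective_ai = eff$ai,
      stringsAsFactors = FALSE)
  }
  list(phantoms = phantoms, truth = do.call(rbind, rows))
}

#' Template pair from synthetic normal and egg-shape cohorts
#'
#' Builds the normal and disease templates the way the clinical templates
#' are built: a set of standardized (undeformed, noiseless) phantoms per
#' type, each occipital-normalized, then averaged.
#'
#' @param n_subjects phantoms per template (default 8, the clinical
#'   template size).
#' @param seed master seed.
#' @param spec_args grid and imaging arguments forwarded to
#'   [phantom_spec()].
#' @return List with `pair` (a [template_pair()]), `atlas` (the phantom
#'   [label_volume()]) and `vois` (the [standard_voi_set()] on that
#'   atlas).
#' @export
phantom_template_pair <- function(n_subjects = 8L, seed = 100L,
                                  spec_args = list()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_subjects)
  make_set <- function(type, sds) {
    rg <- PHANTOM_TYPE_RANGES[[type]]
    lapply(seq_along(sds), function(i) {
      caud <- rep(stats::runif(1, rg$caudate[1], rg$caudate[2]), 2L)
      put <- rep(stats::runif(1, rg$putamen[1], rg$putamen[2]), 2L)
      frac <- rep(stats::runif(1, rg$fraction[1], rg$fraction[2]), 2L)
      args <- c(list(caudate_ratio = caud, putamen_ratio = put,
                     putamen_posterior_fraction = frac), spec_args)
      generate_phantom(do.call(phantom_spec, args), seed = sds[i],
                       compute_effective = FALSE)
    })
  }
  normals <- make_set("normal", seeds[seq_len(n_subjects)])
  eggs <- make_set("egg_shape", seeds[n_subjects + seq_len(n_subjects)])
  atlas <- normals[[1]]$labels
  vois <- standard_voi_set(atlas)
  normal_t <- build_template(lapply(normals, `[[`, "standardized"),
                             vois$occipital)
  egg_t <- build_template(lapply(eggs, `[[`, "standardized"),
                          vois$occipital)
  list(pair = template_pair(normal_t, egg_t), atlas = atlas, vois = vois)
}
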