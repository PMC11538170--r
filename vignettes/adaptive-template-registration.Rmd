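---
title: "Adaptive template registration for striatal DAT-SPECT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive template registration for striatal DAT-SPECT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantifying dopamine-transporter SPECT (¹²³I-ioflupane) requires placing
volumes of interest (VOIs) on the striatum, caudate and putamen, which in
turn requires warping every subject's image into a common template space
("morphological standardization").  Registration is usually driven by the
whole-brain uptake pattern — but in DAT-SPECT almost all signal sits in
the striatum, and in parkinsonian subjects that signal collapses.  A
single normal-uptake template then systematically mismatches diseased
subjects; the gold standard is to drive the warp with each subject's
structural MRI, which is frequently unavailable.

`striatr` implements an MRI-free alternative, adaptive template
registration (ATR): instead of one fixed template, the registration
target is a subject-specific mixture of a normal-type template and a
disease ("egg-shape") template, with the mixing weight chosen to maximize
similarity to the subject.

## The model

Both parent templates are averages of eight spatially standardized
subjects, each intensity-normalized so its mean uptake in the occipital
reference region is 1.  A candidate template for mixing weight $w$ is the
voxelwise convex combination

$$T(w) = w\,T_{\text{normal}} + (1-w)\,T_{\text{egg}},
  \qquad w \in \{0.001, 0.002, \dots, 0.999\},$$

scanned exhaustively at 0.1 % steps.  Similarity is the zero-mean
normalized cross-correlation (ZNCC) over a brain mask $M$:

$$\mathrm{ZNCC}(A,B) = \frac{\sum_{x\in M}(A_x-\bar A)(B_x-\bar B)}
  {\sqrt{\sum_{x\in M}(A_x-\bar A)^2\sum_{x\in M}(B_x-\bar B)^2}},$$

which is invariant to intensity gain and offset, so count scaling never
influences the choice.  Because $T(w)$ is linear in $w$, every grid
point's ZNCC follows exactly from six masked sufficient statistics
(`select_weight` evaluates the same quantity a literal scan over all 999
composed templates would; the test suite asserts this equality).  Ties
are broken toward larger $w$ — the more-normal template — a conservative
choice for borderline subjects.

**Split-ATR** performs the scan independently for the left and right
hemispheres (split at world $x = 0$) and composes an asymmetric template
from the two weights, addressing the strongly lateralized loss typical of
early Parkinson's disease.

The full pipeline per subject (`atr()`):

1. 12-parameter affine pre-alignment to the normal template
   (multiresolution Nelder–Mead ascent on masked ZNCC);
2. weight selection (global or per hemisphere) on the aligned image;
3. nonlinear ("morphological") standardization against the selected
   mixture — a demons-style small-deformation scheme with Gaussian field
   regularization and an accept-only-if-ZNCC-improves update rule;
4. re-selection of the weight on the warped image and a second nonlinear
   pass (outer loop, default 2 passes, stopping early when the weight
   moves by less than 0.005);
5. a single-interpolation resampling of the original subject through the
   composed affine + deformation.

## Quantification

VOIs are built from an integer atlas by the indicator–smooth–threshold
rule: recipe voxels are set to 100, smoothed with an 8 mm FWHM Gaussian
to match SPECT resolution, and binarized at strictly greater than 50.
Composite regions (striatum = caudate ∪ putamen; occipital = its six
component regions) are combined *before* smoothing so feathered edges are
not double-counted.  Laterality is imposed at world $x=0$ before
smoothing.

From the normalized volume, each region's uptake ratio is its VOI mean
divided by the occipital VOI mean.  Per region the higher and lower side
are reported separately (`ratio_high`, `ratio_low`), with the asymmetry
index

$$\mathrm{AI} = \frac{|L - R|}{L + R} \times 200\ \%$$

and the binding ratio (ratio − 1), the specific-binding scale that makes
values comparable with Southampton-method SBR outputs.

Method agreement is assessed the way the clinical comparison is framed:
ordinary least squares (slope, intercept, Pearson r with the t-transform
p-value) for linearity, and the one-way random-effects intraclass
correlation ICC(1,1), Shrout–Fleiss form with $k=2$ raters, exact
two-sided F confidence bounds, for absolute agreement.  ICC(1,1)
penalizes systematic offsets that leave $r$ untouched; the suite asserts
`icc(x, x + c) < 1` while `r = 1`.

## The phantom generator

All validation runs on `generate_phantom()`, a parametric-analytic
digital phantom chosen over a digitized human atlas to keep the package
download-free and the ground truth exact.  It emulates, in world
millimetres on a centred grid:

* an ellipsoidal head (semi-axes 72 × 88 × 66 mm) at nonspecific uptake 1,
  with a scalp/cranial rim at 1.5× background — whole-head
  standardization leans on scalp and cranial accumulation, and without
  this rim an affine stage has nothing but the striatum to anchor scale
  on and will distort disease cases toward the normal template;
* bilateral occipital reference regions (uptake = background);
* spherical caudate heads (radius 9 mm) and elongated putamina
  (9 × 19 × 10 mm semi-axes) with per-side specific ratios;
* the egg-shape pattern via `putamen_posterior_fraction`: the posterior
  fraction of the putamen's length is removed;
* a smooth random deformation field (per-subject anatomy), Gaussian blur
  at the collimator resolution (8.5 mm FWHM), and Gaussian or Poisson
  noise.

The default grid is 128 × 128 × 128 at 1.72 mm, the acquisition matrix
and pixel size of the targeted scanner protocol.  Tests and the
acceptance script use 64³ at 3.44 mm and 40³ at 5.5 mm — the same 220 mm
field of view, so the mm-defined anatomy is identical and runs fit a
desk-scale budget; these sizes are stated here as the package's chosen
validation scale.

Cohort generation draws per-subject parameters from documented ranges
for the five visual uptake patterns (normal, eagle-wing, egg-shape,
mixed, burst striatum), mixed by default at their clinical prevalence
(136 : 42 : 86 : 23 : 13 per 300).  The ranges are the generator's own
conventions, not published values.

### Nominal versus effective truth

Resolution blur moves counts across VOI boundaries (the partial-volume
effect), so even a perfectly registered image cannot measure the
generating ("nominal") contrast: an 18 mm sphere blurred at 8.5 mm FWHM
keeps only ~75–80 % of its contrast under its own VOI.  The phantom
truth record therefore carries both values: the nominal generating
ratios, and the *effective* ratios obtained by quantifying the blurred,
undeformed, noiseless volume with exact-grid VOIs.  The effective values
are the ceiling any registration-based measurement can reach and are the
reference the pipeline is validated against; this isolates registration
and quantification error from partial-volume error, which the package
deliberately does not correct (matching standard clinical practice for
this tracer).  The comparison is not circular: estimates come from the
deformed, noisy subject after the full affine + nonlinear pipeline,
while the effective truth never sees deformation, noise or registration.

What passing phantom tests does *not* show: the generator has no
projection-domain physics (no sinogram, filtered back projection,
attenuation or scatter), no anatomical variability beyond smooth
deformations, and uniform cortical background.  Real-data performance —
e.g. subjects with extreme ventricular enlargement — is outside what
these tests can establish.

## Numerical choices

* **Grids and geometry.** World coordinates are RAS millimetres; voxel
  indices 0-based; the affine voxel→world convention is the NIfTI sform.
  Grid compatibility uses a 1e-6 tolerance on spacing/affine entries so
  header round-trips do not spuriously fail.
* **Resampling** fills 0 outside the source support (SPECT background is
  dark); intensity images use trilinear, labels nearest-neighbour.
* **FWHM→σ** uses 2.3548 (= 2√(2 ln 2)); smoothing is separable with
  per-axis σ in voxels, and boundary-truncated kernels are renormalized
  so constants are exactly invariant.
* **Evaluation mask**: template voxels above 20 % of the template
  maximum.  Whole-volume correlation would be dominated by the air
  background and flatten the weight objective; the mask choice is
  configurable.
* **Midline blend**: split templates feather across world $x=0$ with a
  4 mm FWHM Gaussian CDF profile (0 = hard seam available).  A hard seam
  injects a gradient discontinuity that the demons update would chase.
* **Affine optimizer**: Nelder–Mead over 12 parameters (translation,
  rotation, log-scale, shear), three resolution levels (×4, ×2, ×1) with
  both images smoothed to each level's scale; two chained restarts at
  coarse levels; centre-of-mass initialization; the best level outcome by
  full-resolution masked ZNCC is kept, and the final metric can never be
  worse than the pre-registration value.
* **Nonlinear stage**: demons-style updates capped at 2 mm per
  iteration and 10 mm total, update and field smoothing at 5 and 12 mm
  FWHM, two levels (×2, ×1) with 10 and 6 iterations.  Every candidate
  update is accepted only if masked ZNCC improves, so the metric trace is
  non-decreasing within each level by construction; the final field is
  rejected if its Jacobian determinant is non-positive anywhere in the
  interior (folding).
* **Tie-breaks**: weight-scan ties (within 1e-12) resolve toward larger
  $w$; a metrically flat affine step keeps the current parameters.
* **Degenerate inputs**: constant images, empty masks, zero-variance
  regions, non-finite voxels and 4D files are rejected with specific
  errors rather than propagated.

## Limitations

* The affine stage can absorb genuine disease signal (scaling a shrunken
  striatal pattern toward the normal template); the scalp rim limits
  this on phantoms, and on real data whole-head features play that role,
  but subjects with atypical head anatomy remain a risk.
* The outer re-selection loop assumes the warp toward the selected
  template does not manufacture structure; heavy over-regularized warps
  can bias the re-selected weight, which is why the default schedule is
  conservative.
* Only two parent templates are mixed; burst-striatum patterns, whose
  striatal margins are not identifiable, have no dedicated template.
* Ratios are not partial-volume corrected, and the phantom's effective
  truth makes that explicit rather than hiding it.
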