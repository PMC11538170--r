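# striatr

MRI-free spatial normalization and quantification of striatal
dopamine-transporter (DAT) SPECT by **adaptive template registration
(ATR)**.

## The problem

¹²³I-ioflupane SPECT shows intense uptake in the striatum and little
elsewhere.  Quantifying it — striatal uptake ratios against an occipital
reference, per-side high/low values, asymmetry indices — requires warping
each subject into a common template space so fixed atlas VOIs apply.
But registration driven by the uptake pattern fails exactly where it
matters: in parkinsonian subjects the striatal signal that anchors the
warp has collapsed.  The usual remedy is to drive the warp with the
subject's structural MRI, which is often unavailable.

ATR replaces the single fixed registration target with a
**subject-specific mixture** of two templates — a normal-uptake average
and a disease ("egg-shape") average, both occipital-normalized:

    T(w) = w * T_normal + (1 - w) * T_egg,   w ∈ {0.001, …, 0.999}

The weight is chosen by an exhaustive scan at 0.1 % steps, maximizing
the zero-mean normalized cross-correlation (ZNCC) between the candidate
template and the linearly pre-aligned subject:

    ZNCC(A, B) = Σ (A−Ā)(B−B̄) / sqrt( Σ(A−Ā)² · Σ(B−B̄)² )

over a brain mask.  **Split-ATR** optimizes the left and right
hemispheres independently and composes an asymmetric template, for the
strongly lateralized loss typical of early Parkinson's disease.  The
selected template then drives nonlinear morphological standardization,
and atlas VOIs (indicator → 8 mm FWHM Gaussian → > 50 % threshold) yield
per-region quantities:

    uptake ratio   = mean(region VOI) / mean(occipital VOI)
    asymmetry AI   = |L − R| / (L + R) × 200 %
    binding ratio  = uptake ratio − 1        (Southampton-comparable SBR scale)

Method agreement is reported the way clinical comparisons are framed:
OLS slope/intercept/Pearson r, and the one-way random-effects intraclass
correlation ICC(1,1) with exact F confidence bounds.

Everything is validated end-to-end on a seeded parametric digital
phantom (brain-shaped background, scalp rim, caudate/putamen structures
with configurable uptake and egg-shape truncation, smooth random
deformation, 8.5 mm resolution blur, noise) — no data download needed.

## Worked example

Generate an asymmetric parkinsonian phantom (left side near-normal,
right side egg-like), fit split-ATR, and quantify:

```r
library(striatr)

tpl <- phantom_template_pair(n_subjects = 4, seed = 100,
         spec_args = list(dim = c(40, 40, 40), spacing = 5.5))
ph <- generate_phantom(phantom_spec(dim = c(40, 40, 40), spacing = 5.5,
         caudate_ratio = c(4, 2), putamen_ratio = c(3.5, 1.6),
         putamen_posterior_fraction = c(1, 0.5),
         deformation_amplitude_mm = 3,
         noise = "gaussian", noise_sigma_pct = 3), seed = 11)

fit <- atr(ph$volume, tpl$pair, mode = "split_atr")
print(fit)
#> Adaptive template registration fit
#>   mode: split_atr
#>   selected weights: left 0.931, right 0.029
#>   final masked ZNCC vs template: 0.8581

quantify(fitted(fit), tpl$vois)
#> Striatal uptake ratios (occipital reference)
#>    region ratio_left ratio_right ratio_high ratio_low     ai ...
#>  striatum      2.551       1.251      2.551     1.251 68.371
#>   caudate      2.567       1.489      2.567     1.489 53.154
#>   putamen      2.545       1.156      2.545     1.156 75.041
```

The fitted weights read directly as the method intends: the healthy left
hemisphere selects a 93 % normal template, the diseased right a 3 %
(i.e. almost purely egg-shape) template.  The measured striatal ratios
(2.55 high / 1.25 low) track the phantom's measurable ground truth
(2.66 / 1.46) — the "effective" truth the generator computes from its
own blurred, unregistered volume, which is the ceiling any
registration-based measurement can reach at SPECT resolution (see the
methods vignette on nominal vs effective truth).

`coef(fit)` returns the selected weights, `summary(fit)` the metric
trail, `plot(fit)` a slice view of the normalized subject against its
template.  A thin command-line front end lives in `inst/cli/striatr`
(`phantom`, `build-template`, `run`, `quantify`, `evaluate`
subcommands) for file-based workflows.

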