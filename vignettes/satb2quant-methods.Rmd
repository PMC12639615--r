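---
title: "Quantification methods for cell-based SATB2 variant assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for cell-based SATB2 variant assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satb2quant)
```

## Background and scope

SATB2 is a matrix-attachment-region (MAR) binding transcription factor with
two CUT domains and a homeobox (HOX) domain; heterozygous variants cause
SATB2-associated syndrome. Missense variants in the DNA-binding domains can
perturb the protein in qualitatively different ways — failing to bind and
repress its AT-rich targets (partial loss of function), binding them more
avidly (increased function), or collapsing into nuclear condensates — and
telling these apart requires combining several cell-based readouts.

`satb2quant` implements the quantification layer of that workflow:

1. **Nuclear localization metrics** from two-channel micrographs
   (protein channel + DNA stain), via automatic 8-bit histogram thresholds
   and thresholded-area ratios.
2. **FRAP** (fluorescence recovery after photobleaching) normalization and
   single-exponential fitting of the recovery half-time, a proxy for
   chromatin-binding residence.
3. **Dual-luciferase reporter** normalization into relative transcriptional
   activity against an empty-vector control.
4. **Inference**: one-way ANOVA with Dunnett's many-to-one post hoc test
   against the wild-type protein, for every assay.
5. **Classification** of per-variant call profiles into functional
   subgroups.
6. **Synthetic-data generators** for all three assay types, with exact
   ground truth, so each stage is testable without any microscope or plate
   reader.

## Image quantification

### The four automatic thresholds

All four algorithms operate on the 256-bin histogram of a min–max 8-bit
quantization (`quantize_to_8bit()`), with foreground defined as *strictly
greater* than the returned level — the convention of the ImageJ ecosystem in
which these methods are canonical. Ties resolve to the lowest level, with a
small relative tolerance so that algebraically equivalent variance
formulations cannot flip a tie across an empty-gap plateau.

* **Otsu** maximizes the between-class variance over all 255 cut points.
* **Li** (minimum cross-entropy) iterates
  `t <- (mu_b - mu_f) / (log mu_b - log mu_f)` from the image mean until
  successive iterates differ by less than 0.5 gray level, then polishes to
  the real-valued fixed point. Because the update is a *step function* of
  `t`, only the real-valued iterate is an exact fixed point; the integer
  level is its rounding, and the real fixed point is kept as the `t_star`
  attribute. Empty classes are guarded with a small epsilon.
* **Moments** (Tsai) matches the first three gray-level moments with a
  two-level image and takes the histogram `p0`-tile, `p0` the
  moment-preserved background fraction.
* **Minimum** smooths the histogram with a 3-point running mean until
  exactly two local maxima remain (cap 10,000 iterations) and returns the
  valley between them. Edge bins may be genuine modes (clipped signal piles
  up at 0), so the peak detector pads with `-Inf` rather than replicating
  edges; histograms that never become bimodal raise an error.

Degenerate inputs (constant images, single-bin histograms) return the
occupied/modal bin flagged `degenerate`, which downstream produces an empty
mask; ratio code then reports a missing value and the exclusion is counted —
never a silent `0/0`.

### The three ratio statistics

The channel–method pairings are fixed per metric, because the pairings *are*
the statistics:

| metric | protein channel | DNA channel | reads as |
|---|---|---|---|
| `aggregation_ratio` | Moments | Minimum | protein area / DNA area; smaller = more clustered |
| `coloc_ratio` | Moments | Moments | fraction of protein foreground inside DNA foreground |
| `nuclear_fraction` | Li | Otsu | fraction of protein signal inside nuclei |

`aggregation_ratio` and `coloc_ratio` are meant for the high-zoom
single-nucleus regime where chromatin texture is resolved; `nuclear_fraction`
for the lower-magnification field-of-view regime where the DNA stain reads
as one smooth blob per nucleus. The synthetic generator exposes both regimes
(`style = "airyscan"` vs `style = "field"`), and the ground-truth recovery
tests respect that scoping: on textured single-nucleus images Otsu cuts at
the chromatin contrast rather than the nuclear outline, so the
nuclear-fraction readout is validated on field-style images only.

`intensity_profile()` supplies the line-profile view (bilinear interpolation
at 1-pixel steps, 0-based `(x, y)` coordinates, distances converted to
micrometers when a pixel size is available). `batch_quantify()` applies all
metrics per image with per-group mean ± SEM summaries, skipping and flagging
unreadable images.

## Synthetic micrographs

`generate_nucleus_image()` renders an elliptical nucleus (radius ≈ 0.36 of
the image side, jittered), 1–3 dark nucleoli, and in `airyscan` style a
heterochromatin mask defined by thresholding a sum-of-Gaussians blob field
at the 60th percentile of the nucleoplasm (≈ 40% chromatin coverage).
Protein foreground pixels are *placed by exact counting*: given a target
colocalization fraction and an area multiple of the chromatin mask, the
generator samples exactly the right number of pixels inside and outside the
DNA foreground, so the truth block's overlap fraction is the realized one,
recomputable by direct counting. The four phenotype presets are
`diffuse` (fills the nucleoplasm; colocalization equals the chromatin area
fraction by construction), `dna_cage` (area 0.9× chromatin, coloc 0.85),
`anti_dna_aggregate` (0.45×, coloc 0.05), and `condensate` (0.35×, coloc
0.35, placement weights concentrated in 2–4 foci).

Intensity design is deliberately moment-friendly so that the named
thresholds recover the generative masks: background 0.02, nucleoplasm
0.07–0.10, chromatin 0.80–0.86, protein foreground drawn from a
rising-density band 0.85–0.88 (sparse at its bottom edge). Two facts drove
this: Tsai's percentile selection eats exactly `(p0 − true background
fraction) × N` pixels, an error that scales with the within-class variances,
so both the low-intensity classes and the foreground band are kept narrow;
and making the band's lower edge sparse makes any residual percentile
overshoot cost only a handful of pixels. With the default additive Gaussian
noise (sd 0.02 on the [0, 1] scale) mean measured colocalization tracks the
requested level within ±0.015 across the 0.1–0.9 range; noiseless images
recover all ratios within ±0.02.

What the generator does **not** emulate: optics (no PSF, no Airyscan model),
3D structure, uneven illumination, cell-to-cell expression variability
beyond the placement randomness, or spatially continuous protein texture —
foreground is speckle-granular at the pixel level. Passing tests therefore
demonstrate correctness of the *measurement chain*, not robustness to every
real-microscopy artifact.

## FRAP

`normalize_frap()` follows the standard double-normalization convention:
background subtraction, framewise division by the bleach control (which by
construction cancels exponential photofading exactly — the generator applies
the same `exp(-rate * t)` to ROI and control), then full-scale anchoring
with the pre-bleach mean at 100% and the bleach-frame value (a single
frame, not a smoothed minimum) at 0%. When no bleach frame is supplied the
global minimum of the background-subtracted ROI trace is used (earliest on
ties).

`fit_single_exponential()` fits the two-parameter model
`y(t) = A (1 - exp(-k t))` to the post-bleach frames (the anchored bleach
frame included, consistent with `y(0) = 0`), by Levenberg–Marquardt with
`k > 0` bounded, parameter tolerances 1e-8, initialized at
`A0 = mean(final 10%)` and `k0 = ln 2 / t(A0/2)`. The half-time is reported
as `ln(2)/k`, so `t_half * k = ln 2` holds exactly. The generator's default
series length is 145 frames (2 pre-bleach + 143 post-bleach at 1 s), a
realistic confocal time-series, with bleach depth 0.7 and mobile fraction
0.85. At 2% noise the median fitted half-time over 60 recordings — a
typical per-condition sample size — lands within 10% of `ln(2)/k`;
noiseless recovery is exact to 1e-6 relative.

## Dual-luciferase reporter assays

Each replicate's firefly counts are divided by its Renilla counts
(transfection normalization), and ratios are expressed relative to the
*mean* ratio of the empty-vector control — an unpaired normalization, since
conditions are independent transfections. The control's mean relative
activity is therefore 1 by construction, and relative activities are
invariant to rescaling either luciferase globally.

The simulator applies one independent mean-1 log-normal factor per
luciferase per replicate (`sigma^2 = log(1 + cv^2)`), so the expected
condition/control ratio equals `1 - mean_repression` exactly; a shared
transfection factor would cancel in the ratio and is omitted. The wild-type
default effect size is 75% repression with cv = 0.1 and 8 replicates.

`repression_call()` labels each condition against the wild type by a
Dunnett-adjusted two-sided comparison at α = 0.05 (configurable):
significantly higher activity → `reduced_repression`, significantly lower →
`increased_repression`, otherwise `retained`. Calls are made per reporter
construct (the Ctip2-MAR and Nr4a2-MAR targets are assayed separately) and
combined only at classification time.

## ANOVA and Dunnett's test

`one_way_anova()` delegates to `stats::oneway.test(var.equal = TRUE)` and
flags all-constant data as degenerate. `dunnett_test()` computes
`t_i = (mean_i - mean_ref) / sqrt(MSE (1/n_i + 1/n_ref))` on the pooled
within-group mean square and adjusts two-sided p-values under the
equicorrelated multivariate-t null, `rho_ij = sqrt(lambda_i lambda_j)` with
`lambda_i = n_i / (n_i + n_ref)` (0.5 when balanced), pooled error df. The
tail probability `P(max_j |T_j| >= |t|)` is evaluated by seeded Monte-Carlo
(default 1e5 draws, sampling the shared chi factor and the one-factor
correlated normals), which keeps the procedure dimension-agnostic and
bit-reproducible; each p-value carries its Monte-Carlo standard error, and
the seed and draw count are stored in the result. Adjusted p-values are
floored at the exact unadjusted pooled-t p so the invariant
`p_adj >= p_unadjusted` cannot be broken by Monte-Carlo noise; with one
comparison group the procedure reduces to the plain pooled t-test. The test
suite cross-checks the adjusted p-values against `multcomp::glht` on
balanced and unbalanced designs and calibrates the family-wise error rate
at 5 comparisons, n = 20 per group, over 1000 null simulations.

Comparison families are defined per assay type and per reporter construct;
each output row records the method, seed, and draw count.

## Variant classification

`build_profiles()` turns each readout's Dunnett comparison against the wild
type into a standardized call (`increased`/`normal`/`decreased` for imaging
metrics; `reduced_mobility` for significantly longer FRAP half-times; the
repression labels above per reporter), joins them by variant, and logs every
call's effect estimate and adjusted p-value in a provenance attribute. The
wild type itself is `normal`/`retained` by definition for any assay it
appears in.

`assign_subgroup()` applies a versioned rule table (`"v1"`):

1. `condensate_class` — the localization pattern is `condensate`, **or** the
   variant lies in the HOX domain *and* shows at least one abnormal call.
   The extra abnormality requirement exists because benign HOX-region
   variants with all-normal profiles occur in healthy populations and must
   not be swept into the condensate class by domain membership alone.
   Condensate takes precedence over `partial_LoF`: these variants also lose
   repression, but through a qualitatively different, aggregating mechanism.
2. `increased_function` — DNA colocalization increased and neither reporter
   reduced. Reduced nuclear mobility supports but is not required, since not
   every variant was assayed by FRAP.
3. `partial_LoF` — at least one reporter shows reduced repression and
   colocalization is not increased.
4. `unclassified` otherwise (including the contradictory case of increased
   colocalization together with reduced repression, which satisfies neither
   rule — the subgroups are mutually exclusive by construction).

Whether `increased_function` should require both reporters to agree is a
genuinely open choice; the default requires only the *absence* of a reduced
call on both, and the rule table is versioned so alternative
operationalizations can be compared side by side.

The bundled table `extdata/satb2_variant_calls_synthetic.csv` encodes the
standardized outcomes for a 34-variant cohort (31 etiological + 3
population controls). Twenty-two etiological variants carry their
individually published outcome patterns; 9 rows are synthetic placeholders
(flagged in the `synthetic` column) consistent with the cohort's subgroup
totals, since only aggregate results are published for them. Classifying
the etiological subset yields 8/31 (≈ 26%) increased-function variants.

## Determinism and problem sizes

Every stochastic function takes an explicit seed and routes randomness
through an isolated RNG scope, so identical seeds give bit-identical
objects and the full CLI pipeline reproduces output file hashes from one
seed. The test suite uses problem sizes chosen to give stable Monte-Carlo
estimates at interactive runtimes: 1000 simulated reporter plates, 200
synthetic nuclei per phenotype, 60 FRAP recordings per condition, 1000
null simulations for family-wise error calibration with 1e5 Dunnett draws
each, and 1000 random histograms for the threshold oracles.

## Known limitations

* The thresholds implement the per-image, unsmoothed-histogram variants; no
  stack histograms and no other auto-threshold methods (Huang, Triangle, …).
* No nucleus segmentation: single-nucleus images are assumed for the
  single-nucleus metrics, and the field-of-view metric makes no exclusion
  of border-touching or saturated regions.
* One-component FRAP model only; reaction–diffusion or two-component
  kinetics are out of scope, as is extracting ROI traces from image stacks.
* No plate-effect or batch-correction modeling for the reporter assays.
* The classifier operationalizes verbal criteria; it is a transparent,
  versioned decision table, not a learned or probabilistic model.
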