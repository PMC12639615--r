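# satb2quant

Quantification toolkit for the cell-based assays used to functionally
classify missense variants of SATB2, a matrix-attachment-region (MAR)
binding transcription factor whose haploinsufficiency causes
SATB2-associated syndrome. Missense variants in its CUT1/CUT2/HOX
DNA-binding domains can weaken DNA binding and target repression (partial
loss of function), strengthen them (increased function), or drive the
protein into nuclear condensates — and distinguishing these requires
combining imaging, protein-mobility, and reporter readouts. This package
implements that quantification layer as tidyverse-style R functions, plus
seeded synthetic-data generators so every stage has an exact ground truth.

## What it computes

**Nuclear localization metrics** on two-channel micrographs (protein + DNA
stain), using the four classical automatic 8-bit-histogram thresholds
(Otsu, Li minimum cross-entropy, Tsai Moments, Minimum) with the ImageJ
"foreground strictly above the level" convention:

- aggregation ratio = area(protein mask, Moments) / area(DNA mask, Minimum)
  — smaller when the protein clusters;
- colocalization ratio = area(protein ∧ DNA, both Moments) / area(protein)
  — the fraction of protein signal sitting on chromatin;
- nuclear fraction = area(protein ∧ DNA; Li/Otsu) / area(protein) — the
  nuclear proportion of the signal in field-of-view images;
- intensity line profiles of both channels along a segment (Plot Profile
  equivalent).

**FRAP**: double normalization (background subtraction, bleach-control
division, pre-bleach = 100% / bleach frame = 0% anchoring) and
least-squares fitting of the single-component recovery model
`y(t) = A (1 − e^(−kt))`, reporting the plateau (mobile fraction), rate
`k`, half-time `t½ = ln 2 / k`, and R².

**Dual-luciferase reporters**: firefly/Renilla ratios expressed relative to
the empty-vector control, with per-condition mean ± SEM and
Dunnett-adjusted repression calls (`reduced_repression` / `retained` /
`increased_repression`) against the wild type.

**Inference**: one-way ANOVA plus Dunnett's many-to-one post hoc test with
`t_i = (x̄_i − x̄_ref)/√(MSE(1/n_i + 1/n_ref))` and two-sided adjusted
p-values `P(max_j |T_j| ≥ |t_i|)` under the equicorrelated multivariate-t
null (ρ = ½ balanced), evaluated by seeded Monte-Carlo integration with
reported standard errors.

**Classification**: per-variant profiles of standardized calls joined
across assays, assigned to functional subgroups (`increased_function`,
`partial_LoF`, `condensate_class`, `unclassified`) by a versioned rule
table.

## Worked example

```r
library(satb2quant)

# a synthetic nucleus with a DNA-cage phenotype, and its measured metrics
pair <- generate_nucleus_image(nucleus_phenotype("dna_cage"), seed = 1)
pair
#> <image_pair> 128x128 px, phenotype=dna_cage, style=airyscan, seed=1
#>   truth: coloc=0.850 nuclear=1.000 aggregation=0.900
quantify_pair(pair)[, 1:3]
#>   aggregation_ratio coloc_ratio nuclear_fraction
#> 1             0.907       0.845            0.850

# FRAP: simulate, normalize, fit
rec <- generate_frap_recording(frap_sim_params(k = 0.04, noise_sd = 20), seed = 1)
fit_single_exponential(normalize_frap(rec))
#> <frap_fit> plateau = 87.2%, k = 0.04183 /s, t_half = 16.6 s, R^2 = 0.9708

# reporter assay at the wild-type effect size (75% repression)
tab <- generate_reporter_table(list(control = reporter_sim_params(0),
                                    WT = reporter_sim_params(0.75)), seed = 1)
reporter_summary(relative_activity(tab))
#>   condition n mean_relative_activity    sem
#> 1 WT        8                  0.254 0.0121
#> 2 control   8                  1     0.0448

# classify the bundled 31-variant etiological cohort
classified <- assign_subgroup(satb2_variant_calls())
cohort_summary(classified[classified$cohort == "etiological", ])
#>   subgroup           n fraction
#> 1 increased_function 8   0.258
#> 2 partial_LoF        20  0.645
#> 3 condensate_class   3   0.0968
#> 4 unclassified       0   0
```

The measured ratios track the generator's exact truth (coloc 0.845 vs 0.850
requested); the FRAP fit recovers the simulated `k = 0.04 /s` (truth
`t½ = 17.3 s`) from a noisy recording; the wild-type condition shows ~75%
repression relative to the empty vector; and 8 of 31 etiological variants
(≈ 26%) classify as increased function.

See `vignettes/satb2quant-methods.Rmd` for the models, parameter defaults,
numerical choices, and what the synthetic data does and does not emulate.

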