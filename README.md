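# smlmcoloc

Coordinate-based colocalization analysis for two-channel single-molecule
localization microscopy (SMLM/STORM), built around the kind of question
asked of the photoreceptor rod Golgi: do two immunolabeled proteins
occupy the same subcompartment of a sub-micrometer organelle, or closely
apposed but distinct ones?

## The statistic

Per region of interest (one organelle, two channels of fitted molecule
coordinates in nm):

1. the organelle **center** is the mean position of the reference
   channel's molecules;
2. each channel becomes a distribution of molecule **distances to that
   center**;
3. the exact two-sample Kolmogorov–Smirnov statistic
   `D = sup_x |F₁(x) − F₂(x)|` compares the two empirical distance CDFs;
4. the **overlap score** is `1 − D`: 1 for identical distance
   distributions, 0 for fully separated ones.

Scores are aggregated by condition and compared with the mean-based
Brown–Forsythe heteroscedastic ANOVA

    F* = Σ nᵢ(ȳᵢ − ȳ)² / Σ (1 − nᵢ/N) sᵢ²

(Satterthwaite-type denominator df) and Dunnett-T3-style pairwise
comparisons (Welch t with Welch–Satterthwaite df, studentized-maximum-
modulus adjustment over the requested pairs). Intensity-ratio
quantifications for layered retina images (myoid/total-IS,
IS/photoreceptor, surface-label/reporter) and pooled-variance unpaired
t-tests round out the pipeline. A seeded synthetic-data generator
produces two-channel point patterns (elliptical cisterna shell versus
vesicular clusters, controllable inter-channel offset, localization
noise, uniform background) and layered intensity images with ground
truth, so everything is testable without microscope data.

## Worked example

The numbered scripts under `analysis/` run the full study — simulate
two conditions to disk, score every ROI, compare groups, quantify
intensity ratios:

```sh
Rscript analysis/01_simulate_storm.R
Rscript analysis/02_score_overlap.R
Rscript analysis/03_group_comparison.R
Rscript analysis/04_intensity_ratios.R
```

which prints

```
scored 80 ROIs; overlap range 0.308-0.963
  colocalized  mean overlap 0.894 (n=40)
  apposed      mean overlap 0.581 (n=40)
   condition  n  mean median    q1    q3
 colocalized 40 0.894  0.897 0.867 0.931
     apposed 40 0.581  0.597 0.526 0.653

Brown-Forsythe ANOVA: F* = 337.7 (df 1, 58.8), p = 4.88e-26
Dunnett T3 colocalized vs apposed: t = 18.38, df = 58.8, adj. p = 2.23e-308
```

Read: 40 simulated single-Golgi ROIs per condition (3,500–6,200
molecules per channel). The "colocalized" geometry (vesicle clusters on
the reference shell, zero offset) scores a mean overlap of 0.89; the
"apposed" geometry (identical but offset 300 nm) drops to 0.58, and the
heteroscedastic group comparison separates the two decisively. Per-ROI
rows, summaries, ANOVA and pairwise tables land under `results/`.

The same machinery runs on real exports: `read_localizations()` with a
column-mapping dialect, `read_rois()` for ROI JSON, then
`run_storm_pipeline()`; `read_layer_image()` + `run_ratio_pipeline()`
for mask-annotated intensity images.

## Scope

The pipeline starts from fitted localization tables and hand-drawn
ROIs/masks. Raw-frame fitting, drift correction, chromatic calibration,
segmentation, and curvature straightening of retinal sections are
acquisition/preprocessing steps outside its scope; see the vignette in
`vignettes/` for the model, parameter defaults, and limitations.
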