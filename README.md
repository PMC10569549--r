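# hivemorph

Volumetric segmentation and morphometry of bee brains from micro-CT scans,
as an R package. hivemorph is aimed at comparative neuroanatomists who want
to measure neuropil volumes across large cohorts of social bees (honey
bees, bumblebees) without segmenting hundreds of scans by hand, and at
methods developers who need a fully testable reference implementation of
the pipeline.

The pipeline covers:

- **Synthetic phantoms** (`sample_cohort()`, `render_phantom()`): labelled
  3D volumes emulating stained micro-CT scans of bee brains, with realistic
  cohort structure — per-specimen and hive-level volume variation,
  left/right asymmetry, occasionally midline-merged mushroom bodies — so
  every downstream stage is testable without external data.
- **Preprocessing** (`denoise_mean3()`, `normalize_intensity()`,
  `flip_z()`, `auto_crop()`): 3×3×3 arithmetic mean denoising, intensity
  standardization, orientation normalization, and automatic cropping to the
  brain region via per-axis CNN slice classifiers.
- **Segmentation** (`build_unet()`, `train_unet()`, `predict_volume()`): a
  patch-based 3D U-Net — two 3×3×3 conv + batch-norm + ReLU blocks per
  level, 2×2×2 max pooling, channels doubling per level, skip connections —
  trained with SGD (lr 0.01, decay 1e-6, Nesterov momentum 0.9) on
  overlapping 64³ patches of volumes rescaled to 256³ (full profile), with
  best-validation-epoch selection and exact overlap-averaged stitching.
  Implemented natively on BLAS; no deep-learning framework required.
  `finetune_encoder()` (frozen decoder) and `learning_curve()` cover the
  transfer and data-efficiency experiments.
- **Postprocessing & morphometry** (`remove_islands()`,
  `split_left_right()`, `measure_volumes()`): connected-component outlier
  removal (threshold 0.1 of the largest component, CX excluded), centroid
  left/right splitting with merged-MB detection, and voxel-count volumetry
  (mm³, relative volumes, OL = ME + LO).
- **Evaluation** (`dice()`, `assd()`, `error_category()`): Dice similarity
  `2|X∩X′|/(|X|+|X′|)` per label and total, average symmetric surface
  distance from an exact Euclidean distance transform, and the
  correction-burden triage (<0.01% negligible, 0.01–4% slight, >4% flawed).
  Both metrics are validated against brute-force oracles in the test suite.
- **Cohort statistics** (`percent_variation()`, `pearson()`,
  `allometric_slope()`, `colony_effect_test()`, `lateralization_test()`,
  `asymmetry_quadrants()`, `simulate_operating_characteristics()`):
  volume-variation percentages `(max−min)·100/max`, correlations, log–log
  allometry against isometry (slope 1), mixed-model hive F-tests
  (population as random intercept; containment df, e.g. F(8, 101) for 110
  bees in 9 hives), paired left/right t-tests, asymmetry quadrants, and
  simulation-based type-I/power checks of those tests.

I/O sticks to open formats: NRRD (native), NIfTI-1, multi-page TIFF,
CSV/XLSX specimen tables. `run_pipeline()` chains everything with stage
toggles and reproducible seeds; `inst/cli/hivemorph` is a thin command-line
wrapper with `simulate`, `train`, `predict`, `evaluate`, `morphometry`,
`stats`, `learning-curve`, `oc-sim` and `run` subcommands.

## Worked example

```r
library(hivemorph)

# a small cohort of honeybee-like phantoms
pp <- phantom_params(grid_shape = c(32, 32, 32), seed = 11)
cohort <- sample_cohort(pp, hive_plan = c(H1 = 14))
pairs <- lapply(1:14, function(i) {
  ph <- render_phantom(cohort[i, ], pp, seed = 100 + i)
  list(image = denoise_mean3(ph$image), labels = ph$labels)
})

# train on 8, validate on 2, test on 4 (CPU-scale profile)
cfg <- net_profile("micro", epochs = 20, base_channels = 8,
                   max_channels = 64, stride = 16, val_freq = 5, seed = 1)
m <- train_unet(pairs[1:8], pairs[9:10], cfg)

pred <- predict_volume(m, pairs[[11]]$image)
evaluate_segmentation(pred, pairs[[11]]$labels)
#> <eval_result> total Dice 0.9624 (error 3.76%, slight), total ASSD 0.145 vox
#>   per-label Dice: 1=0.961 2=0.971 3=0.000 4=0.971 5=0.920 6=0.967

# morphometry on the cleaned segmentation
rec <- measure_volumes(remove_islands(pred))
round(rec[, c("AL", "MB", "CX", "OL", "OTH", "total")], 6)
#>        AL       MB CX       OL      OTH    total
#> 1 5.6e-05 0.000267  0 0.000388 0.000339 0.001051

# cohort statistics on a study-sized synthetic table
tab <- cohort_to_table(sample_cohort(phantom_params(seed = 3),
                                     hive_plan = honeybee_hive_plan()))
colony_effect_test(tab, "AL")
#> <stat_result> F(8,101) = 1.776, p = 0.09054, n = 110
lateralization_test(tab, "OL")
#> <stat_result> t(df=109) = -0.6328, p = 0.5282, n = 110
```

Reading the output: 96.2% total voxel overlap with the ground truth (a
"slight" correction burden — one or two minutes of manual cleanup on a real
scan) and predicted surfaces off by 0.15 voxels on average. The central
complex (label 3) is missed entirely on this specimen — at 32^3 it spans
only a handful of voxels, faithfully mirroring CX's status as the hardest,
most correction-prone class at full scale. Being tiny, it barely moves the
overlap-weighted total. The F-test reproduces the degrees of freedom of the
published honey-bee design (9 hives, 2 apiary populations, n = 110), and
the lateralization test is, correctly, null on this symmetric cohort.

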