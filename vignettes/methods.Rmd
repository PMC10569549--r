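---
title: "Models and methods behind hivemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hivemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hivemorph is a pipeline for large-scale volumetric comparison of insect
brains from micro-CT data. It covers the whole path from a stained,
reconstructed scan to population statistics: denoising, locating the brain
(automatic cropping), semantic segmentation of six neuropils with a
patch-based 3D U-Net, cleanup and left/right splitting of the segmentation,
volumetric morphometry, and the statistical analyses used in comparative
bee neuroanatomy. A synthetic phantom generator stands in for scan data so
that every stage is testable without external downloads. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic experiments do and do not establish about real data.

## The segmentation problem

Honey bee (*Apis mellifera*) and bumblebee (*Bombus terrestris*) brains are
under 1 mm^3 yet show large inter-individual variation in the sizes of
their functional regions. The six segmentation classes are the paired
antennal lobes (AL, olfactory input), paired mushroom bodies (MB, learning
and memory; the two sides sometimes touch across the midline and then
cannot be separated automatically), the small central complex (CX, the
hardest class: fine structure and low contrast), the paired medullae (ME)
and lobulae (LO) which together form the optic lobes (OL = ME + LO), and
the remaining neuropils (OTH). Total brain volume is the sum of the six.
OL is always derived, never stored as a voxel label; label ids are fixed as
0 = background, 1 = AL, 2 = MB, 3 = CX, 4 = ME, 5 = LO, 6 = OTH.

Arrays are ordered (z, y, x) throughout; the anatomical left-right axis is
the third array axis and "left" means lower x index. Voxel spacing is
isotropic, 0.0054 mm in the reference protocol.

## Synthetic phantoms

`phantom_params()` + `sample_cohort()` + `render_phantom()` generate
image/label pairs with the statistical structure the analyses assume.

**Cohort draws.** Volumes are positive and right-skewed, so each specimen's
neuropil volume is drawn lognormally around the preset mean. The draw has
three factors: a hive-level multiplier (log-sd `hive_sigma`, default 0.02)
shared within a hive; a per-specimen size factor (`size_cv`, default 0.06)
shared by all neuropils of one brain; and a per-neuropil residual chosen so
that the *marginal* CV of each neuropil matches the preset. The shared size
factor is what produces the positive correlations between all neuropil
volumes, a total-brain CV of about 7%, and near-isometric part-whole
scaling, all of which real cohorts show; without it the generator would
produce anatomically implausible independent volumes. The lognormal family
itself is an assumption — the field's data are usually summarized as
approximately normal, and at these CVs (7-12%) the two families are
practically indistinguishable.

**Lateralization.** Paired neuropils are split by drawing
`log(L/R) ~ Normal(log(1 - delta), lateral_noise_cv^2)`: `delta` is the
expected fractional left deficit (0 under symmetry; about 0.02-0.05 matches
the directional asymmetries reported for bumblebee optic lobes, where ~62%
of individuals had a smaller left side), and `lateral_noise_cv` (default
0.03) is the specimen-to-specimen scatter of the log ratio. With `delta = 0`
the ratio distribution is symmetric, so the paired *t*-test holds its
nominal level. A `p_merge_mb` probability renders the two mushroom bodies
touching across the midline, reproducing the non-separable MB segmentations
seen in practice.

**Presets.** The honeybee preset uses the published cohort summary of 110
foragers (shipped as `inst/extdata/honeybee_cohort_summary.csv`); the
bumblebee preset keeps the same central volumes but multiplies the CVs by
1.6, a stylized version of the much larger variability of bumblebee
workers. Both are conveniences; every value is overridable.

**Rendering.** Six classes are rasterized as ellipsoids in anatomically
inspired positions (AL anterior, MB dorsal flanking the midline, CX small
and central, ME/LO lateral, OTH central mass). Structure volumes are
rescaled so the brain fills `fill_fraction` (default 0.22) of the grid —
desk-sized grids cannot hold a full-resolution brain at true scale, so the
phantoms preserve relative, not absolute, volumes. Rasterization quantizes
the targets and adjacent ellipsoids contest boundary voxels (ties go to the
nearer surface); a second calibration pass inflates the losers so achieved
voxel counts track the draws to about 1 percentage point of relative
volume. The voxel-true achieved volumes are recorded and are the reference
for morphometry tests. The image is a tissue-intensity lookup (distinct
gray levels per class, 20 units apart), Gaussian blur (`blur_sigma` 0.7
voxels) and additive Gaussian noise (`noise_sd` 8, i.e. 2.5 gray-level
gaps per noise s.d. before denoising).

**What phantoms do not emulate:** real neuropil geometry (calyces,
peduncles), CT physics (beam hardening, rings, streaks), staining
gradients, damaged or incompletely stained tissue, and the low CX contrast
that makes CX the dominant error source on real scans. A network that
segments phantoms at Dice 0.95 is therefore evidence that the training,
stitching and evaluation machinery is correct — not that the same
configuration reaches any particular accuracy on micro-CT scans.

## Preprocessing

`denoise_mean3()` is the arithmetic 3x3x3 mean filter applied to stained
scans before interpolation or training; borders use reflect padding (edge
slice duplicated). The choice of border policy is ours (the operator is
standard but underdetermined at borders); the test-suite oracle implements
the same policy independently. `normalize_intensity()` rescales every
volume to a common mean and variance (0/1) before the network sees it.
`flip_z()` normalizes specimens scanned upside down and is an involution.

**Automatic cropping.** Training and inference improve markedly when scans
are cropped to the neuropil region. Three per-axis binary slice
classifiers decide whether each slice contains the object; the box spans
the first to last positive slice plus a safety buffer of 25 slices at the
256-slice reference scale, scaled as `round(25 * len/256)` with a floor of
2 for small grids. The classifier is a small from-scratch 2D CNN (two
conv+BN+ReLU+pool blocks, global average pooling, dropout 0.3, sigmoid
head) trained with binary cross-entropy and Adam in two phases: head only
at learning rate 1e-3, then the full network. The two-phase shape follows
the standard transfer-learning recipe; because our backbone is randomly
initialized rather than pretrained, the second phase also defaults to 1e-3
(a 1e-5 fine-tuning rate, appropriate when the backbone already encodes
ImageNet features, would leave random convolutions untrained — we verified
that held-out slice accuracy then stalls far below usable levels). Slice
classes are strongly unbalanced along some axes (an uncropped scan has few
object-free x slices), so the loss is class-balanced. Ground truth for
"contains the object" is any non-background voxel in the slice.

## The 3D U-Net

`build_unet()` follows the standard 3D U-Net layout: per level two 3x3x3
convolutions each followed by batch normalization and ReLU, 2x2x2 max
pooling between encoder levels, feature channels doubling from
`base_channels` up to `max_channels`, and a decoder of nearest upsampling,
skip concatenation and two conv+BN+ReLU blocks per level, closed by a 1x1x1
convolution onto the class scores. Volumes are resampled to a working shape
(trilinear for images, nearest for labels), standardized, and cut into
overlapping cubic patches (patch 64, stride 32 at full scale) that are
zero-padded to stride multiples; offsets are recorded so stitching is
exact.

Training minimizes voxel-wise categorical cross-entropy — the loss is our
choice; it is the standard choice consistent with monitoring plain voxel
accuracy — with stochastic gradient descent at learning rate 0.01, decay
1e-6 (inverse-time), momentum 0.9 with Nesterov enabled, 200 epochs and
batch 24 in the full-scale profile. After each epoch (configurable cadence)
the current network segments the validation volumes by full stitched
inference and the mean total Dice is recorded; the weights of the best
validation epoch are kept, not the last. Class scores of overlapping
patches are fused by averaging softmax probabilities before the argmax
(majority voting over per-patch argmaxes is available by flag); with
stride = patch the stitched result equals per-patch argmax reassembly
exactly, which the suite asserts.

`finetune_encoder()` implements cross-species transfer: the decoder and
classification head are frozen and only the encoder is optimized on the new
species' data, which helps when very few labelled volumes exist.
`learning_curve()` retrains from scratch for increasing numbers of training
volumes and evaluates Dice/ASSD on a fixed test set, reproducing the
rising-then-plateauing accuracy that motivates stopping manual annotation
after a dozen or two volumes.

**Implementation.** No deep-learning framework is available to this
package, so the network is implemented natively: activations are
(voxels x channels) matrices, a 3x3x3 convolution is an im2col gather (C++)
followed by a single BLAS GEMM, and its adjoint is the reverse gather, so
the whole training loop runs on the platform BLAS. Backpropagation is
verified against central finite differences to ~1e-9 relative error in the
suite. Determinism: all randomness (init, shuffling, noise) derives from
configuration seeds, and two runs with the same config are bit-identical.

**Profiles and problem sizes.** The `paper` profile is the full-scale
configuration (256^3 working shape, channels 32..1024, 200 epochs, batch
24); it is provided for completeness and needs GPU-class throughput. The
`desk` profile (96^3, channels 8..128, 40 epochs) is a reduced single-CPU
configuration. The test suite and the acceptance script run a further
reduced scale chosen to keep a complete train/evaluate cycle in CPU
minutes: 32^3 phantoms, patch 16, stride 16, channels 8..64, 20 training
epochs (10 for the learning-curve replicates), 8 training / 2 validation /
4 test phantoms. At this scale the held-out total Dice is ~0.95 and the
learning curve over k = 2, 4, 8 training phantoms rises monotonically in
nearly every seed; the accuracy thresholds asserted by the suite
(total Dice >= 0.90, monotone curve in >= 4/5 seeds) are not relaxed
relative to the full-scale expectations.

## Postprocessing and morphometry

`remove_islands()` removes outlier components: per label, 26-connected
components smaller than `threshold` (default 0.1) times that label's
largest component are relabeled to background. The threshold is interpreted
as a fraction of the largest component, which makes the published
preference for 0.1 over 0.9 coherent — near-equal paired bodies have a size
ratio close to 1, so 0.1 never deletes the smaller side of a pair, whereas
0.9 would. CX is excluded by default (small, fragmented CX output is better
kept for review). The operator is idempotent and never increases a label's
count.

`split_left_right()` places the midline at the x-centroid of all
paired-label voxels (robust to off-center crops), assigns each 26-connected
component to the side containing its centroid, and flags a label
non-separable when it forms a single component spanning both sides by more
than 5% each — the signature of midline-merged mushroom bodies; the 5% span
and the centroid tie-break (majority voxel side, then left, with a warning)
are implementation choices exposed in the arguments. `measure_volumes()`
converts voxel counts to mm^3 (count x spacing^3), derives OL, total,
relative volumes (percent of total over AL, MB, OL, CX, OTH) and left/right
volumes, withholding sides for non-separable labels.

## Evaluation metrics

Dice per label is `2|X_i ∩ X'_i| / (|X_i| + |X'_i|)`; total Dice sums
intersections over labels and divides by the total non-background voxel
counts. Whether background belongs in the totals is ambiguous in common
usage; we exclude it, since including it inflates scores toward 1 on
mostly-empty grids and would misstate the correction burden. The convention
is applied consistently, so internal comparisons are unaffected. A label
empty on both sides scores 1 and is flagged.

ASSD uses 6-connectivity surfaces (a labelled voxel with a face neighbour
outside the label; array borders count). Distances come from an exact
Euclidean distance transform (Felzenszwalb/Huttenlocher, three 1D passes),
summed symmetrically and divided by the total surface count; reported in
voxels and mm. A label with surface on exactly one side is undefined (NA,
flagged, excluded from the total). Both metrics are validated in the suite
against brute-force oracles (set arithmetic; all-pairs distances) on
hundreds of random small volumes — Dice exactly, ASSD to 1e-9.

Error triage mirrors the published correction-burden bands on
`error = (1 - total Dice) x 100`: below 0.01% negligible, 0.01-4% slight,
above 4% flawed.

## Cohort statistics

- `percent_variation()`: `(max - min) x 100 / max`, the spread statistic
  used in the published cohort tables. Recomputing it from the published
  min/max reproduces the printed percentages to printed precision; the
  suite propagates the rounding half-ulp of the printed min/max as the
  comparison tolerance.
- `pearson()`: product-moment correlation with the two-sided *t* p-value
  (n - 2 df), via `cor.test`.
- `allometric_slope()`: least-squares slope of log(part) on log(total);
  slope 1 is isometry, and the flag reports whether the 95% CI contains 1.
- `colony_effect_test()`: linear mixed model (lme4) with hive as fixed
  effect and population as random intercept, followed by an F-test of the
  hive term. Denominator df use the containment convention n - n_hives
  (numerator n_hives - 1): for the honey-bee design (110 bees, 9 hives, 2
  populations) this gives F(8, 101), matching the published statistics;
  Satterthwaite approximations would give fractional df that do not. With a
  single population the model reduces to one-way ANOVA with the same df.
- `lateralization_test()`: Student's paired t-test of left minus right,
  plus the percentage of specimens with a strictly smaller left side; rows
  with non-separable sides are excluded and counted, exact ties reported.
- `asymmetry_quadrants()`: sign-based classification of each specimen by
  (right - left) of two pairs into four categories with strict
  inequalities; ties are measure-zero on real data but common on phantoms,
  so they are excluded and reported rather than silently assigned.
- `simulate_operating_characteristics()`: draws cohorts (volumes only, no
  rendering) and measures test rejection rates. Under delta = 0 the
  lateralization test holds its 5% level; at delta = 0.05 with log-ratio
  noise 0.03 and n = 77 (the bumblebee design) power exceeds 0.9 — the
  observed optic-lobe asymmetry is comfortably detectable at that sample
  size.

## I/O and the pipeline

Open formats only: NRRD (native reader/writer — text header plus raw or
gzip block; float32 images, uint8 labels with a JSON sidecar label map),
NIfTI-1 (RNifti), multi-page TIFF (no spacing metadata; a 1 mm default is
used with a warning), CSV/XLSX specimen tables with documented column
synonyms. AMIRA Mesh is deliberately unsupported. `run_pipeline()` chains
simulate → preprocess → train → predict → postprocess → evaluate → stats
with stage toggles; every run writes its seed and a config hash, and
identical configs produce identical summaries. A thin command-line wrapper
(`inst/cli/hivemorph`) exposes the stages as subcommands.

## Known limitations

- Phantom geometry is ellipsoidal; none of the fine anatomy that makes CX
  hard on real scans is present, so per-label difficulty rankings on
  phantoms do not transfer to micro-CT data.
- The native network trains at CPU speed; the full-scale profile is
  provided but impractical without hardware acceleration.
- No real per-specimen measurement table is bundled; statistics that
  require per-specimen data are demonstrated on synthetic cohorts, and only
  the published summary statistics are recomputed literally.
- Non-isotropic voxel spacing is not supported; inputs are expected
  resampled to isotropic grids.
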