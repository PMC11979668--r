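---
title: "Prior-mask-guided staged segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-mask-guided staged segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gross tumour volumes in the head-and-neck region — the primary tumour
(GTVp, label 1) and involved lymph nodes (GTVn, label 2) — must be
delineated on MRI both before radiotherapy and again mid-treatment, when
the tumour has typically shrunk. Automating the mid-treatment task has a
structural advantage over the pre-treatment one: a registered earlier scan
and its segmentation already exist, and a tumour that responds to therapy
stays roughly where it was while losing volume. `stagedseg` implements a
coarse-to-fine strategy built on that observation:

1. a *prior mask* (a first-stage model output, or the registered
   pre-treatment segmentation) restricts where training patches are drawn
   (`sample_masked()`: the patch centre is a uniformly chosen nonzero voxel
   of the binarized prior);
2. the prior image and prior mask may additionally enter the network as
   extra input channels (`channel_recipe()`);
3. sliding-window inference may be restricted to patches that intersect
   the prior (`sliding_window_predict(roi = ...)`), with uncovered voxels
   labelled background by contract.

The configurations compared in `run_pre_rt_pipeline()` and
`run_mid_rt_pipeline()` follow the usual ablation naming: *c1* uses the
prior only for sampling, *c2* adds the mask as an input channel, *c3*
stacks image + prior image + prior mask, and *staged_c3* combines c3 with
mask-guided sampling and mask-restricted inference.

## The network and loss

The backbone is a compact 3D residual encoder-decoder
(`build_network()`): residual blocks of two conv(3³)–instance-norm–leaky-ReLU
units with an identity skip (1×1×1 projection on channel change), strided-conv
downsampling, transposed-conv (2³, stride 2) upsampling with encoder skip
concatenation, and 1×1×1 heads emitting logits at the `ds_levels` finest
decoder resolutions. Full-scale incarnations of this family run seven
stages and hundreds of channels; the desk configurations run three
stages at 3-8 base channels, because every experiment here must run on
one CPU in minutes. The forward and backward passes are implemented in the package
(compiled direct convolutions; gradients verified against central finite
differences in the test suite), so results do not depend on an external
deep-learning runtime.

Training minimizes a deep-supervision composite loss
(`composite_loss()`): per level, an equally weighted sum of cross-entropy
and soft Dice, the latter computed per foreground class with
intersections and sizes pooled over the batch ("batch Dice", ε = 1e-5),
levels combined with weights halving per coarser level and normalized to
sum to one. Targets are downsampled to coarser levels by nearest
neighbour. The optimizer is SGD with Nesterov momentum under a
polynomial learning-rate decay `lr0 · (1 − step/total)^0.9`, `lr0 = 0.01`.

**Momentum at desk scale.** The customary momentum of 0.99 assumes
schedules of hundreds of thousands of steps; its velocity timescale,
`1/(1−m)` = 100 steps, consumes a large share of a 600-step desk
schedule before the optimizer reaches full effective speed. The desk
presets therefore run momentum 0.9, whose 10-step timescale matches the
short schedule; 0.99 remains the `stage_config()` default for
full-scale settings, and both are plain configuration fields.

**Network width at desk scale.** Very narrow networks occasionally
collapse to the all-background solution within a short schedule (the
soft-Dice dead-class regime: once a class's softmax mass vanishes, its
Dice gradient does too, and cross-entropy alone escapes only slowly).
Width buys optimization reliability at quadratic compute cost; the
desk-study preset uses 3 base channels as the narrowest width that
trains dependably across seeds at 600 steps.

## Patch sampling

The default sampler reproduces foreground oversampling: with probability
`fg_fraction` (default 0.33) the patch is centred on a uniformly chosen
reference foreground voxel and clipped to bounds, otherwise the origin is
uniform. The mask-guided sampler interprets "samples drawn from within
the mask" as *centre-on-mask-voxel* (then clipped), the reading that
makes patches likely to contain large lesion portions and mirrors how
foreground oversampling itself is implemented; mere patch-overlaps-mask
would admit patches that barely graze the prior. GTVp and GTVn are merged
for sampling eligibility. By default no dilation margin is added to the
prior before sampling (`margin = 0`; a voxel radius can be supplied when
a stale prior should be trusted less). An empty prior cannot abort
training: the affected case falls back to the default sampler with a
warning.

Masked *inference* eligibility is deliberately the looser
patch-intersects-prior rule: the prior at inference time is a stale
earlier-timepoint mask, and the residual lesion may sit near its edge, so
discarding patches whose centre misses the prior would risk cropping true
tumour. The asymmetry with the training sampler is intentional and
documented here.

## Synthetic phantoms

`make_case()` builds paired timepoints on a 48×48×32 grid at 1×1×1.2 mm:
one GTVp ellipsoid (mean radius 6-10 mm) and two GTVn ellipsoids
(3-5 mm), non-overlapping, over a background of a smooth low-frequency
field (trilinearly upsampled coarse Gaussian noise, emulating bias-field
variation) plus white Gaussian noise (σ = 0.3). Lesions add a contrast of
3 — ten times the noise floor, so a small network can learn the task in
minutes, which is the point of the phantom: it tests mechanisms, not
clinical difficulty. The mid timepoint multiplies every lesion radius by
`shrink_factor` (default 0.6, i.e. ~78% volume loss, a plausible
mid-treatment response) around unchanged centres. The "registered" prior
carried by the mid record is the pre image and reference translated
rigidly by a random jitter of magnitude ≤ `prior_jitter_mm` (default
2 mm), truncated to whole voxels so the bound is never exceeded; no
rotation or elastic residual is simulated. Ellipsoids admit an analytic
voxelization oracle, which is how the shrinkage factor is verified in the
tests.

What the phantom does *not* emulate: anatomy, Rician noise, registration
failure modes, multi-observer label noise, or class imbalance as extreme
as clinical data. Passing the mechanism tests therefore says the
*pipeline machinery* behaves as specified — not that clinical-grade
accuracy is achieved.

## Evaluation

`dsc()` is the per-patient Dice per class; `agg_dsc()` pools
intersections and mask sizes across patients before forming the ratio,
the definition that makes a single all-miss case shift the score
continuously instead of contributing a hard zero. (The two-case example
in the tests — pooled 0.5 against per-case mean 0.33 — is that robustness
made concrete.) When a class is absent from both prediction and
reference, the per-case DSC is defined as 1 and flagged; flagged cases
are excluded from significance pairing. Configurations are compared with
a two-sided paired Wilcoxon signed-rank test at α = 0.05 on per-case mean
DSC, zero differences dropped, exact by enumeration of all 2^n sign
assignments for n ≤ 15 (valid under ties, which grid-valued Dice scores
produce readily) and a tie-corrected normal approximation beyond. Report
tables print scores ×100 with two decimals and star configurations that
differ significantly from the best.

## Desk-scale study design

The shipped comparative experiment (`preset = "desk-study"`, also what
`scripts/acceptance.R` runs) uses a 20-case phantom cohort split 16/4,
32³ patches, batch 2, and 600 optimizer steps (15 epochs × 40 steps) per
model — sizes chosen so one configuration trains in about a minute on a
single CPU. Predictions use the best-validation checkpoint, matching
validation-based model selection (the mid-treatment setting is precisely
where best checkpoints tend to beat fully decayed final ones). Under
these conditions the staged configuration (prior channels + mask-guided
sampling + mask-restricted inference) is expected to outperform an
image-only baseline trained from scratch, which at 600 steps often barely
leaves the all-background regime — the desk-scale analogue of the
full-scale ordering.

A single-patch overfit run is the learning sanity check: the
desk-default network driven for 200 steps on one fixed foreground-centred
patch of a single-lesion phantom must reach foreground soft-Dice ≥ 0.95.
The harness uses a learning rate of 0.1 — an order of magnitude above the
cohort-training rate, as is appropriate when fitting one fixed example —
because at the cohort rate some initializations remain stuck in the
soft-Dice dead-class regime (a class whose softmax mass has collapsed
receives vanishing Dice gradient) within the step budget.

The island artifact is reproduced as a testable behaviour: a model
trained only on mask-guided patches (foreground always present) and then
run with *unrestricted* sliding windows over a phantom containing a
bright decoy blob outside the prior emits connected components disjoint
from the prior; `count_disjoint_components()` detects them, and
mask-restricted inference on the same model cannot label anything outside
its patch coverage. Island *removal* is intentionally absent — it is an
observed failure mode, not something to be postprocessed away.

## Numerical and degenerate-input choices

* Instance-norm ε = 1e-5; z-score normalization guards `sd < 1e-8` by
  dividing by 1, so constant volumes normalize to zero.
* Softmax is computed with per-voxel max subtraction; blended
  probabilities sum to 1 within 1e-6 per covered voxel.
* Argmax ties in the label map resolve to the lowest class index.
* The Gaussian window (σ = patch/8 per axis, floor-clamped, max 1) and
  50% overlap are the conventional sliding-window settings.
* Masked and unmasked inference agree *exactly* on every roi voxel — any
  patch covering an roi voxel intersects the roi, so both plans blend the
  identical patch set there. Outside the roi (but inside masked
  coverage) the two modes may differ, because the unmasked plan blends
  additional patches; the tests assert the guaranteed region only.
* Patch starts are spaced `ceil(patch·(1−overlap))` with the last start
  clipped to the boundary; volumes smaller than the patch are zero-padded
  and cropped back.
* All randomness flows through R's RNG; every entry point takes or
  derives a seed, and repeated runs on one CPU are bit-identical.
* The NIfTI loader accepts only axis-aligned affines: phantoms and
  challenge-style data are axis-aligned, and silently reinterpreting a
  rotated grid would corrupt geometry. Grids are compared with a 1e-6
  tolerance on spacing and origin.

## Known limitations

The augmentation set is reduced (flips, in-plane 90° rotations, global
intensity scaling, additive noise); elastic deformation, simulated
low-resolution and gamma transforms are out of scope. Stage-1 training
priors for the two-stage pre-treatment pipelines come from in-sample
inference with the stage-1 model itself — a single split, no
cross-validated ensembling. Hausdorff or surface distances are not
computed. The resampling planner of the full-scale framework is not
re-derived; phantoms are generated at target spacing directly. Whether an
absent class should be excluded rather than scored 1 in pooled Dice is a
convention choice; it is flagged in the output so either analysis is
possible.
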