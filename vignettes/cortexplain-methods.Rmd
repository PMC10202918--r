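---
title: "Methods: explainable CNN classification of cortical current-density volumes"
author: "cortexplain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable CNN classification of cortical current-density volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Event-related EEG can be mapped to cortical current-density time series by
linear inverse modeling, giving a spatiotemporal image of cortical activity
per trial. When two groups (for example patients with a prodromal
neurodegenerative disorder and matched controls) differ in localized,
time-locked cortical processing, a 3d convolutional classifier trained on
single-trial spatiotemporal volumes can both *discriminate* the groups and
— through attribution methods — *localize* which cortical regions and
latencies carry the difference, without pre-selecting a time window of
interest.

`cortexplain` implements that full chain as reusable, tested components:

1. a synthetic-cohort generator that plants a known spatiotemporal group
   effect in trial-wise source activity on a spherical surface;
2. an optional forward/inverse stage (synthetic lead field, weighted
   minimum-norm estimation, wMNE);
3. conversion of source time series into standardized Mollweide-projected
   image volumes;
4. a 2d/3d CNN with a leave-one-subject-out (LOSO) pretraining and
   fine-tuning protocol;
5. the explainability mathematics: layer-wise relevance propagation (LRP),
   GradCAM, guided backpropagation (GBP) and guided GradCAM (GGCAM);
6. heatmap aggregation, ROI time courses, localization scoring and the
   cohort statistics (pooled-SD Cohen's d, two-sample t tests from summary
   statistics, Fisher's exact test, one-tailed Pearson correlations).

Because the clinical recordings behind the motivating study are not
available, the package's verification strategy is *recovery of a planted
effect*: every end-to-end claim is tested against simulated ground truth.

# The synthetic cohort

Each trial is a vertices-by-time matrix of current density on a unit-sphere
surface (Fibonacci lattice, regions = spherical Voronoi cells; 2,000
vertices at desk scale, 15,002 supported), sampled at 400 Hz over an epoch
from -1200 to 800 ms around target onset:

* **Background noise** — spatially correlated Gaussian noise: white noise
  smoothed by a k-nearest-neighbour Gaussian operator whose rows are scaled
  to unit L2 norm, so the per-vertex SD equals `noiseSd` exactly (default
  0.5 a.u.). Temporal coloring is deliberately omitted: white noise keeps
  every closed-form oracle in the tests exact, and the 30 Hz lowpass applied
  during preprocessing imposes the dominant temporal correlation anyway.
* **Evoked components** — Gaussian temporal envelopes confined to a region.
  The defaults mirror the N1/P300 framing of visuospatial attention tasks:
  an "occipital" component at 200 ms and a "parietal" component at 325 ms
  (SD 25 ms, amplitude 1 a.u. each).
* **Planted effect** — in the patient group the amplitude of every
  component in `roiRegion` is multiplied by `delta` in [0, 1]; the default
  experiment uses `delta = 0.5` in the 300-350 ms window, i.e. attenuated
  parietal attention-related activity. `delta = 1` is the null condition.
* **Subject and trial variability** — a per-subject amplitude factor
  `aS ~ N(1, 0.2^2)` (the recorded ground truth used for correlation
  analyses) and a per-trial multiplicative jitter with SD 0.1.

The amplitude-to-noise defaults were chosen so that a single trial's ROI
feature separates the groups at roughly the level the motivating study
reports for its trained classifiers (95-100% test accuracy): simple
thresholding of the 300-350 ms ROI mean reaches the mid-90% range at desk
scale. Real single-trial EEG is harsher in many respects the generator does
not emulate — artifacts, non-stationary noise, inter-subject anatomical
variability, volume-conduction leakage — so green tests here demonstrate
the *pipeline's* correctness and sensitivity, not clinical performance.

Cohorts are deterministic in the seed: every (subject, trial) pair has a
derived seed, and trials are materialized lazily (a fully materialized
desk-scale cohort would occupy ~4 GB). Clinical scores are generated as
`score = mean + sd * (rho * zA + sqrt(1 - rho^2) * e)` with `zA` the
population-standardized `aS`, so the population correlation with the
planted amplitude is exactly `rho`.

## Preprocessing

Per trial and vertex: zero-phase (forward-backward) Butterworth lowpass
below 30 Hz (order 4 per pass; reflective padding and steady-state initial
conditions), then baseline correction by subtracting the mean over -200 to
0 ms. After baseline correction the baseline mean is exactly zero;
constants are annihilated. Only the cutoff is scientifically fixed; the
order is configurable.

# From sources to CNN inputs

Vertices are mapped to the plane by the Mollweide projection (equal-area,
2:1 ellipse). The auxiliary angle solves `2θ + sin 2θ = π sin(lat)` by
Newton iteration to 1e-12 with analytic handling of the poles; tests
compare against a bisection root-finder. Conventions (arbitrary but fixed):
longitude 0 at the anterior midline, occipital pole at ±π, grid row 1 at
`y = +√2`, column 1 at `x = -2√2`.

Interpolation onto the `gridSize x gridSize` grid (120 at full scale, 40
for the desk-scale classifier) uses inverse-squared-distance weighting of
the 4 nearest projected vertices, precompiled into a sparse matrix; weights
sum to one so constants are reproduced exactly, and off-ellipse pixels are
zero. With ~2,000 or 15,002 near-uniform vertices the nearest neighbours
are local, so this behaves like local linear interpolation without
requiring a triangulation.

3d volumes average the current density in 16 contiguous half-open 50 ms
bins covering 0-800 ms (a sample at exactly 800 ms is excluded), project
each bin, and z-score each frame over the in-ellipse pixels (mean 0, SD 1;
a constant frame maps to zeros). Per-frame standardization is the literal
reading of "images were converted to z-scores" and keeps frames comparable
across the volume; per-volume or per-dataset scoping would couple frames
through global amplitude, which the per-subject amplitude factor would then
leak into. 2d images are the single standardized 200-350 ms average.

# The inverse stage

The optional wMNE stage implements
`K = W Gᵀ (G W Gᵀ + λI)⁻¹` with depth weights `W_jj = ‖g_j‖^(-2p)`,
`p = 0.5` by default, and `λ = trace(GWGᵀ)/(channels · SNR²)` with SNR 3
when unspecified — conventional choices, since the motivating analysis
delegates them to its source-imaging toolbox. The synthetic lead field uses
smooth angular-decay sensitivity profiles. The pipeline bypasses this stage
by default (synthetic sources are fed to volumization directly); enabling
it routes every trial through `K (G E)`.

# The classifier

Three blocks of convolution (3×3×3 in 3d, 3×3 in 2d; stride 1, same
padding), batch normalization, ReLU and max pooling (first pool 2×2×1,
then 2×2×2 in 3d; all 2×2 in 2d), then two fully connected ReLU layers and
a single sigmoid output. Full-scale channels are 64/128/256 with
fully-connected width 512 on 120×120×16 inputs; the desk-scale variant used
by tests is 8/16/32 with width 32 on 40×40×16 — the same topology at
tractable size. Padding is not stated in the motivating description and its
printed parameter counts cannot be reconciled with any simple padding
variant, so same-padding was adopted and parameter counts are treated as
non-normative (the package reports its own).

Training: Kaiming initialization, Adam on binary cross-entropy (computed
from logits for stability), weight decay 1e-5, mini-batches of 128 at full
scale (16 at desk scale). The learning rate comes from an exponential
range test between 1e-8 and 1: one Adam step per rate over successive
mini-batches, with the loss measured on a fixed probe batch so the curve
reflects parameter movement rather than batch-composition noise. The
chosen rate sits one order of magnitude below the curve's divergence
point — divergence is the one large, unambiguous feature of a short
sweep, whereas the curve's shallow minima and slopes are noise-prone at
desk scale; when nothing diverges, the loss-minimizing rate is used if it
at least undercuts the trivial constant-predictor loss `log 2`, and
otherwise the method falls back to 1e-3 with a warning. Early stopping monitors validation accuracy with patience 10
(100 epochs max) at full scale; desk-scale runs use 20 epochs with
patience 5 and additionally stop when validation accuracy reaches 1.0,
which cannot improve further — with the planted `delta = 0.5` effect this
typically ends pretraining within a handful of epochs.

## Transfer-learning protocol

For each held-out patient (SP):

1. **Pretraining** — all volumes of the SP are excluded; classes are
   randomly undersampled to 1:1 at trial level; the rest splits 90/10 into
   training/validation; the best-validation model is kept.
2. **Fine-tuning** — the SP's volumes plus *reserve controls* (a seeded 20%
   of control subjects withheld from every pretraining) are undersampled,
   split 80/20; only fully connected and output layers are updated
   (convolution and batch-normalization parameters stay bit-identical,
   which tests assert by fingerprint); learning rate and weight decay are
   the pretraining values divided by 10. Early stopping here monitors
   training accuracy, because the 20% split is reserved for evaluation.
3. **Evaluation** — accuracy, precision, recall (threshold 0.5) and
   rank-statistic AUROC on the 20% split; undefined-safe rules: precision
   and recall are NA when their denominator is empty, AUROC is NA for
   single-class label sets.

Folds iterate over patient subjects, matching the protocol's asymmetry
(fine-tuning pools the held-out subject with reserve *controls*; a control
SP would make that set single-class). The range test runs once on the first
fold and the rate is reused across folds.

# Explainability

All methods operate on the trained model in evaluation mode and attribute
the *pre-sigmoid logit* (standard LRP practice; the sigmoid is monotone, so
the probability would only rescale relevance).

* **LRP** — batch normalization is first folded into the adjacent
  convolution (running statistics define an affine map), so propagation
  sees plain affine layers. Fully connected layers use LRP-0
  (`z_jk = a_j w_jk`), convolutions LRP-gamma
  (`z_jk = a_j (w_jk + γ max(w_jk, 0))`, γ = 0.25 by default — the rule's
  source describes the family without fixing γ). Denominators are
  stabilized by ε = 1e-9 signed; bias contributions are absorbed by the
  denominator and not redistributed, so conservation of total relevance is
  exact only on bias-free networks, and that is how the conservation test
  is stated. Max pooling routes relevance to the winning input
  (winner-take-all); ReLU passes relevance through.
* **GradCAM** — per-feature-map weights are the spatial means of the
  logit's gradient at a convolutional block output (default: the last
  block's ReLU output); the map is the ReLU of the weighted activation sum,
  at that layer's resolution. The weighted-sum reading of the importance
  formula is the standard one and is adopted here.
* **GBP** — the input gradient where each ReLU's backward signal is zeroed
  unless both the forward activation and the incoming gradient are
  positive.
* **GGCAM** — the GradCAM map, upsampled to input resolution by separable
  linear interpolation, multiplied elementwise with the GBP gradient. The
  product is nonnegative wherever the GBP gradient is.

Every rule is tested against literal per-node re-implementations on
networks small enough to enumerate (convolutions materialized as explicit
affine maps), and the whole backward engine against central differences.

# Analysis

Heatmaps are averaged over (group, correctness) cells at trial level — the
literal reading of "averaging the correctly classified test data"; empty
cells are reported missing, never as zeros. ROI masks in grid space are the
projected footprints of surface regions (each pixel takes its nearest
projected vertex's region), avoiding any anatomical atlas. ROI time courses
average the aggregate per 50 ms bin; the peak window is the argmax bin with
ties broken to the earliest bin. Localization is quantified as the
rank-based AUC of absolute relevance against the planted
region-and-window mask: 1 is perfect concentration, 0.5 chance.

Cohort statistics use the (n-1)-weighted pooled SD for Cohen's d (group 1 =
control, group 2 = patient, so negative d means lower patient scores),
pooled-variance two-sample t tests from summary statistics, Fisher's exact
test (two-sided point-probability rule), and one-tailed Pearson
correlations via the t transform. On published group summaries these
reproduce the printed effect sizes at two decimals, with two documented
exceptions traceable to the inputs being rounded at two decimals.

# Problem sizes and reproducibility

The test suite and the acceptance script run the full protocol at desk
scale: 10 subjects per group × 40 trials on 2,000 vertices, 40×40×16
volumes, the 8/16/32 classifier — two LOSO folds in the tests (one in the
acceptance script, which also caps training at 15 epochs with patience 4)
— plus a one-fold null study (delta = 1, 6 per group × 25 trials) as the
no-effect control.
These sizes are the package's standing desk-scale configuration; the
full-scale configuration (49 + 49 subjects, 500 trials, 15,002 vertices,
120×120×16, 64/128/256) is expressible through the same interfaces. All
randomness flows from named seeds; cohorts, training and reports are
reproducible bit-for-bit from configuration plus seed.

Cohorts, volumes and heatmaps serialize as RDS containers with CSV
metadata tables; 3d heatmaps can additionally be exported to NIfTI via
`writeHeatmapNifti()` when RNifti is available.

# Known limitations

* **Temporal resolution of LRP peak windows.** The second and third pooling
  stages merge the 16 50 ms bins in pairs, so the deepest convolution sees
  100–200 ms depth resolution, and LRP's winner-take-all routing through max
  pooling attributes relevance to whichever bin of a merged pair held the
  per-sample maximum. In the planted-effect study the LRP aggregate
  localizes the effect well in space-time overall (rank-AUC above 0.8), but
  its ROI *peak bin* can land on the 350–400 ms neighbour of the planted
  300–350 ms bin — or, by signed-mean cancellation, on a late noise bin —
  whereas guided GradCAM, which upsamples its coarse map smoothly, recovers
  the planted bin exactly. Peak-window readings from LRP should therefore
  be interpreted at the network's pooled temporal resolution, not the bin
  width.
* **Saliency under the null is not chance.** With no planted effect
  (`delta = 1`) both groups still carry the evoked components, and
  activation-dependent attribution — GradCAM in particular — concentrates
  on stimulus-evoked structure regardless of class evidence; a fine-tuned
  null model can additionally exploit per-subject amplitude differences.
  The null pipeline's localization AUC against the would-be planted mask
  therefore sits systematically above 0.5 (the test suite leaves this
  documented expectation failing rather than widening its band). Heatmaps
  from this family of methods should always be read against a null-model
  control, not assumed to be flat in the absence of an effect — echoing
  the inconsistency that incorrectly-classified-sample heatmaps show.
* The generator's noise is temporally white and spatially stationary; real
  source-space noise has 1/f structure, artifacts and leakage from the
  inverse operator.
* The synthetic lead field is a smooth angular-decay model, not a
  boundary-element head model; the inverse stage therefore exercises the
  estimator's algebra, not conduction realism.
* Sphere regions are Voronoi cells, not anatomical parcels; "occipital"
  and "parietal" are configurable labels, not atlas structures.
* Fine-tuning uses the held-out subject's labels, as in the motivating
  protocol; it evaluates feasibility of subject-specific adaptation, not
  label-free diagnosis.
* The engine is CPU-oriented R/C++; it is sized for desk-scale experiments,
  not full-scale training.
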