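# cortexplain

Explainable convolutional classification of spatiotemporal cortical
current-density volumes.

## What this is for

Event-related EEG can be transformed into cortical current-density time
series by linear inverse modeling. When a patient group differs from
controls in localized, time-locked cortical processing — the motivating
case is attenuated parietal/occipital attention-related activity in REM
sleep behavior disorder — a 3d convolutional network trained on
single-trial spatiotemporal volumes can discriminate the groups, and
attribution methods can then localize *where* and *when* the
discriminative activity occurs, without pre-selecting a time window.

`cortexplain` implements that analysis chain for methods researchers who
want to study, extend or stress-test it with full control over ground
truth:

* a **synthetic cohort generator**: two groups of subjects with trial-wise
  source activity on a spherical cortical surface, Gaussian-envelope
  evoked components (occipital ~200 ms, parietal ~325 ms), spatially
  correlated background noise, and a *planted* group effect — the patient
  group's parietal component in 300–350 ms is attenuated by a known factor
  `delta`;
* **wMNE inverse stage** (optional): `K = W Gᵀ (G W Gᵀ + λI)⁻¹` with depth
  weights `W_jj = ‖g_j‖^(−2p)`;
* **volumization**: zero-phase 30 Hz lowpass, −200–0 ms baseline
  correction, Mollweide projection of the sphere onto a 120×120 grid,
  per-frame z-scoring, and 16 half-open 50 ms bins over 0–800 ms →
  120×120×16 input volumes (2d mode: one 200–350 ms frame);
* a **2d/3d CNN** (three conv–batchnorm–ReLU–maxpool blocks, two fully
  connected layers, sigmoid output) with the **leave-one-subject-out
  transfer-learning protocol**: pretrain on all subjects but one with 1:1
  undersampling and a 90/10 split, learning rate from a range test, early
  stopping on validation accuracy; then fine-tune only the fully connected
  layers (rates ÷ 10) on the held-out subject plus reserve controls, and
  evaluate on the held-out 20%;
* **explainability**: layer-wise relevance propagation
  `R_j = Σ_k z_jk / (Σ_j z_jk) · R_k` with LRP-0 on dense layers and
  LRP-gamma on convolutions, GradCAM
  `L = ReLU(Σ_n w_n A^n)`, `w_n = mean ∂y/∂A^n`, guided backpropagation
  (ReLU-gated gradients), and guided GradCAM (their product at input
  resolution);
* **analysis**: heatmap aggregation over correctly/incorrectly classified
  samples, ROI time courses with peak windows, a rank-AUC localization
  score against the planted ground truth, and the cohort statistics
  (pooled-SD Cohen's d, two-sample t tests from summary statistics,
  Fisher's exact test, one-tailed Pearson correlations).

Because the clinical recordings behind the motivating study are not
publicly available, everything end-to-end is validated by *recovering the
planted effect* from simulation. See the methods vignette
(`vignettes/cortexplain-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(cortexplain)

## a small two-group cohort with a planted 50% parietal attenuation
surf <- makeSphereSurface(500, 8, seed = 1)
coh  <- simulateCohort(surf, effectSpec(delta = 0.5), nPerGroup = 4,
                       nTrials = 10, fsHz = 100, seed = 7)
coh  <- simulateClinicalScores(coh, rhoTarget = 0.26, seed = 8)
coh
#> SourceCohort: 4 control + 4 patient; 10 trials/subject, 500 vertices,
#>   100 Hz, -1200..800 ms, seed 7

## preprocess + project into CNN input volumes
map  <- mollweideMap(surf, gridSize = 24)
vols <- cohortVolumes(coh, map)
vols
#> VolumeSet (3d): 80 samples of 24x24x16 (40 control + 40 patient)

## the planted group difference is visible in the ROI current density
cd  <- roiMeanCurrentDensity(coh, 2, c(300, 350))
tapply(cd, cohortMeta(coh)$group, mean)
#>   control   patient
#> 0.8401135 0.4199211

## effect sizes from published group summaries (control vs patient, n = 49)
cohenD(4.94, 3.36, 49, 47.53, 19.46, 49)    # RBD questionnaire
#> [1] 3.050007
cohenD(28.88, 1.29, 49, 27.27, 2.14, 49)    # MMSE
#> [1] -0.9112129
summaryTTest(66.00, 6.37, 49, 65.96, 5.94, 49)$p   # age
#> [1] 0.974421
fisherExactTest(matrix(c(33, 29, 16, 20), 2))      # sex
#> [1] 0.5299101
```

The first block builds a cohort whose patient group has the parietal
300–350 ms component halved; `roiMeanCurrentDensity` shows the planted
attenuation (patient mean ≈ half the control mean, up to noise and
per-subject amplitude variability). The effect-size block reproduces the
published demographics table's Cohen's d and test p values from its
printed means and SDs.

The full protocol — LOSO training, heatmaps, localization — runs through
`runExperiment()` (see `defaultPipelineConfig()`), or stage by stage via
`runLoso()`, `lrp()` / `guidedGradCam()`, `aggregateHeatmaps()` and
`localizationScore()`. A command-line wrapper is in
`inst/scripts/cortexplain`.

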