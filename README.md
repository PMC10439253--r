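# dlrs — deep-learning radiomics scoring of the tumor microenvironment from CT

`dlrs` predicts a binary tumor-microenvironment (TME) class — the
immune-hot versus immune-cold contexture that normally requires
immunohistochemistry on resected tissue — directly from a contrast-enhanced
CT scan and a tumor delineation. It is aimed at imaging researchers who
want a fully inspectable, CPU-only reference implementation of a fused
hand-crafted-radiomics + convolutional-network classifier, together with a
synthetic phantom generator so every stage can be exercised and verified
without access to protected patient images.

## The model

For each case the axial slice with the largest tumor cross-section is
analysed after resampling to a common spacing (default 0.75 × 0.75 ×
2.5 mm, trilinear) and window normalization to \[−150, 150\] HU:

* **Radiomics branch.** A fixed bank of 361 features: 9 two-dimensional
  shape features computed once, plus, for each gray-level discretization
  *N*<sub>bins</sub> ∈ {8, 16, 32, 64}, 18 first-order statistics and the
  four classical texture families — 24 GLCM, 16 GLRLM, 16 GLSZM and
  14 GLDM features (IBSI definitions, distance-1 pairs in four directions
  with direction averaging, 8-connected zones, exact-equality dependence).
  Features are z-scored with statistics fitted on the training split only.
* **Image branch.** A three-channel 64 × 64 input (full CT crop, masked
  crop, binary mask) feeds a multi-resolution convolutional backbone with
  a high-resolution and a half-resolution stream exchanging information
  after every stage; a squeeze-and-excitation gate
  (global average pool → bottleneck MLP → sigmoid channel weights)
  terminates every branch.
* **Fusion head.** The pooled image embedding is concatenated with a dense
  embedding of the standardized radiomics vector and mapped through one
  hidden layer to a single sigmoid probability — the deep-learning
  radiomics score (DLRS).

Training minimises the focal loss
FL(p<sub>t</sub>) = −α (1 − p<sub>t</sub>)<sup>γ</sup> log p<sub>t</sub>
with α = 1, γ = 2 (p<sub>t</sub> is the predicted probability of the true
class), using Adam at batch size 16, learning rate 10⁻³ halved every
10 epochs, with random left/right and anterior/posterior reflections and
rotations in (−30°, +30°). The operating threshold is the Youden-index
maximiser (J = sensitivity + specificity − 1) on the training cohort;
evaluation covers ROC/AUC with stratified bootstrap confidence intervals,
confusion-matrix metrics, calibration curves and decision-curve analysis,
and Guided Grad-CAM saliency maps show which image regions drive a
prediction. The network's forward and backward passes are written in
plain R on top of BLAS matrix products and are verified against
finite-difference gradients in the test suite.

## Worked example

Phantom cohorts stand in for CT data: soft-tissue-range volumes with one
ellipsoidal tumor each, whose intratumoral texture statistics and mean
attenuation carry the class signal.

```r
library(dlrs)

coh <- generate_cohort(phantom_spec(), n = 120, seed = 7)
pre <- lapply(coh, function(cs)
  preprocess_case(cs$volume, cs$mask, case_id = cs$provenance$case_id))
features <- radiomics_table(pre)          # 120 x 361 feature table
labels <- vapply(coh, `[[`, 0L, "label")

train <- 1:90; test <- 91:120
fit <- hrradnet(lapply(pre[train], `[[`, "input"),
                features[train, ], labels[train],
                control = train_control(n_epochs = 10), seed = 1)
print(fit)
#> HR-Rad-Net fit
#>   90 cases (72 train / 18 validation), 10 epochs, seed 1
#> HR-Rad-Net model: 2 stages, width 8, with radiomics, with SE, 41556 parameters
#>   best validation AUC 1.000 at epoch 1

scores <- predict(fit, lapply(pre[test], `[[`, "input"), features[test, ])
cut <- youden_cutoff(fitted(fit), labels[train])
print(cut)
#> threshold 0.5258: sensitivity 1.000, specificity 1.000, Youden J 1.000

report <- eval_report(scores, labels[test], threshold = cut$threshold,
                      n_boot = 500, seed = 1)
print(report)
#> Diagnostic evaluation on 30 cases (prevalence 0.47)
#>   AUC 0.982 (95% CI 0.933-1.000)
#>   cutoff 0.526: sensitivity 1.000, specificity 0.938, accuracy 0.967
#>   confusion: TP 14  FP 1  TN 15  FN 0
```

The fit separates held-out phantoms almost perfectly (AUC 0.98) because
the generator plants a strong, recoverable texture difference between the
classes; the threshold printed by `youden_cutoff()` is the training-cohort
operating point that the test-cohort report then applies. `grad_cam(fit,
pre[[91]]$input, features[91, ])` returns the saliency map for one case,
and `run_pipeline(run_config("out"))` executes the whole
simulate → preprocess → extract → train → predict → evaluate → explain
chain with provenance hashes. A thin command-line wrapper lives at
`inst/cli/dlrs.R`.

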