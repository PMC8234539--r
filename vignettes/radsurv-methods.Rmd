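---
title: "Deep-radiomic survival modelling of biochemical recurrence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-radiomic survival modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsurv)
```

## The problem

Biochemical recurrence (BCR) after radical prostatectomy — two consecutive
PSA readings above 0.2 ng/mL — marks relapse long before clinical
progression. Clinical point systems (CAPRA, CAPRA-S, NCCN risk groups,
Gleason grade groups) stratify patients coarsely and leave the intermediate
group with ambiguous guidance. `radsurv` implements an image-driven
alternative: quantitative (radiomic) features are extracted from the
lesion-masked T2-weighted MRI volume, screened by univariate concordance
against BCR-free survival, and fed to a deep survival network trained on the
Cox partial likelihood. Its scalar output — the deep-radiomic signature for
BCR, **DRS-BCR** — ranks patients by BCR hazard and is evaluated with the
standard survival-analysis battery against the clinical systems.

Because the motivating patient cohorts are not public, the package ships a
synthetic-cohort generator whose phantoms carry a *known* survival signal.
Every downstream stage is therefore testable end to end, with ground truth
available for recovery experiments.

## The model

For patient $i$ with feature vector $x_i$, the network produces risk
$r_i = f_\theta(x_i)$ and is trained full-batch by minimizing the negative
log Cox partial likelihood (Breslow ties),

$$\ell(\theta) = -\sum_{i:\,\delta_i=1}\Big[ r_i -
  \log \!\!\sum_{j:\,t_j \ge t_i}\!\! e^{r_j} \Big],$$

optionally plus an L1 activity penalty on the bottleneck code. The
architecture is: input $\to$ *dense box* (three 48-unit layers, each seeing
the raw input concatenated with all previous layer outputs, DenseNet-style)
$\to$ *auto-coding box* (48–48–24 bottleneck, "sparse features") $\to$
linear risk head. The published description fixes only the layer widths;
everything else is a documented choice here:

| parameter | default | rationale |
|---|---|---|
| wiring | sequential, input → dense box → auto-coding box → head | minimal reading of the description |
| activation | SELU | self-normalizing; robust at these widths without batch norm |
| dropout | 0.2 on hidden layers (never the code, never at inference) | standard regularization |
| sparsity | L1 activity penalty $10^{-4}$ on the 24-unit code | weight 0 gives a plain bottleneck; no reconstruction loss by default |
| weight decay | L2 on weight matrices, default 0 (the recovery protocol uses $10^{-3}$) | standard for Cox-loss networks on small feature-rich cohorts |
| optimizer | Adam, lr $10^{-3}$, full batch | cohorts are hundreds of rows |
| early stop | patience 20 on validation partial likelihood, best weights restored | standard |
| validation split | 20%, event-stratified, seeded | |

One integer seeds the split, the initialization and the dropout streams, so
training is bit-reproducible. Gradients are hand-derived and verified
against central finite differences in the test suite.

## Radiomic features

Volumes are z-score normalized (population SD, whole volume) before
extraction. The registry holds 295 named features:

* **first-order** (18) and **GLCM texture** (6) on the original image, on
  Laplacian-of-Gaussian filtered images at $\sigma \in \{1,2,3\}$ mm, and on
  the 8 sub-bands of a one-level 3D coiflet-1 wavelet decomposition
  ($18\cdot12 + 6\cdot12 = 288$);
* **shape** (7) from the mask alone.

Choices where the published pipeline is silent: intensities are discretized
to a fixed 32 gray levels inside the ROI (robust for z-normalized
intensities); GLCMs use distance 1, the 13 unique 3D directions, symmetric
accumulation, matrices normalized then averaged before feature computation;
the wavelet transform is decimated with periodic extension (orthogonal, so
sub-band energies sum to the input energy — a test asserts Parseval), and
the mask is any-pooled to the half-resolution grid; the LoG response is
scale-normalized ($\sigma^2 \nabla^2 G$), which makes the response maximal
near the blob scale. Surface area uses the co-area formula (integral of the
gradient magnitude of a slightly smoothed mask) rather than a mesh: it is
far less staircase-biased than face counting, and sphericity is clipped at
1 to absorb the residual few-percent bias on digitized balls. Parity with
any external tool's 702-feature registry is explicitly out of scope; the
registry is self-consistent and extensible.

Degenerate inputs return sentinels rather than NaN: zero-variance ROIs give
skewness/kurtosis/GLCM-correlation 0, uniformity 1; a GLCM with no valid
voxel pairs warns and returns its sentinel vector.

## Screening

Every feature is ranked by Harrell's C against BCR-free survival, with a
two-sided Wald p from a univariate Cox fit on the z-scored feature (the
convention behind "C-index and p-value" feature tables; the source is not
explicit about the test). The retention rule is applied literally:
C $> 0.5$ **and** $p < 0.05$; features with C $< 0.5$ are *not* rescued by
sign flipping, and no multiplicity correction is applied — deliberately
liberal, since the screen only feeds the network. Under a pure-noise
feature pool the expected retention is therefore the upper half of the
two-sided 5% rejections, about 2.5%.

## Evaluation statistics

All estimators are implemented directly (the `survival` package appears
only as an independent oracle in the tests):

* Harrell C with percentile-bootstrap CI (2000 replicates by default);
  paired model comparison via the jackknife variance of the difference of
  the two concordance U-statistics.
* Kaplan–Meier with Greenwood variance; multi-group log-rank.
* Time-dependent ROC at horizon $t^*$: cumulative cases / dynamic controls
  with inverse-probability-of-censoring weights from the censoring KM
  (which specific estimator the source used is unstated; real-data numbers
  may differ). The Youden cutoff maximizes sens + spec − 1.
* Absolute 3-year probabilities are built from a univariate Cox fit on the
  score with the Breslow baseline, $P = 1 - \exp(-\hat H_0(t^*) e^{\hat\beta s})$
  (the source never says how risk became probability); these feed the
  decile calibration curve with the Hosmer–Lemeshow $\chi^2_{g-2}$, the
  survival-adapted decision curve
  $NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$ (group KM at $t^*$ defines
  TP/FP), and the IPCW IDI / continuous NRI with bootstrap p-values.
* Cox fits use Newton–Raphson on the Breslow partial likelihood with
  step-halving, converging when the score max-norm drops below $10^{-8}$;
  separation is caught by the iteration cap and warned about.
* Wilcoxon signed-rank: exact distribution (rank-sum recursion) up to 25
  untied pairs, tie-corrected normal approximation beyond.

## The synthetic world

`cohort_config()` states the generator's world; the defaults emulate the
published cohort's margins:

* **Phantoms**: ellipsoidal lesion (radius 4–10 mm, mildly anisotropic) on
  a 32³ grid of 1 mm voxels; lesion intensity = patient mean
  $\mu_i \sim N(100, 10^2)$ plus a Gaussian field with patient correlation
  length $\ell_i$ (roughness; mapped through
  $\ell_i = 1.2\,e^{-0.35 z_i}$ voxels) scaled to SD 10; background
  $N(60, 5^2)$ white noise.
* **Risk**: $\eta_i$ is a linear combination of the z-scores of lesion mean
  (log-HR 0.7/SD), roughness (0.5), log-volume (0.3) and modest clinical
  effects (PSA 0.25, GG-RP 0.3, margin 0.15, SVI 0.15). All z-scores use
  theoretical moments, so effects are exactly per-SD.
* **Clinical covariates** are drawn from the published cohort's marginal
  proportions via a latent-Gaussian threshold model; a shared latent factor
  (loading 0.3 by default) couples them to the image signal. The source
  gives no joint image–clinical distribution, so this coupling is exposed
  as a parameter rather than asserted.
* **Survival**: Weibull proportional hazards (shape 1.3), with the scale
  calibrated *deterministically* (quadrature over the latent-risk
  distribution) so the marginal 3-year event fraction hits the configured
  target of 22%, matching the ~22–28% 3-year BCR rates reported; censoring
  is exponential (rate 1/120 per month) truncated at 96 months. Times are
  months throughout.

`strong_signal_config()` is the stated world for discrimination-recovery
experiments: all signal flows through the image (no clinical effects),
parameter spreads are wide (lesion mean SD 20, roughness slope 0.6, size
log-HR 0.6), the 3-year event target is 40% with administrative censoring
at 120 months, and the grid is 24³ for CPU-scale runs. These choices were
made while designing the generator so that the latent risk is in principle
recoverable from the extracted features (the generator's stated purpose);
they were then frozen. A green recovery test establishes that the network
can recover a *feature-expressible* proportional-hazards signal — it says
nothing about real MRI texture, scanner effects, segmentation noise, or
non-PH hazards, none of which the phantoms emulate.

## What the tests establish (and what they cannot)

The published headline numbers (C ≈ 0.8 across cohorts, 3-year AUC ≈ 0.84,
and the comparator table) were computed on private multicenter data and are
not reproducible here; no test asserts them. What the suite does assert:
in-paper arithmetic (event-rate and feature-family percentages) recomputed
exactly; estimator equivalence to brute-force oracles; frequentist
operating characteristics (type-I error, CI coverage, screening
sensitivity) of the statistics under their nulls; and end-to-end
discrimination recovery in the synthetic world. Comparator point tables
(CAPRA/CAPRA-S/NCCN) come from their original publications and are shipped
as editable JSON; the NCCN variant is the three-tier one, and clinical-T is
held at integer resolution (cT2a sub-stages are not modelled — records at
cT2 map to the low-risk criterion).

## Known limitations

Pure-R training is adequate for hundreds of patients but not thousands;
no GPU path. The wavelet mask is pooled, not re-delineated. No competing
risks, time-varying covariates, interval censoring, or transfer learning.
2D slice-wise extraction and GLRLM/GLSZM/NGTDM texture families are
extension points only.
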