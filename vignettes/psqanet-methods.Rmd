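---
title: "Methods: balanced multimodal prediction of gamma passing rates and dose-difference maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced multimodal PSQA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psqanet)
```

## The problem

Before an intensity-modulated radiotherapy (IMRT) plan is delivered, each
beam undergoes patient-specific quality assurance (PSQA): the planned dose
distribution is compared against a delivered/measured one. The coarse
clinical endpoint is the **Gamma Passing Rate (GPR)** — the percentage of
evaluated dose points whose gamma index is at most 1 under a dose-tolerance
/ distance-to-agreement pair such as 2%/2 mm. The fine endpoint is the
**dose-difference (DD) map**, measured minus planned dose at every pixel.

`psqanet` predicts both endpoints from two input modalities per beam:

* an **image modality** — the planned fluence map, min-max normalized to
  `[0, 1]`;
* a **tabular modality** — a 33-element vector of plan-complexity metrics
  describing the multi-leaf-collimator (MLC) aperture geometry
  (`complexity_metric_names()`).

Tabular complexity features are low-dimensional and quickly informative for
GPR, while the DD map depends on spatial detail only the image carries.
Trained jointly, the tabular branch converges first and suppresses image
feature learning ("modality imbalance"). The package quantifies each
modality's contribution with Shapley values and uses the imbalance to
re-weight the DD loss during training.

## Gamma engine

`gamma_map()` implements discrete-grid 2-D gamma analysis in absolute dose
mode with global normalization:

* the dose tolerance Δ and the low-dose threshold (default 10%) are
  percentages of the **reference** grid's global maximum;
* points at or below the threshold are excluded from both numerator and
  denominator;
* γ at a reference point is the minimum over compared points of
  √(dist²/δd² + dose-diff²/Δ²); a point passes when γ ≤ 1. The
  implementation adds a `1e-9` slack to the pass comparison because ratios
  that equal 1 in real arithmetic (e.g. a 3% dose offset at 3% tolerance)
  do not in floating point.

Conventions chosen where the protocol is silent: evaluation points live on
the **measured** grid (`gpr_targets(reference = "planned")` swaps roles);
no sub-pixel interpolation; the search is restricted to a radius of
`search_radius_factor * dist_tol` (default 3), visited in order of
increasing distance with an exact early-termination bound. `gamma_oracle()`
enumerates every compared point and is the ground truth for equivalence
tests; the radius-3 search matches it exactly on all tested simulator
pairs, and a factor at least the grid diagonal is provably identical.

GPR targets are always the ordered triple 1%/1 mm, 2%/2 mm, 2%/3 mm at the
10% threshold (`clinical_criteria()`). Relaxing tolerances can only lower
γ, so GPR(1/1) ≤ GPR(2/2) ≤ GPR(2/3) holds sample-wise.

## Synthetic PSQA simulator

No public PSQA dataset exists at this granularity, so the package ships a
generator whose samples exercise every stage:

* **Apertures** (`gen_aperture_sequence()`): a sliding-window sequence of
  left/right leaf edges sweeping the field, with site-dependent gap
  statistics (head-and-neck: mean 8 mm gaps, most modulated; chest: 20 mm;
  abdomen 13 mm; pelvis 16 mm) and a random active leaf band. Site mix
  defaults to the 19/138/31/22 cohort proportions, allocated by
  deterministic largest remainder.
* **Fluence** (`render_fluence()`): MU-weighted open-aperture exposure,
  min-max normalized. Smoothing is available but defaults to off so that
  aperture footprints are geometrically exact.
* **Complexity** (`compute_complexity_vector()`): simplified geometric
  analogues of the published metrics (aperture-area variability, leaf
  sequence variability, modulation complexity score, beam area, union
  aperture area, plan irregularity, plan modulation, circumference/area,
  closed-leaf score, mean asymmetry distance, small-aperture scores at
  2/5/10/15 mm, average leaf gap and its spread, total MU). The dual-layer
  MLC is emulated by computing each metric on the sequence itself
  ("distal") and on a deterministically jittered copy ("proximal") — a
  schema-preserving stand-in, not a transport model.
* **Delivery** (`simulate_delivery()`): measured =
  gain · shift(blur(planned)) + noise, clipped at zero. This family is a
  stand-in — the clinical protocol does not describe its measurement error
  modes — and is labelled as such.
* **Targets**: DD = measured − planned; GPR from the gamma engine.

### Modality-informativeness dials

`sim_config(rho_tab =, rho_img =)` controls what each modality can know:

* perturbation **severity** is `rho_tab · f(geometry) + (1 − rho_tab) · u`,
  with `f` a monotone map of the mean leaf gap and `u` uniform noise; the
  site-difficulty multiplier is likewise scaled by `rho_tab`. At
  `rho_tab = 0` the complexity vector is uncorrelated with GPR (tested:
  max |mean r| < 0.1 over 3 seeds at n = 500).
* `rho_img` scales a spatially structured error — edge softening
  `blur(planned) − planned` with a fixed 2.5 mm kernel — whose *pattern* is
  a deterministic function of the planned image. Its magnitude is
  normalized over the gamma-evaluated region so that sparse apertures are
  not systematically penalized (this keeps the `rho_tab = 0` decoupling
  honest), and tracks severity so GPR stays tabular-predictable.

Default amplitudes (gain 0.03, blur 0.30 mm, shift 0.08 mm, noise 0.0012,
structured 0.003) were calibrated once so the 2%/2 mm GPR distribution
populates all four clinical bins (<85, 85–90, 90–95, ≥95) with a realistic
bulk above 90%, and frozen. What a green test establishes is therefore
*internal consistency* of the pipeline on a plausible synthetic world — it
says nothing about clinical accuracy, detector physics, or the real
dataset's GPR distribution beyond bin occupancy.

## Network

Encoders: a four-stage strided 3×3 convolution stack (total stride 16,
`N_c` output channels, ReLU) for the image; a two-layer MLP for the
33-vector (standardized with training-split statistics), emitting a
`N_t·H_z·W_z` embedding with `N_t < N_c` enforced — the DD task is
image-dominant by construction. Any backbone with the same output shape is
admissible behind `encode_image()`'s contract.

**GPR fusion** (`fuse_gpr()`): global-average-pool the image features to an
`N_c` vector; pool the tabular embedding over its fold positions to an
`N_t` vector (`tab_pooling = "none"` projects the full vector instead);
project each to a scalar score; softmax the two scores into attention
weights α; output the α-weighted sum of the two linear projections into a
`d_f`-wide fused vector (default 512, matching the 3-output head). Forcing
α to (1,0), (0,1) or (0,0) yields the image-only, tabular-only and null
forwards used for attribution; `multi_subset_forward()` computes all four
predictions from one encoder pass, bit-identical to independent passes.

**GPR head** (`predict_gpr()`): ReLU → dropout (0.1, training only) →
affine `d_f → 3`, outputs in percent. The head bias is initialized to the
training-set mean GPR — standard regression practice, and necessary here
because MAE-with-Adam moves outputs by roughly the learning rate per step
and could not reach ~95% from zero in a short desk-scale run.

**DD fusion and decoder** (`fuse_ddp()`, `predict_ddp()`): the tabular
embedding is folded to `N_t` maps (channel-fastest, so fold∘flatten is the
identity) and concatenated before the image channels — the order is
arbitrary but fixed. The decoder is an initial 3×3 convolution followed by
four (bilinear ×2 upsample + 3×3 convolution) stages with a five-entry
channel schedule (full scale: 768/384/192/128/32; desk scale: slimmer) and
a final 1×1 convolution. Two deliberate deviations from a textbook stack:

* decoder activations are **leaky ReLU (slope 0.1)** — with hard ReLU the
  sign-based MAE gradient drives whole stages into the dead regime
  (observed as a permanently constant output and silently frozen DDP
  gradients);
* optional **U-Net skip connections** (`skips = TRUE`) concatenate encoder
  stages 3/2/1 onto the matching decoder resolutions. Off by default (the
  source architecture is described by its channel schedule alone), but
  without them a 4×4 latent cannot express edge-scale DD structure at all;
  the balancing experiment below enables them.

## Shapley balancing

After each epoch, the validation set is pushed through the four modality
subsets (one shared encoder pass, dropout off so the value function is a
deterministic function of the weights). The value of a subset is the
negative validation MAE of its GPR predictions over all three criteria
jointly; the empty subset is fixed at 0, since the null forward is a
sample-independent constant and only differences enter the attribution.
The two-modality Shapley decomposition

φ_img = ½[v({img}) − v(∅)] + ½[v({img,tab}) − v({tab})]

(and symmetrically φ_tab) is verified against an exact permutation-
enumeration oracle (`shapley_oracle()`, up to 8 players) for efficiency,
symmetry, dummy and additivity. The DD loss weight for the *next* epoch is

λ_DDP = 1 + max(φ_tab − φ_img, 0) · r/2,

with Modality Balance Factor `r` (default 16); λ starts at 1, equals 1
whenever the tabular modality does not dominate, and `r = 0` recovers the
unbalanced baseline through the same code path. The total loss is
`L_gpr + λ·L_ddp`, both MAE. Only this loss-weighting rule is implemented;
learning-rate modulation and gradient-normalization alternatives mentioned
in passing by the source material are out of scope.

Adam normalizes per-parameter step sizes, so λ acts almost entirely through
the **shared encoders** — which is precisely the modality-imbalance
mechanism: upweighting the image-sensitive DD task redirects encoder
learning toward spatial features that the tabular-dominated GPR objective
would otherwise starve.

## Training, splitting, evaluation

* `stratified_split()`: strata are GPR bin (<85, 85–90, 90–95, ≥95 on the
  2%/2 mm criterion by default) × lesion site; within each stratum samples
  are id-sorted, seed-shuffled, and allocated 7:1:2 by largest remainder
  with ties broken train > test > val. Deterministic and input-order
  invariant. Note the tie rule starves validation in very small strata —
  intentional, but worth knowing at toy scale.
* `fit()`: Adam (lr 5e-4 default), 30 epochs, batch 32, dropout 0.1 —
  the published protocol constants — with one master seed fanning out to
  initialization, shuffling and dropout; runs are bit-reproducible on a
  single CPU thread.
* `compute_regression_metrics()` (MAE/RMSE/R², R² may be negative and is
  undefined under zero target variance), `ssim_global()` (single
  global-statistics SSIM, C1 = (0.01L)², C2 = (0.03L)², population
  moments, no sliding window), and `stratified_report()` (GPR metrics per
  criterion stratified by that criterion's own ground truth; DD metrics
  stratified by the 2%/2 mm ground truth; R² for "All" only; DD MAE
  reported as % of the planned map's global maximum, raw units alongside;
  per-sample SSIM uses L = range of the true DD map, with unit range
  substituted for degenerate constant maps; empty strata are absent, not
  zero).

## The balancing experiment (what the acceptance test runs)

A 400-beam 64×64 cohort with crafted imbalance: `rho_tab = 0.95`,
`rho_img = 1`, amplitudes chosen so the image-predictable structured error
dominates the DD map (gain 0.015, noise 0.0005, structured 0.012) — the
"tabular knows the GPR, only the image knows the DD pattern" premise made
concrete. Training: 10 epochs, batch 32, lr 5e-3 (90 Adam steps at the
clinical 5e-4 would barely move a desk-scale network), skip connections
enabled, r = 16 versus r = 0, three seeds. The test asserts the median
held-out DD MAE under balancing is no worse than unbalanced, and that the
final-epoch φ_img is higher under balancing — the qualitative
contribution-dynamics phenomenon. During development the no-skip variant
was measured and sat at seed-noise level, which is itself informative: if
the decoder cannot express the DD structure, no loss weighting can help.

## Known limitations

* The perturbation family is invented; clinical portal-dosimetry error
  modes are richer and the simulator makes no claim to them.
* Gamma analysis is discrete-grid; sub-pixel interpolation variants are out
  of scope, so GPRs here are systematically conservative relative to
  interpolating implementations.
* The desk-scale network is far smaller than a clinical-scale backbone;
  absolute error levels are not comparable to published clinical figures,
  only the relative balanced-vs-unbalanced behaviour is.
* Beam-level splitting only; plan-level grouping is a noted extension.
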