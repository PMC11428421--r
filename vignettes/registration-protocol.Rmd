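---
title: "Surface registration with a learned refinement stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface registration with a learned refinement stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surgical navigation systems align a preoperative image-space point cloud
(extracted from CT) with the intraoperative patient, using only what a
tracked probe can touch: a handful of anatomical landmarks (nasion, nose
tip, inner and outer canthi) and a few hundred surface points. The
conventional pipeline is two-stage:

1. **Coarse registration.** The picked landmarks are aligned to their
   image-space counterparts with the closed-form SVD paired-point solve
   (centroids subtracted, cross-covariance `H = U S V^T` decomposed, the
   rotation `R = V diag(1,1,det(VU^T)) U^T` guarding against reflections).
2. **Fine registration.** Point-to-point ICP alternates exact
   nearest-neighbour correspondence with the same closed-form solve until
   the change in RMS correspondence distance falls below a tolerance.

Manual landmark localization carries 1–5 mm of error, so the coarse
transform T_PAT starts ICP several millimetres — and, more damagingly, a
few degrees — away from the truth. Point-to-point ICP converges to the
nearest fixed point. `navreg` inserts a learned **refinement stage**
between the two: a network that looks at the coarse-registered landmark
constellation together with the surface patches the picks could have come
from, and predicts the corrective rigid transform T_REF, so ICP starts
from `T_REF x T_PAT`.

## Why a narrow ICP basin is the crux

On closed, predominantly smooth head surfaces, point-to-point ICP has a
basin of attraction of only a few degrees: a yaw misalignment slides
points tangentially along the surface, nearest neighbours re-match to
nearby samples, and the least-squares step is dominated by the smooth
majority of pairs whose residuals rotation cannot reduce. We verified the
effect is not an artefact of this implementation — an independent ICP
(trimesh's) reaches byte-identical fixed points on the same inputs. On a
strongly anisotropic convex surface the classical wide basin reappears
(the exact-recovery tests use one); on the head phantom a 2-degree offset
is recovered and a 5-degree offset is not. That narrow basin is exactly
why refining the initial alignment pays off at depth, and why similar
surface errors (SRE) can hide very different target errors (TRE).

## What the refinement network learns

During training-set generation everything happens in image space, so the
true pose is known to be the identity. A simulated trial picks each
landmark somewhere on the surface within its **candidate region** (radius
10 mm — the 1–5 mm manual range deliberately widened), coarse-registers
the picks to the reference landmarks (transform `T_c`), and stores the
coarse-registered picks `X = T_c(picks)`. Because the picks lie on the
true surface, the misregistration is entirely localization-induced, and
the corrective label is

> `T_gt = T_c^{-1}` — the transform that puts the coarse-registered
> constellation back onto the true patient geometry.

A subtlety decides the whole design: the component of the localization
error field that looks like a rigid motion of the landmark set is
*absorbed* by the coarse solve and is invisible in `X` alone. It can only
be inferred from the **local surface shape** at the picks — tilted
normals and curvature make a tangential slide detectable as an
out-of-surface inconsistency. The network therefore receives, besides
`X`, the **candidate-region cloud** `Y`: a fixed-size sample of each
landmark's surface patch (default 8 points per region spanning centre to
rim). Undoing the coarse error is then an amortized docking of a 6-point
constellation onto 6 patches. This is also why the synthetic phantom
gives its landmarks anthropometrically curved neighbourhoods (narrow
nasal-tip boss, bridge ridge, orbital-rim creases at the canthi): on a
locally planar surface the task is provably ill-posed.

## Architecture and losses

Two branches (rotational / translational) process both clouds with
shared-weight point-wise MLP encoders (widths 3, 64, 128, 256, 512),
batch norm and ReLU, channel-wise max-pooling after every stage. Every
second stage a point-wise feature interaction (PFI) module mixes each
pick's features with the pooled feature of *its own* candidate region
(the landmark correspondence between picks and regions is known by
construction) — the exchange that lets the network compare a pick with
the patch it should sit on. The reference encoding is independent of the
source cloud, so it is computed once per batch and shared across the
records of a phantom and across refinement iterations. The rotational
branch sees centroid-subtracted coordinates; the
translational branch raw coordinates plus the centroid difference.
Multi-level pooled features of both clouds feed a per-branch fusion stack
(2048, 2048, 1024); the concatenated branch outputs drive a regression
trunk (2048, 1024, 512, 256) with two heads: a 4-vector normalized into a
unit quaternion (offset toward `(1,0,0,0)`, so the cold-started network
predicts the identity) and a 3-vector translation. The prediction is
applied, the transformed constellation re-enters the network, and the
per-iteration transforms compose right-to-left into the cumulative
correction (3 iterations by default).

The loss, summed over iterations with gradients through all of them, is

* rotation: MSE of intrinsic z-y'-x'' Euler angles in **degrees**,
* translation: MSE in **mm** (de-standardized via the unit-sphere scale),
* geometry: symmetric Chamfer distance between the transformed picks and
  the region cloud, in mm².

Degrees and millimetres are deliberately commensurate on a head (1° of
facial rotation displaces surface points by roughly 1.5–2 mm), so the
default weights are 1, 1 — and 0.2 for the Chamfer term, whose
patch-coverage half penalizes even a perfect docking (six picks cannot
cover whole patches) and therefore carries a bias near the optimum.

Coordinates are standardized per image cloud: PCA axes aligned to the
Cartesian axes, centroid at the origin, scaled into the unit sphere.
Predicted transforms return to mm space by exact conjugation
`T_mm = S^{-1} T_std S`.

## Numerical and training choices

* **Autodiff.** Training runs on a small in-package reverse-mode engine
  over matrices; every op's gradient is checked against central finite
  differences in the test suite. The hot blocks (dense + batch norm +
  ReLU, quaternion algebra, pooling, Adam) are fused C++ kernels.
* **Batch norm across contexts.** The shared blocks run in several
  statistical contexts (source vs reference cloud; refinement iteration
  1, 2, 3 as alignment improves). Each context keeps its own running
  statistics, and halfway through the epoch budget the statistics are
  calibrated (cumulative average over the training split) and frozen, the
  remaining epochs training under the frozen statistics so that
  single-case inference sees exactly the normalization the final weights
  were fitted to. Without the per-context statistics and the freeze,
  frozen-statistics inference diverges from batch-statistics behaviour by
  an order of magnitude on an 11-layer normalized stack.
* **Optimizer.** Adam (weight decay on weight matrices only), step decay
  0.1x. The reference schedule decays every 100 of 500 epochs; shortened
  desk-scale runs keep the same shape by scaling `lr_step` to a fifth of
  the budget.
* **Determinism.** Every stochastic step draws from a seed derived by an
  integer hash from one master seed; identical seeds give bit-identical
  phantoms, datasets, and studies.

## The synthetic phantom study

`make_phantom()` builds a head at adult scale (superellipsoid cranium,
half-axes ~72/92/100 mm) with a parametric face: nose with a narrow tip
boss, nasal-bridge ridge, brow ridges, orbital depressions with rim
creases at the canthi, cheeks, chin, ears, an offset occipital bump and a
one-sided cheek feature that removes mirror symmetry. Six landmarks are
snapped onto sampled surface points; 27 internal targets sit at 30, 70
and 110 mm beneath nine mid-face entry points (3 vertical layers x 3
rows x 3 depths); five acquisition patterns (forehead+nose, entire face,
face borderline, forehead, above-lip) restrict which surface points a
trial may probe, emulating intraoperative access constraints. Probe
jitter defaults to 0.3 mm isotropic Gaussian (typical optical-tracker
noise); patient-side landmark picks draw offsets uniformly from 1–5 mm
along the continuous surface. Four study phantoms are four seeds of the
generator with ~4% shape perturbations.

What the phantom does **not** emulate: soft-tissue deformation physics
(only a 0.5 mm normal-direction augmentation on half the training
trials), CT reconstruction artefacts, tracker occlusion or drift, or the
point-density inhomogeneity of manual probing. Conclusions about real
patients therefore rest on the paper-scale physical validation, not on
these synthetic checks; what the synthetic study does establish is that
the pipeline's stages interact as designed (refinement widens ICP's
effective basin; depth amplifies residual rotation).

## Study sizes used by the checks

The test suite and the acceptance script run a scaled-down version of the
full design, chosen to keep a single-CPU run comfortable: 4 phantoms x
1,250 unique trials (5,000 records, split 8:1:1 into 4,000/500/500) for
network training at `width_scale = 0.25` with 15 epochs and batches of
50; the dataset-bookkeeping check runs the full 4 x 5,000-trial
generation; the qualitative study comparison uses 1 phantom x 2
restricted patterns (forehead+nose, forehead) x 2 trials x both methods.
The restricted patterns are the clinically relevant hard cases — they are
where initialization quality decides where ICP converges.

## Known limitations

* The refinement model is phantom-family-specific: it is trained on the
  same heads it refines (as in the preoperative-training workflow it
  mirrors), and nothing here measures cross-anatomy generalization.
* Point-to-point ICP only; point-to-plane or trimmed variants would
  change the basin geometry and are out of scope.
* The learned stage assumes six named landmarks in a fixed order; missing
  landmarks are not handled.
* Desk-scale training (quarter width, 15 epochs, 4k records) is far from
  the accuracy ceiling of the full 500-epoch, 16k-record GPU schedule.
  The dominant residual is the tangential-slide ambiguity of the large
  (up to 10 mm) simulated localization errors: the component of the error
  field that mimics a rigid motion of the landmark set is absorbed by the
  coarse solve and must be reconstructed from local surface shape, which
  bounds what any estimator can recover from a pick constellation (a
  point-to-patch docking oracle attains median zero error but a heavy
  tail). At desk scale the network reliably rescues the catastrophic
  coarse initializations — which is what moves the study-level target
  error — while per-axis RMSE on the full 0-10 mm error range remains
  several times the full-scale figures.
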