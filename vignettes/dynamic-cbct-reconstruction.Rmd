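---
title: "Time-resolved dynamic CBCT reconstruction with spatiotemporal implicit neural representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved dynamic CBCT reconstruction with spatiotemporal implicit neural representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A rotating-gantry cone-beam CT scan of a breathing patient acquires one 2-D
projection at a time — typically 660 projections over a 60 s, 360-degree
rotation at 11 frames/s. Conventional reconstruction treats the anatomy as
static and produces a single motion-blurred volume; phase-binned 4D-CBCT
recovers ~10 respiratory phases but averages away cycle-to-cycle variation.
*Dynamic* CBCT asks for one volume per projection: 660 volumes from 660
single projections, an extremely under-determined inverse problem that is
solvable only with strong structural priors.

`stinr` implements a self-supervised, one-shot solution. The dynamic sequence
is decomposed into

* a **reference volume** `CBCT_ref`, represented by a spatial coordinate MLP
  `\Phi^s(x | \theta)`, and
* a **time-resolved deformation** `D(t)` mapping each frame's coordinates into
  the reference, constrained to a PCA respiratory motion model:
  `D(t) = PC_0 + \sum_{dim} \sum_{n=1..3} w_{dim,n}(t) \, PC_{dim,n}`,
  with the nine scalar weight functions `w_{dim,n}(t)` represented by nine
  independent temporal MLPs `\Phi^t_{dim,n}(t | \phi)`.

Both representations are optimised jointly against the measured projections:

```
theta, phi = argmin sum_t || A_t  Phi^s(x + D(t)) - P_t ||^2
```

where `A_t` is the cone-beam forward projector at frame `t`'s gantry angle.
Frame volumes are obtained by trilinear backward warping of the rendered
reference, so every term is differentiable in `theta` and `phi`.

## Model components

**Coordinate encoding.** Spatial coordinates are normalised to `[-1,1]^3`
(temporal to `[0,1]`) and passed through a Gaussian random Fourier feature
encoding `gamma(x) = [sin(2*pi*B*x), cos(2*pi*B*x)]`, with `B` drawn once
from `N(0, sigma_B^2)` and frozen. Without this encoding a coordinate MLP
cannot fit the high-frequency content of a CT volume. `sigma_B = 2.5` is the
preset for phantom studies (a `sigma_B = 4` preset exists for
higher-detail patient-like data); both the spatial and temporal encoders use
128 features in the full preset.

**Architecture.** The full-fidelity preset is a 4-layer, 256-neuron spatial
MLP and nine 3-layer (256, 100, 100) temporal MLPs, Swish-activated
(`swish(y) = y * sigmoid(y)`) everywhere except the linear outputs. The
`"scaled"` preset used throughout the shipped studies reduces this to 64
spatial / 32 temporal Fourier features, 64-neuron spatial layers and
(64, 32, 32) temporal layers — a capacity study on the 32^3 phantom showed
64-wide layers reach a voxel-fit relative error of ~0.15 where 32-wide
layers stall near 0.34, and 64 spatial features stabilise the random
encoder's spectral coverage across seeds. The network
internally represents attenuation in units of 0.02 mm^-1 (soft tissue) so
activations and gradients are O(1); outputs are rescaled on evaluation.
The spatial output is linear; negative attenuations are clipped only at
export, never inside the loss, which would bias gradients.

**Motion model.** A prior 10-phase 4D set is registered phase-by-phase to its
end-expiration (EE) phase — EE is the most stable phase — giving 9
inter-phase pull-back deformation fields. Per Cartesian direction, the
flattened fields are mean-centred and decomposed by SVD; the top 3 right
singular vectors, each scaled by `singular value / sqrt(m - 1)` (one standard
deviation of the training coefficient), are the scaled principal components.
The mean field is the DC component `PC_0`. Scaling makes unit temporal-MLP
outputs correspond to typical training motion, balancing gradient magnitudes
across components. Signs are fixed so each component's training weight track
correlates positively with the SI surrogate, making recovered weight tracks
directly comparable to planted coefficient tracks. Registration can be the
built-in multi-resolution demons scheme or a ground-truth bypass (the
simulator knows its own fields), which isolates reconstruction tests from
registration error.

**Three-stage schedule.** Joint optimisation from scratch is prone to poor
local optima, so the fit proceeds in stages: (1) the spatial MLP is fitted
voxelwise to an FDK reconstruction of the EE projection subset (the lowest
decile of the respiratory surrogate), with the target clipped at zero —
attenuation is non-negative, and a sparse-view FDK's negative streak
artifacts would otherwise consume network capacity and later alias into the
motion gradients (the stage is also kept deliberately short: early stopping
regularises against fitting the residual streaks); (2) it is fine-tuned
directly against the EE projections; (3) spatial and temporal MLPs are
optimised jointly on all projections, each iteration rendering the reference
once on the optimisation grid, then warping/projecting a uniformly sampled
random minibatch of frames. All INRs use Adam; the full preset keeps the
reference schedule (500/500/4000 iterations at learning rate 0.002). The
scaled preset uses 300/300/2000 at learning rate 0.01 with 4-frame
minibatches — the smaller network tolerates and needs the larger step, chosen
from stage-1 convergence curves, and the smaller batch keeps a stage-3 run
practical on a single CPU core.

Stage 3 opens from the static end-expiration state: the temporal output
biases are initialised at the weights that cancel the model's mean field
(`D ~ 0`), matching the anatomy the first stages reconstructed, and the
spatial parameters are held fixed for the first tenth of the stage while the
temporal weights catch up with the intra-scan motion. Without this, the
reference can absorb motion artifacts early and drag the joint fit into a
poor basin — observed as strong seed sensitivity in desk-scale runs.

The scaled component weights are box-bounded at ±4 in both the joint fit and
the per-projection comparator: scaled weights are standard deviations of
training motion, so every simulated trajectory (including baseline shifts)
stays well inside the box, while weakly-projecting components — whose
gradients are tiny but whose Adam steps are full-size — would otherwise
drift to large values and corrupt the composed deformation.

Two further stabilisers matter at this scale. First, Adam's per-parameter step
normalisation keeps parameters random-walking on minibatch noise even after
the loss plateaus; the returned fit therefore uses Polyak tail averages of
the spatial and temporal parameters over the final quarter of stage 3, which
removes the stationary noise walk without slowing convergence (an optional
exponential learning-rate schedule, `lr_decay`, exists but is off by
default — on short runs it freezes early transients in). Second, the scaled
temporal encoder is deliberately band-limited (32 features): each frame's
weight is informed by a single projection, and the narrow encoder band acts
as a temporal smoothness prior; widening it to 128 features measurably
degraded weight-track recovery by letting the nets chase per-frame noise.

One identifiability caveat: deformation components supported on uniform
interior tissue barely change any projection, so the corresponding weight
directions are data-null and drift freely. Solved deformation fields are
therefore meaningful where the image has contrast (tumor, diaphragm, organ
boundaries) — which is what the tumor-tracking metrics measure — and should
not be read voxelwise in flat regions.

## The synthetic dynamic-thorax study

The phantom is a parametric ellipsoid thorax: a soft-tissue body
(0.020 mm^-1), two lungs (0.005), a heart, a bony spine cylinder (0.045) and
a 15 mm-radius spherical tumor (0.028) in the lower right lung — all inside
the conventional [0, 0.05] mm^-1 display range. Ground-truth motion is built
from K = 3 smooth displacement basis fields (SI-dominant diaphragm field with
12 mm peak amplitude, a 3 mm AP chest-wall field, and a weaker secondary
mode), all vanishing on the spine and outside the body. Every simulated
deformation is `D(x,t) = sum_k c_k(t) b_k(x)`, so ground-truth motion is
exactly rank-3 and a 3-component PCA model can represent it exactly — which
turns weight-track recovery into a well-posed acceptance surface.

The coefficient tracks are closed forms on a 5 s breathing cycle starting at
end-expiration, with eight scenario variants: S1/S2 add a +3/+8 mm SI
baseline step at mid-scan; S3 changes the period to 3.5 s; S4 modulates the
amplitude by ±30 % and drifts the baseline by 3 mm; S5 modulates amplitude
and period simultaneously; S6 is a single slow monotone excursion
(non-periodic motion); S7 halves the tumor diameter and S8 shifts the tumor
6 mm per axis relative to the prior anatomy (inter-scan changes). The
magnitudes are this package's own choices — chosen once as representative
lower-lobe lung-tumor motion (the tumor's SI excursion is ~7.5 mm) — and are
configurable.

The scan model follows the standard thorax protocol: source-isocentre
1000 mm, source-detector 1500 mm, full-fan flat panel, 6 deg/s over 360
degrees. Projections are line integrals from a ray-driven (Joseph-style)
projector sampled at half the smallest voxel spacing; its adjoint is the
transpose of the same discretisation, which keeps algebraic updates and
gradients consistent. Optional Poisson noise converts line integrals to
photon counts at dose `I0` and back.

What the phantom does *not* emulate: anatomically realistic organ shapes,
cardiac motion, scatter, beam hardening, detector blur, or motion outside the
rank-3 span (an out-of-span perturbation can be added via a registration
perturbation instead). Passing tests therefore demonstrate correctness of the
method's machinery and its behaviour under controlled model mismatch — not
clinical performance.

## Desk-scale study conditions

The shipped studies run at `scaled_study_config()` sizes: a 32^3 optimisation
grid (6 mm voxels over the same 192 mm field of view — the same ratio of
optimisation grid to ground-truth grid as the reference setting), a 64^2
detector whose 300 mm panel covers the magnified field of view, and 220
projections over one full 360-degree, 60 s rotation. Keeping the full
rotation (rather than the clinical 11 fps frame rate, which over 220 frames
would span only 120 degrees) preserves the regular-breathing full-scan
condition; the frame-angle law `alpha_N = (speed/rate)(N-1)` is unchanged.
The comparative scenario study (joint fit vs per-projection PCA fitting on S1
and S6) runs at 24^3 / 48^2 / 110 frames with every 5th frame evaluated.

## Comparators

**Per-projection PCA fitting** (`pca_cv_fit()`): the classical
single-projection approach. A fixed reference volume — here an ART+TV
reconstruction of the EE projection subset — is warped by the same motion
model, and each frame's 9 weights are fitted independently by
Polak–Ribière nonlinear conjugate gradient (Armijo line search, warm starts,
box bound ±4 on scaled weights, ≤60 iterations/frame). Its known failure
mode: under non-periodic motion the EE frames cluster into a limited-angle
wedge, the reference collapses, and the weight fits degrade catastrophically.
The ART update is implemented as the per-view simultaneous (SART-style)
variant of the row-action scheme, alternated with steepest-descent steps on
the smoothed isotropic TV norm (step length 0.1× the preceding update norm,
10 steps per alternation, relaxation 0.4, non-negativity enforced).

**Polynomial temporal baseline** (`inr_poly_fit()`): the same spatial INR,
but motion parameterised as per-voxel coefficient grids weighted by temporal
polynomials `D(x,t) = sum_k t^k M_k(x)` (default order 3). With no motion
prior and a polynomial time basis it recovers slow drifts but cannot
represent multi-cycle breathing — the failure mode it exists to demonstrate.

## Numerical choices and degenerate inputs

* Warping uses clamp-to-edge trilinear interpolation (no NaNs); the
  displacement gradient is zero along clamped axes.
* FDK uses cosine weighting, a discrete band-limited ramp kernel with a
  raised-cosine apodisation, and full-scan (×1/2) weighting; it is exact only
  in the high-view, small-cone limit and is used as an initialiser and
  baseline, not as the method.
* PCA components with numerically zero scale (rank-deficient directions)
  receive zero weight in projections rather than blowing up the normal
  equations; a model with *all* zero scales is rejected.
* Constant surrogate signals make EE extraction degenerate: all frames are
  selected with a warning.
* Divergence (non-finite loss) aborts a fit with a diagnostic rather than
  returning garbage.
* All randomness (encoder matrices, weight init, minibatch order, noise) is
  seeded; a master seed fans out to per-component seeds by hashing, so any
  stage is independently reproducible and full runs are bit-identical.

## Limitations

The registration substitute is a lightweight demons scheme, not a validated
clinical registration; the bypass mode exists precisely so that model and
reconstruction tests do not inherit its error. The phantom's rank-3 motion
makes weight recovery well-posed; real respiratory motion has out-of-model
components that appear as a floor on achievable accuracy. The desk-scale
architecture trades spatial resolution for CPU tractability — reconstructed
references at 6 mm voxels blur 15 mm lesions appreciably, which is visible in
DICE values. No scatter or detector physics beyond Poisson counting noise is
modelled.
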