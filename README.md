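# stinr

Time-resolved ("one volume per projection") dynamic cone-beam CT
reconstruction from a single rotating-gantry scan, in R.

## The problem

A 60 s cone-beam CT scan of a breathing thorax acquires 660 projections, one
every 1/11 s, while the anatomy moves. Standard reconstruction yields one
motion-blurred volume; respiratory-phase binning yields ~10 averaged phases.
Reconstructing a *separate volume for every projection* from that single scan
is massively under-determined — each volume is constrained by exactly one 2-D
view — and becomes tractable only with strong priors.

`stinr` implements a self-supervised spatiotemporal
implicit-neural-representation (INR) approach. The dynamic sequence is
factored into a reference volume and a time-resolved deformation constrained
to a PCA respiratory motion model:

```
CBCT_dyn(x, t) = CBCT_ref( x + D(t) ),
CBCT_ref       = Phi_s(x | theta)                       (spatial MLP)
D(t)           = PC_0 + sum_{dim,n} w_dim_n(t) PC_dim_n
w_dim_n(t)     = Phi_t_dim_n(t | phi)                   (9 temporal MLPs)
```

with Gaussian random Fourier feature encodings on the MLP inputs, and both
parameter sets fitted jointly by minimising
`sum_t || A_t Phi_s(x + D(t)) - P_t ||^2` over the acquired projections
`P_t` through a differentiable warp-and-project pipeline, in three stages
(FDK-based pre-conditioning of the reference on the end-expiration
projection subset, projection-domain fine-tuning, then joint spatiotemporal
optimisation). The PCA motion model is built from inter-phase registrations
of a prior 10-phase 4D set.

The package is self-contained for synthetic studies: it ships a parametric
dynamic-thorax phantom (ellipsoid anatomy, rank-3 diaphragm-driven motion, a
15 mm spherical lung tumor, eight breathing/anatomy scenarios), a ray-driven
cone-beam projector with an exact adjoint, FDK and ART+TV reconstruction, a
per-projection PCA-weight comparator and a polynomial temporal baseline, and
an evaluation suite (relative error, tumor DICE, tumor center-of-mass error,
SI motion trajectories).

## Worked example

A desk-scale regular-breathing study (32³ grid, 64² detector, 220
projections over one 360° rotation; a few minutes on one CPU core):

```r
library(stinr)

cfg <- scaled_study_config("S1", seed = 1)   # S1: small baseline shift
report <- run_experiment(cfg, "s1_run")
print(report)
#> <stinr_report> stinr, 220 frames
#>  method  metric      mean          sd
#>   stinr      re 0.1638489 0.003989046
#>   stinr    dice 0.9206123 0.059996733
#>   stinr come_mm 1.4154680 1.307445669
```

The report says: across all 220 reconstructed frames, the reconstructed
volumes differ from ground truth by ~16 % relative error (dominated by the
6 mm optimisation voxels), while the solved motion tracks the tumor to a
mean center-of-mass error of 1.4 mm with a mean mask overlap (DICE) of
0.92. `s1_run/` contains the phantom, projections (TIFF + YAML), the motion
model (NIfTI + YAML), the solved weight track, per-stage loss curves, the
per-frame metric table and a manifest with seeds and file checksums;
`plot_trajectory(report)` draws the reconstructed vs ground-truth SI tumor
trajectory.

Individual pieces are plain functions: `build_reference_anatomy()`,
`breathing_track()`, `generate_dynamic_sequence()`, `forward_project()`,
`fdk_reconstruct()`, `build_pca_model()`, `stinr_fit()` / `stinr_infer()`,
`pca_cv_fit()`, `inr_poly_fit()`, `evaluate_sequence()`. A thin CLI wrapper
lives at `inst/cli/stinr`.

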