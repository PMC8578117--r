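---
title: "Model-driven registration of free-breathing MR renography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven registration of free-breathing MR renography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdreg)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI of the kidney acquires an image every
second or so while a contrast agent washes through the tissue. Quantitative
renography fits a tracer-kinetic model to every pixel's signal-time curve to
map plasma flow, tubular flow and the two mean transit times. Free breathing
moves the kidney by many pixels between frames, and the image contrast
reverses several times during the passage of the bolus, so conventional
pairwise registration to a fixed reference fails: no single reference frame
looks like the others.

Model-driven registration (MDR) resolves this by registering every frame to
a *synthetic* target with the correct contrast: the frame predicted by the
kinetic model fitted to the current estimate of the motion-corrected data.
Model fitting and per-frame co-registration alternate, both reducing the
same least-squares cost, until the deformations settle.

## Signal model

The signal is assumed linear in concentration, with the calibration factor
absorbed into the kinetic parameters, so `S(x, t) = S0(x) + C(x, t)`. The
tissue is modelled as a two-compartment filtration system (2CFM): a plasma
compartment with flow `FP` (mL/min/100 mL) and mean transit time `TP`
(seconds) fed by the arterial input function `ca(t)`, draining into a
tubular compartment with flow `FT` and transit time `TT`. The tissue
response to an impulse is a biexponential, and forward simulation
(`simulate_concentration_2cfm()`) convolves it with `ca` by a trapezoid
rule. Flows are carried in clinical units and converted internally by
1 mL/min/100 mL = 1/6000 s⁻¹.

For fitting, the model is rewritten in *linearised* form: the
baseline-subtracted signal equals a linear combination of its own single
and double running time integrals and those of the AIF. This makes the
per-pixel fit an ordinary least-squares problem with no initial values and
no iteration (`fit_linear_2cfm()`), which matters because the fit runs once
per outer iteration over every pixel of the image. The four regression
coefficients map back to `(FP, TP, FT, TT)` through the roots of a
quadratic (`coeffs_to_params()`); the branch is fixed by the renal
convention `TP < TT`. The mapping was validated by a round-trip oracle
(simulate, fit, invert) across the full parameter ranges of the phantom
rather than transcribed from a closed form, and the package carries the
companion `params_to_coeffs()` so the consistency of the pair is testable.

Degenerate pixels — flat background, rank-deficient regressors, complex
roots — return zero coefficients with a constant target at `S0` and a
cleared `ok` flag, never an error: whole-image fitting must not abort in
the middle of a registration. When parameter maps are exported, flagged
pixels are written as zero flow.

## Deformation model

Motion is modelled by free-form deformations on a rectangular control-point
lattice with *linear* (tent) interpolation, chosen for speed over cubic
B-splines. Coordinates are voxel-centre, 0-based, in pixel units. A
deformation maps corrected-frame coordinates to source-frame coordinates
(backward warping), and images are sampled between voxel centres with the
same tent kernel. Out-of-bounds source coordinates clamp to the image edge;
with shifts of ten pixels or more, zero-filling would inject false signal
steps into the kinetic fit near the borders.

The lattice starts at the image corner and its last point lies on or
beyond the opposite corner. `refine_grid()` halves the spacing and samples
the new control displacements from the old piecewise-linear field; because
the new knots sit at the old knots and their midpoints, the dense field is
reproduced exactly — refinement changes the parameterisation, never the
deformation.

## The optimizer

The joint cost is `chi^2(D, P) = 1/2 * sum((S_D - Sigma)^2)` over all
pixels and frames. One outer iteration alternates:

1. **Model fit at fixed deformation** — per-pixel linear least squares on
   the currently corrected series, producing the target stack `Sigma`.
2. **Deformation fit at fixed target** — for each frame independently,
   gradient descent on the control-point displacements with a
   back-tracking line search.

The gradient over a control point is the tent-weighted sum of
residual × image-gradient products over the kernel support, computed once
per frame and shared by all control points. The image gradient entering
this expression is the *exact* spatial derivative of the tent-kernel
interpolant, evaluated during the warp. A central-difference gradient
warped to the deformed coordinates differs from the true derivative of the
sampled image at second order, which is enough to break the
finite-difference validation of the gradient and to produce occasional
non-descent directions; the exact derivative costs nothing extra (it uses
the same 4 corner values as the interpolation) and makes the analytical
gradient agree with finite differences of the cost to machine precision at
any displacement state away from interpolation-cell boundaries. At the
exact identity every voxel sits *on* a cell boundary, where the
piecewise-linear interpolant is one-sidedly differentiable — gradient
checks are therefore run at a generic sub-pixel state.

The line search starts each frame's first descent step scaled to a maximum
displacement of 1 pixel, then reuses the previously accepted step
(preconditioning). On first-try success it keeps doubling while the cost
keeps falling and accepts the best trial; on failure it halves, up to 20
trials. A frame stops when the accepted update changes no control point by
more than the tolerance, or when the search finds no descent. The step
memory is reset at each resolution level because the gradient scale
changes with the lattice.

The multi-resolution schedule starts with the control-point spacing equal
to the field of view (a translation-like deformation per frame) and halves
it down to `grid_spacing_min`. A level ends when a sweep changes no frame
by more than the tolerance, with a safety cap of 50 outer iterations.
Deformations carry across levels through exact grid refinement. The whole
procedure is deterministic: identical inputs produce identical outputs.

### A moving target, and a monotonicity safeguard

Because `S0` and the signal integrals are computed from the data, the
target `Sigma` is itself a function of the data being deformed — the
registration target moves. The exact gradient of the groupwise problem
replaces the residual with a generalised residual built from the matrix
`dR = (I - alpha1*L - alpha2*L^2)(I - M0)`, where `L` is the cumulative
trapezoid integration matrix and `M0` the baseline-averaging matrix. The
off-identity terms scale with `dt/TP + dt/TT` and `1/n0`, which are small
at renography frame rates, so the engine adopts `dR = I` and treats frames
independently; the exact `dR` ships as a diagnostic
(`generalized_residual()`, `residual_derivative_matrix()`), validated
entrywise against numerical perturbation of the fit formula.

One consequence of the moving target: a model *refit* is not mathematically
guaranteed to lower the cost measured against its own new target. The
engine therefore accepts a refit only if the logged cost does not increase
and otherwise keeps the previous target; deformation steps, which always
compare against a frozen target, are monotone by construction. The final
reported maps always come from a fresh fit of the final corrected series.

A second consequence is a gauge freedom: a slow temporal drift of the
frozen breathing state can be absorbed by the kinetic model and is
therefore almost invisible to the cost. More aggressive optimization does
not remove it — in experiments on the phantom, tightening the tolerance
let the alternation wander *further* along this degenerate direction. The
algorithm deliberately keeps the stopping rule at its stated operating
point and leaves the frozen state to emerge from the optimization, as no
reference frame is ever chosen.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `grid_spacing_min` | 32 (2D), 4 (3D) | pixels | finest control-point spacing; smaller values start correcting model error as if it were motion |
| `tolerance` | 0.3 (2D clinical), 0.2 (phantom, 3D) | pixels | per-frame and per-level stopping threshold on displacement changes |
| `n0` | 15 | frames | pre-contrast frames averaged into `S0` (about 10–20 for renography) |
| `model` | `linear_2cfm` | — | target generator; `modified_tofts` exists to probe model bias |
| `max_line_search` | 20 | trials | back-tracking budget per descent step |
| `max_outer` | 50 | iterations | per-level safety cap |

The modified Tofts solve is a deterministic grid search: 30 log-spaced
efflux rates between 10⁻⁴ and 1 s⁻¹ with exact two-variable non-negative
least squares at each grid point, so results carry no optimizer state.

## The digital reference object

`build_dro()` builds a kidney-mimicking phantom on a 135 × 135 matrix with
120 frames at 1.1 s, simulated at 0.1 s and block-averaged (frame-centred,
11 fine samples per frame) to the frame grid, with `S0 = 1` and a 15 s
pre-contrast baseline (13 baseline frames at the default timing). Each
kidney is three concentric ellipses — cortex ring, medulla ring, pelvis
core — with parameters at the endpoints and midpoints of the ranges
`FP` 30–300 mL/min/100 mL, `TP` 6–20 s, `FT` 40–60 mL/min/100 mL,
`TT` 90–300 s (cortex: high flow, fast transit; pelvis: low flow, slow
transit). The exact ellipse geometry is a configurable default; only the
concentric-ellipse construction and the parameter ranges are prescribed.

The arterial input function is a documented population form — exponential
bolus rise (3 s) with biexponential washout (20 s and 300 s) after the
baseline, in arbitrary concentration units — injected everywhere rather
than hard-coded, so a measured AIF table can replace it.

Motion corruption warps every frame (and, with the identical fields, the
ground-truth parameter maps) backward: rigid motion is a vertical
sinusoidal shift of amplitude 12 px and period 4 s, zero at `t = 0`;
non-rigid motion interpolates seeded sinusoidal trajectories of a coarse
4 × 4 control lattice with one coherent breathing phase per axis plus
per-point jitter, amplitude larger vertically, checked for positive
Jacobian. The non-rigid fields are a synthetic stand-in for fields measured
on clinical data, which this package does not ship. Gaussian noise with
standard deviation `max(ca)/CNR` is added after motion corruption (a
declared choice; the alternative order is equally defensible).

Because a motion-frozen reconstruction may legitimately settle in any
breathing state, evaluation selects the ground truth per run: the
co-deformed truth map whose plasma-flow field best matches the
reconstruction (`select_reference_state()`), with ties to the earliest
frame.

### What the phantom does and does not emulate

It reproduces the geometry, kinetics, frame timing, motion scale and noise
convention of free-breathing renography — enough to validate the
optimizer, the gradient, and the error metrics. It does not simulate
acquisition physics (saturation-recovery signal equations, SENSE,
within-frame artefacts), a real background anatomy, or through-plane
motion. Two consequences matter when reading test results. First,
pre-contrast frames are featureless (uniform `S0` plus noise), so no
intensity-driven method can register them — mask-overlap metrics are
evaluated on frames acquired after bolus arrival. Second, the phantom's
piecewise-constant regions make edge pixels maximally sensitive to
sub-pixel resampling: corruption and correction each resample the image
with frame-dependent fractional offsets, creating partial-volume errors at
region boundaries that set a floor on map precision which even an oracle
correction (the exact inverse motion) cannot undo. Passing tests show the
algorithm recovers the motion to a fraction of a pixel; they do not show
that parameter maps from resampled data match unresampled ones at sharp
interfaces, because they cannot.

## Evaluation metrics

Percent error is `(recon − truth) / max(truth) × 100` with the maximum
taken over the whole ground-truth field; bias is the median over evaluated
pixels and precision the width of the equal-tailed 90% confidence interval
(95th − 5th percentile, linear interpolation — the rule matters at small
pixel counts and is fixed here). The Hausdorff distance between binary
masks uses boundary voxels from morphological erosion and the classical
max–min definition in voxel units, validated against a brute-force
all-pairs computation. `time_cut()` extracts space × time images along a
chosen line for visual inspection of residual motion.

## Problem sizes in the test suite

The packaged tests exercise the full pipeline at two scales chosen as the
package's own validation conditions: a half-scale phantom (64 × 64, 60
frames, 6 px rigid motion) for the optimizer properties, and the full-size
phantom (135 × 135, 120 frames, 12 px) for the segmentation-overlap
property. The gradient oracle runs on a 16 × 16 image with 5 frames and
interior control points; the kinetic round-trip covers a 5⁴ grid spanning
the phantom parameter ranges at 0.1 s resolution. `scripts/acceptance.R`
reruns all of these from scratch and writes the measured quantities as
JSON.

## Known limitations

- The 3D code path is implemented in the kernels (trilinear warping,
  anisotropic spacing) but the shipped phantom is 2D; 3D use is exercised
  only at the unit level.
- At fine grid spacings the deformation starts absorbing residual model
  error — with a wrong model (modified Tofts on filtration-dominated
  tissue) this produces visible unphysical deformations during the first
  pass, which the package treats as a diagnostic signal, not a failure.
- The frozen breathing state is determined only up to the gauge freedom
  described above; applications needing a specific state (e.g.
  end-expiration) should select it downstream via the reference-state
  machinery.
- Exact groupwise optimization with the full generalised residual is
  available as a diagnostic only; it is not an optimizer mode.
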