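# mdreg — model-driven registration for DCE-MR renography

Free-breathing dynamic contrast-enhanced (DCE) MRI of the kidney moves the
organ by many pixels between frames while the image contrast reverses
during the passage of the contrast bolus, so registering all frames to any
single reference image fails. **Model-driven registration (MDR)** instead
co-registers every frame against a synthetic target with the *right*
contrast: the frame predicted by a tracer-kinetic model fitted to the
current motion-corrected data. Model fitting and per-frame free-form
deformation alternate on one joint least-squares cost,

> χ²(D, P) = ½ Σ₍ₓ,ₜ₎ ( S_D(x, t) − Σ(P(x), t) )²,

inside a multi-resolution schedule whose control-point spacing starts at
the field of view and halves down to a user-defined minimum. The
deformation gradient over each control point has a closed form — the
tent-weighted sum of residual × image-gradient products over the kernel
support — which makes the descent cheap and exactly verifiable against
finite differences.

The package is aimed at quantitative-MRI researchers: it provides

- the renal **two-compartment filtration model** (2CFM): forward
  simulation, and the linearised per-pixel least-squares fit
  (`fit_linear_2cfm()`) whose coefficients map back to plasma flow `FP`,
  plasma transit time `TP`, tubular flow `FT` and tubular transit time
  `TT` (`coeffs_to_params()`), plus a modified Tofts fit for studying
  model bias;
- the **FFD registration engine** with linear (tent) interpolation,
  analytical gradient, back-tracking line search and exact grid
  refinement, exposed as one fitting function `mdr()` returning a classed
  object with `print`/`summary`/`coef`/`fitted`/`residuals`/`plot`
  methods;
- a kidney-mimicking **digital reference object** (`build_dro()`) with
  ground-truth parameter maps, rigid and non-rigid motion corruption and
  CNR-controlled noise;
- **evaluation metrics**: percent-error maps, bias (median) and precision
  (90%-CI width), Hausdorff distance between masks, space×time cuts;
- NIfTI/CSV/YAML/JSON input and output and a thin command-line wrapper
  (`inst/cli/mdr` with `dro`, `fit` and `eval` subcommands).

## Worked example

Build a half-scale phantom with 6-pixel sinusoidal breathing motion,
correct it, and score the plasma-flow map against the matching ground-truth
breathing state:

```r
library(mdreg)

spec <- dro_spec(matrix = c(64, 64), n_frames = 60, motion = "rigid",
                 amplitude = 6, period = 4, cnr = 1000, seed = 7)
phantom <- build_dro(spec)
phantom
#> Kidney DRO: 64 x 64 matrix, 60 frames at 1.1 s, motion = rigid, CNR = 1000

fit <- mdr(phantom$series, phantom$aif_frames,
           grid_spacing_min = 32, tolerance = 0.2)
fit
#> Model-driven registration
#>   model: linear_2cfm | levels: 2 | frames: 60
#>   chi2: 3058.04 -> 10.2385
#>   mean |displacement|: 3.13 px

ref   <- select_reference_state(fit$params$FP, phantom)
truth <- moving_truth_maps(phantom, ref$frame)
fp    <- fit$params$FP; fp[!is.finite(fp)] <- 0
unlist(bias_precision(percent_error(fp, truth$FP)))
#>      bias precision
#>  0.000000  6.139321
```

The cost falls by two orders of magnitude while the recovered mean
displacement (3.13 px) matches the mean of the applied |6·sin(2πt/4)|
shifts; the corrected plasma-flow map has zero median error, and the 90%
confidence interval of the percent-error map — dominated by partial-volume
pixels at the sharp region edges of the phantom — is a few percent, versus
tens of percent without correction. `plot(fit, "cost")` and
`plot(fit, "timecut")` show the cost trace and the before/after space–time
cuts.

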