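---
title: "Multi-scale dipole inversion: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale dipole inversion: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msdiqsm)
```

## The model

Gradient-echo phase measures the dipole-convolved susceptibility
distribution: in the frequency domain, the local field is `D(k) F(chi)` with
`D(k) = 1/3 - (k.B0)^2/|k|^2`, converted to radians by
`2 pi gammabar B0 TE 1e-6` (`gammabar` = 42.576 MHz/T). Direct inversion is
ill-posed (D vanishes on the magic-angle cone) and fragile against
background fields, noise, and flow-corrupted phase.

`msdiqsm` splits the inversion into a Laplacian pyramid. At scale `l` with
spherical-mean-value (SMV) kernel `S_l` of radius `r_l`:

1. **Re-initialisation.** `phi_l = phi - FH D F X_{l-1}`: the field not yet
   explained by finer scales. Expanding the recursion shows
   `phi_l = phi_{l-1} - FH D F X'_{l-1}` — each level sees only what the
   previous level left behind, which is what prevents noise amplification
   and mask erosion from compounding across scales.
2. **Band selection.** `phi'_l = phi_l - S_l * phi_l`: the high-pass
   complement. Background fields are harmonic inside the ROI and equal
   their spherical means, so they are suppressed; dipole fields of spatial
   extent below `r_l` pass.
3. **Constrained inversion.** Minimise
   `lambda ||Q_l W_l (exp(i FH S~_l D F X) - exp(i phi'_l))||_2^2 +
   ||M grad X||_1`. The complex-exponential fidelity makes the residual
   insensitive to residual wraps; the weighted L1 gradient penalty promotes
   piecewise-constant solutions except where the magnitude image itself has
   edges.
4. **Accumulation.** `X_l = X_{l-1} + X'_l`. The final level is the
   full-scale map; truncations are high-pass susceptibility maps (HPSM).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `radiiMm` | 2, 4, 8, 16 | mm | SMV radii (snapped to voxel multiples); power-of-two growth balances background suppression against quantitative completeness. Radii below ~6 mm as the maximum give attenuated but detail-rich HPSM maps. |
| `lambda` | 10^2.7 | – | Weight of the consistency term; the L-curve optimum under the TE.B0 = 60 ms.T normalisation. 10^1.6 is the strong-regularisation venography recipe; 10^3.3 the high-fidelity 2 mm HPSM recipe. |
| `meritF` | 6 | – | Residual threshold for dynamic down-weighting: voxels whose normalised consistency residual exceeds f get weight `a'/rhat^2`, recomputed from the pristine weights each outer iteration. |
| `qPercent` | 10 | % | Base reliability-mask percentile; scale `l >= 2` masks the top `q r_l / r_2` percent of phase second differences (10/20/40% at scales 2–4). |
| `epsilon` | 1e-6 | (ppm/mm)^2 | Weak-derivative smoothing of the L1 term; sets the gradient magnitude below which flatness is no longer enforced (~1e-3 ppm/mm). |
| `cgTol`, `outerTol` | 0.1, 0.1 | – | Relative CG residual and quasi-Newton update tolerances. |
| `maxOuter` | 10 | – | Outer iteration cap (the update tolerance usually stops the loop after 3–5). |
| `edgePriorScales` | 1 | – | Scales using the morphological prior (top-30% magnitude gradients exempted from the regulariser); only the 2 mm scale, where vascular edges are co-localised with magnitude edges. |

Preprocessing: Laplacian unwrapping, variable-kernel SMV background removal
(`r0 = 40` mm down to one voxel in one-voxel steps, SHARP-style
deconvolution by the final kernel under a 0.05 truncation threshold), and
the `60/(TE[ms] B0[T])` field normalisation that makes one lambda range
transfer across acquisitions.

## What the phantom generator emulates — and what it does not

`standardPhantom()` is a 64 mm cube (default 1 mm isotropic) with a 28 mm
spherical ROI: three "nuclei" spheres (0.05/0.10/0.20 ppm), two 1.5 mm
paramagnetic cylinders along B0 (0.45 ppm, venous-blood-like), one
diamagnetic slab (−0.05 ppm), and two external point-dipole sources.
Acquisition: complex signal `A exp(i phase)` with i.i.d. complex Gaussian
noise at SNR 50 per channel (TE 20 ms, B0 3 T, so TE.B0 = 60 ms.T and the
normalisation is the identity), seed 1234.

The background source moments (±1.0/0.8 ppm·mm³ just outside the ROI) are
capped by the phase-sampling constraint: the wrapped in-ROI phase gradient
must stay below ~pi/2 per voxel, because data aliased beyond pi per voxel
are unmeasurable — no unwrapping method can identify the underlying field,
so stronger sources would not constitute a valid synthetic measurement.
They produce ~0.1–0.15 ppm boundary fields, a realistic residual-background
level. Tests that need a *dominant* background instead add a strong distant
source (e.g. moment 2500 at 60 mm, outside the volume), which is both strong
and Nyquist-compliant.

The generator does **not** emulate: anatomical texture (the background is
exactly zero susceptibility between objects), multi-echo signal evolution
and R2* decay, flow and motion, coil sensitivities, or resolution
anisotropy. Two consequences matter for interpreting green tests. First,
recovery numbers on piecewise-constant scenes flatter any
gradient-sparsity-regularised method; real tissue is less sparse. Second,
the zero-susceptibility background makes the *sign* of the reconstructed
background undecidable at the noise floor: the reconstruction settles into a
symmetric ±2e-3 ppm ripple (set by the `sqrt(epsilon)` knee of the L1 term
against the phase-noise data gradient), so the sign-binarised venography
mask admits roughly a tenth of the background voxels as false positives on
the phantom — even though vessel sensitivity is 100% — whereas in vivo the
rule discriminates because parenchyma has systematically nonzero (mostly
diamagnetic) susceptibility relative to veins.

## Numerical choices

- **FFTs and kernels.** All convolutions are circular; SMV spheres are
  rasterised by voxel-centre inclusion (no partial-volume anti-aliasing)
  and unit-normalised; `D(0) = 0` enforces unreferenced (zero-mean)
  solutions throughout.
- **Gradient operator.** Forward differences scaled by voxel size, zero
  gradient at the trailing volume face, with the exactly matched adjoint.
  Both cost terms are therefore DC-blind, the CG right-hand side is
  zero-mean, and the solution mean stays at zero to machine precision
  without any explicit referencing step.
- **L1 reweighting.** Componentwise `1/sqrt(g_d^2 + epsilon)` weights,
  updated every outer iteration (anisotropic, matching the quasi-Newton
  fixed-point solver family this follows).
- **MERIT residual.** `|Q a'(exp(i C X) - exp(i phi'))|`, normalised to ROI
  mean 1, measured with the *pristine* weights: the reweighting rule defines
  W as a function of the residual, so the residual itself must not depend on
  W (a current-weight residual sets up a two-cycle in which crushed voxels
  leave the normalising mean and get alternately restored and crushed).
- **Step safeguard.** The quasi-Newton step is backtracked (halved, at most
  a few times) whenever it would increase the current-weight objective; the
  recorded per-scale cost histories are non-increasing in practice.
- **Laplacian unwrapping.** The sin/cos Laplacian is inverted by a spectral
  Poisson solve on the even-mirrored (Neumann-like) domain — a purely
  periodic solve cannot recover linear ramps, which are harmonic on the
  torus — followed by a few residual-refinement passes (rewrap the residual,
  unwrap, add back). Refinement makes smooth wrapped fields exact to machine
  precision; accuracy degrades only where true phase steps approach pi per
  voxel, which is a property of the data, not the solver. The global
  constant is unrecoverable and set by a zero-mean convention.
- **vSMV.** For each voxel, the largest kernel radius that fits inside the
  ROI (occupancy >= 1 − 1e-6) is used; each radius band is SHARP-deconvolved
  by its own kernel complement with a truncated inverse (threshold 0.05), so
  retained local fields are not attenuated while the near-harmonic band is
  zeroed rather than amplified. Output loses only a one-voxel shell. Within
  the pyramid itself the ROI is never eroded: SMV filtering near the
  boundary renormalises the in-ROI kernel mass instead.
- **Percentiles.** Linear-interpolation quantiles (type 7), strict `>` for
  masking, matching the reliability rule's tie-breaking.
- **L-curve.** Curvature of the (log fidelity, log regulariser) curve over
  `log10(lambda)` from smoothing-spline derivatives (df ≈ half the number of
  points; raw central differences as fallback); the corner is the maximum
  curvature magnitude; collinear curves raise a no-corner flag. The default
  grid is 10^1.0–10^3.4 in 10^0.2 steps. Curvature estimates are
  notoriously sensitive to sweep rate and solver stopping criteria; treat
  the corner as a neighbourhood, not a point.
- **Degenerate inputs.** Constant magnitude yields an all-ones edge mask
  (no edges); zero-magnitude voxels inside the ROI get zero weight with a
  warning; an effective masking percentile above 100% and an ROI too small
  for the smallest vSMV kernel are errors.

## Problem sizes used by the tests

Operator identities and oracle comparisons run at 16³; schedule, telescoping
and contrast properties at 32³ (the same 64 mm scene at 2 mm resolution);
full parameter recovery, background robustness and the unwrapping fixtures
at 64³; the lambda sweep for the L-curve shape check uses the 32³ scene at
13 grid points. The dense solver oracle assembles the one-step Gauss–Newton
normal equations as explicit 4096² matrices and solves them directly, with a
rank-one term pinning the zero-mean null space; the package solve is run at
a tight CG tolerance for that comparison so it isolates operator assembly
rather than CG truncation.

## Known limitations

- 1−SSIM rewards over-smoothed reconstructions and should be interpreted
  with caution; it is included for completeness.
- The solver is deliberately the reference quasi-Newton/CG scheme; faster
  solvers (e.g. ADMM-type) are out of scope.
- Oblique acquisitions are supported only through `b0Dir`; no resampling.
- Single field map in, single map out: multi-echo fitting, coil
  combination and brain extraction belong upstream.
- Susceptibility values are unreferenced (volume mean zero); referencing to
  a tissue (e.g. CSF) is left to the user.
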