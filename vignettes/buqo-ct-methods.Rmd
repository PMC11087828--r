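---
title: "Uncertainty quantification for structures in CT reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty quantification for structures in CT reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Computed tomography pulmonary angiography (CTPA) is the routine modality for
detecting pulmonary embolism (PE), which appears as a small dark filling
defect inside a contrast-filled pulmonary artery. Reconstructed CT images
also contain artifacts — structures created by noisy or insufficient data
and by the reconstruction algorithm itself — and some artifacts mimic PEs
closely enough that radiologists must decide, structure by structure,
whether what they see is pathology or a reconstruction effect.

`buqoct` implements a scalable Bayesian answer to that question. Instead of
sampling a posterior (hopeless at CT dimensions), it phrases the question
"could this structure be absent?" as a convex feasibility problem and solves
it with the same class of primal-dual proximal algorithms used for the
reconstruction itself.

## Model and test

Measurements follow the linear model `y = Phi x + w`, with `Phi` a 2-D
parallel-beam Radon operator (`Ma` angles equispaced over [0, pi), `D`
detector bins of pixel spacing) and `w` i.i.d. Gaussian noise whose energy
is bounded: `||w||_2 <= epsilon` with probability `quantile` (default 0.99,
a chi-square quantile bound — `epsilon_bound()`). The reconstruction is the
constrained MAP estimate

    x_dagger = argmin ||Psi x||_1   s.t.   x >= 0,  ||Phi x - y||_2 <= epsilon,

with `Psi` either the anisotropic TV analysis operator (default) or an
orthonormal Haar wavelet transform. Nonnegativity is part of the problem
so that `x_dagger` provably lies in the credible region below.

The *conservative credible region* is

    C_alpha = { x >= 0 : ||Phi x - y||_2 <= epsilon, ||Psi x||_1 <= eta_alpha },

with `eta_alpha = ||Psi x_dagger||_1 + N + sqrt(16 N log(3/alpha))`. `C_alpha`
contains at least `1 - alpha` of the posterior mass and costs nothing beyond
the MAP solve. The *structure-absent set* for a masked candidate region is

    S = { x >= 0 } ∩ { ||M x - mu_pix||_2 <= r_pix sqrt(NS) }
                  ∩ { ||M grad x - mu_grad||_2 <= r_grad sqrt(2 NS) },

where `M` selects the `NS` masked pixels. The null hypothesis — the
structure is absent from the true image — is rejected at level `alpha`
exactly when `S ∩ C_alpha` is empty, which the package decides by computing
`dist(S, C_alpha)` through the joint problem

    min 0.5 ||xC - xS||_2^2   over  xS in S, xC in C_alpha .

The scalar report is the structure confidence

    rho_alpha = ||xC_hat - xS_hat|| / ||x_dagger - Proj_S(x_dagger)||  in [0, 1],

the fraction of the structure's energy that the data insist on. The
decision applies a user tolerance `delta` (default 1e-3): reject the null
iff `rho_alpha > delta`. The package deliberately reports `rho_alpha` and
the witness images `xS_hat`, `xC_hat` together — the images carry as much
diagnostic content as the number.

## Automatic structure-set parameters

`build_structure_set()` samples an annulus around the mask (morphological
dilation minus the mask, default width 3 px, optionally restricted to a
supplied region such as the enclosing vessel): `mu_pix` is the annulus
median intensity and `r_pix = max(P60 - median, median - P40)` under the
linear-interpolation percentile convention (`quantile` type 7). The same
rule applied to the histogram of sampled gradients gives `mu_grad`,
`r_grad`; the sampled gradients are the *signed* finite-difference
components of both channels. Two choices here deserve comment:

* **Signed gradients, not magnitudes.** In a homogeneous annulus the signed
  components center near zero, so the smoothness ball demands a flat masked
  region — which is what "structure absent" means. Centering the ball on a
  positive magnitude median would instead demand a spurious intensity ramp
  inside the mask and can make `S` (numerically) empty: the energy ball
  wants a flat fill while the smoothness ball forbids it.
* **sqrt(N)-scaled radii.** The percentile spreads are per-pixel
  quantities; multiplying by `sqrt(NS)` (and `sqrt(2 NS)` for the two
  gradient channels) turns them into root-mean-square bounds whose
  tightness does not depend on the mask size. For a single-pixel mask this
  reduces to clamping the pixel into `[mu_pix - r_pix, mu_pix + r_pix]`.

With TV reconstructions the annulus can be nearly constant, collapsing
`r_pix` toward zero; the energy constraint then pins the masked pixels to
the neighborhood value exactly, which is legitimate and handled (a radius-0
ball projects to its center).

## Solver

Both the reconstruction and the set-distance problem are solved by one
generic Condat–Vu/PDHG routine (`primal_dual_solve()`) handling
`f(x) + sum_i g_i(L_i x)` with `f` given by its prox and every `g_i`
dualized. Numerical choices that matter:

* Step sizes from norm bounds with a safety factor (`step_scale` 0.95),
  the dual budget allocated proportionally to each term's norm bound, and
  over-relaxation `relax = 1.8`.
* Constraint operators in the distance problem are pre-scaled to unit norm
  (the sets are unchanged — centers and radii are divided by the same
  factor). This keeps the primal step, and with it the coupling term
  `0.5||xC - xS||^2`, from being crushed by the CT operator's norm.
* Stage 2 warm-starts: the primal pair at `(Proj_S(x_dagger), x_dagger)`,
  the S-side duals from the stage-1 projection, the data-ball dual from
  the MAP solve (rescaled), and the `eta_alpha` budget dual at zero (that
  constraint is inactive at `x_dagger` by construction).
* Convergence is declared when every constraint violation — measured as
  distance to the set relative to the set's scale, the largest of its
  radius, its center norm, and the reference magnitude of the constrained
  quantity at the MAP estimate — is below `tol_feas` (1e-4) and the mean
  per-iteration relative drift of the iterate over the last check window
  is below `tol_primal` (1e-5). The reference term matters when a
  percentile radius degenerates: without it, a floored-radius ball around
  a near-zero center demands absolute feasibility orders of magnitude
  below anything the problem can resolve.
* The distance stage stops early in one extra case: once the pair is
  feasible and its distance is below `delta` times the structure scale
  `||x_dagger - Proj_S(x_dagger)||`, the confidence can never exceed
  `delta` and the decision is fixed, so further refinement is pointless.
  No stopping heuristic based on *stability of the distance alone* is
  used: the distance trajectory exhibits long pseudo-plateaus before late
  descents, and such a rule misreports intersecting sets as separated.
* Non-convergence within `max_iters` (default 20000) is flagged and
  propagated; a flagged run never produces a decision, and its reported
  confidence is an upper bound (the pair is feasible, so its distance
  bounds the set distance from above).
* Strict inequalities in the energy/smoothness sets are implemented as
  closed balls (projections onto open sets are ill-defined; the closure
  changes nothing measurable), and the l1-ball projection resolves
  equal-magnitude ties by the common soft threshold, deterministically.
* If stage 2 stalls with a distance at the solver's resolution, the
  confidence is reported as 0 rather than a spurious positive — the
  conservative direction for the null.

The CT operator is assembled once per geometry as a sparse matrix
(pixel-driven splatting with linear detector interpolation, unit-width
strip integrals); its adjoint is the exact transpose, so the adjoint
identity holds at machine precision and the cost of `Phi` and `Phi'`
applications — the hardware-independent cost unit used throughout — is
symmetric. Cost counters are exact application counts, incremented by the
operator wrapper itself.

## Synthetic scenarios

`generate_thorax_phantom()` builds a piecewise-constant stand-in for a
contrast-enhanced thorax slice: body ellipse (0.30), two lung fields
(0.08), a spine marker (0.55), and bright circular vessel cross-sections
(0.85) placed randomly inside the lungs; a PE insert is a darker disc
inside a vessel, its intensity pulled from the vessel value toward the
lung value by the requested contrast (default 0.85). The noise convention
rescales sigma by the maximum absolute value of the noiseless sinogram, so
the reference noise regimes (sigma 0.007–0.175) transfer to synthetic
sinograms of arbitrary dynamic range.

Structure-present scenarios (`make_pe_scenario()`) probe a ground-truth PE
mask; the defect is hosted in the largest vessel so that the sampling
annulus stays inside the lumen (the stand-in for a radiologist sampling
the surrounding artery). Structure-absent scenarios
(`make_artifact_scenario()`) reconstruct a PE-free phantom from a degraded
acquisition (50 angles, sigma 0.175) and automatically select as probe a
compact blob that is dark in the reconstruction but bright in the truth —
the component, among those whose reconstruction deficit exceeds 30% of the
vessel–lung contrast, whose mean intensity falls furthest below its
surrounding annulus. Seeds that produce no such blob are retried with
derived seeds a bounded number of times, then fail loudly.

What the generator does *not* emulate: realistic artifact physics (beam
hardening, scatter, motion), anatomical texture, 3-D geometry, or masks
near the image boundary (the gradient constraint is unsuitable there).
Passing tests therefore demonstrate the statistical and numerical
machinery under controlled conditions, not clinical performance.

## Problem sizes and defaults

The package's desk scale is a side-64 image with D = 64 detectors for
end-to-end experiments (a `paper_geometry()` preset with D = 450 detectors
is available, and unit tests run at sides 8–48). Angle counts follow the
reference grid Ma in {50, ..., 450}; the cost-ratio sweep uses
Ma in {50, 100, 200} crossed with sigma in {0.007, 0.035, 0.175} with
three seeds per cell, and the data-quality trends are read along
Ma in {50, 200, 450} at sigma = 0.007 and along
sigma in {0.007, 0.035, 0.175} at Ma = 100. End-to-end suite and
reproduction-script runs use an iteration budget of 8000 per solve;
distance solves that exhaust it are flagged and carry upper-bound
confidences, which the trend statistics treat at the `delta` resolution
(values at or below `delta` count as zero confidence). Significance
defaults to `alpha = 0.01` (exposed, not asserted — the reference
experiments do not state theirs), `delta = 1e-3`, noise-bound quantile
0.99, annulus width 3 px.

## Known limitations

* The distance problem's optimum is approached to solver tolerance only;
  near-tangent sets can leave a small positive residual distance, which is
  why decisions pass through the `delta` relaxation rather than comparing
  to exact zero.
* `eta_alpha`'s printed source formula is ambiguous; the package defaults
  to the sqrt-N concentration reading and exposes the verbatim linear-in-N
  reading behind a flag. Both only rescale the l1 budget.
* The histogram rule assumes the annulus is representative lumen; masks
  touching vessel boundaries or the image edge degrade it.
* Cost ratios between the UQ stage and the reconstruction depend on both
  solvers' stopping rules and on problem scale. At the desk scale the
  warm-started reconstruction converges in roughly a thousand operator
  evaluations, while the set-distance solve is governed by the geometry of
  near-tangent convex sets and typically needs several times that; only
  scenarios resolved by the early exit or the decision floor are nearly
  free. On large problems, where reconstruction itself is the dominant
  cost, the same distance solve becomes a small fraction of it. The
  package reports exact operator-evaluation counters so the trade-off is
  always visible in the output.
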