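# buqoct

Uncertainty quantification for structures observed in computed tomography
(CT) reconstructions, aimed at the pulmonary-embolism (PE) reading problem
in CT pulmonary angiography: a dark filling defect inside a contrast-filled
artery may be a real embolism or an artifact of noisy, insufficient data.
`buqoct` runs a Bayesian hypothesis test on any masked candidate structure
and reports how strongly the measured data insist on its presence.

## Method

Measurements follow `y = Φx + w` with `Φ` a 2-D parallel-beam Radon
operator and `w` bounded-energy Gaussian noise. The reconstruction is the
constrained MAP estimate

```
x† = argmin ‖Ψx‖₁   s.t.  x ≥ 0,  ‖Φx − y‖₂ ≤ ε,
```

solved by primal-dual proximal splitting (`Ψ` = anisotropic TV by default,
orthonormal Haar as an alternative). Around `x†` the package builds the
conservative credible region

```
Cα = { x ≥ 0 : ‖Φx − y‖₂ ≤ ε, ‖Ψx‖₁ ≤ ηα },
ηα = ‖Ψx†‖₁ + N + √(16·N·log(3/α)),
```

which holds at least `1 − α` posterior mass, and a convex *structure-absent*
set `S` of images whose masked region matches the intensity and gradient
histograms of its neighborhood (energy and smoothness balls around the
annulus medians, radii from the 40th/60th percentiles). The null hypothesis
"the structure is absent" is rejected exactly when `S ∩ Cα = ∅`, decided by
computing `dist(S, Cα)` with the same primal-dual machinery. The reported
statistic is the structure confidence

```
ρα = ‖x̂C − x̂S‖₂ / ‖x† − Proj_S(x†)‖₂ ∈ [0, 1],
```

the fraction of the structure's energy confirmed by the data; the decision
rejects the null iff `ρα > δ` (default `δ = 1e-3`).

## Worked example

A structure-present scenario at low noise (50 angles, noise 0.7% of the
sinogram maximum) and a low-quality artifact scenario:

```r
library(buqoct)

sc <- make_pe_scenario(ma = 50, sigma = 0.007, seed = 1, side = 64)
print(run_test(sc))
#> structure uncertainty test [STRUCTURE_PRESENT scenario]
#>   rho_alpha = 0.5502, decision: REJECT_H0 (delta = 1.0e-03)
#>   set distance 1.136 (early exit: FALSE)
#>   cost: 35599 UQ vs 2043 reconstruction operator evals (ratio 17.425)

art <- make_artifact_scenario(seed = 11, side = 64)
print(run_test(art))
#> structure uncertainty test [STRUCTURE_ABSENT scenario]
#>   rho_alpha = 0.0001476, decision: CANNOT_REJECT (delta = 1.0e-03)
#>   set distance 0.0001695 (early exit: FALSE)
#>   cost: 715 UQ vs 2706 reconstruction operator evals (ratio 0.264)
```

In the first run 55% of the defect's energy is demanded by the data — no
image without the structure fits the measurements, so the structure is
real (it is the phantom's ground-truth PE). In the second, the probed blob
exists only in the reconstruction; an image without it lies essentially
inside the credible region (the residual distance is at the solver's
resolution, far below the decision tolerance), so the null stands.
`run_test()` also returns the witness images `x̂S`, `x̂C` and their
difference map, which are written alongside a JSON summary by the
command-line driver:

```sh
Rscript inst/cli/buqoct.R test --seed 1 --angles 450 --sigma 0.007 --out out/
Rscript inst/cli/buqoct.R sweep --config sweep.yaml
```

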