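# tmsbem — charge-based boundary element modeling of TMS-induced E-fields

`tmsbem` computes the electric field that a transcranial magnetic
stimulation (TMS) coil induces in a nested volume-conductor head model. It
is written for researchers who need many field maps from one head model —
coil placement optimization, motor mapping, dosing studies — and for
methods work that needs a transparent, oracle-tested reference
implementation of the charge-based boundary element method (BEM) in R.

## The method

A coil current pulse with drive rate dI/dt creates a primary field
E^p(r) = −(μ₀/4π)(dI/dt) Σⱼ mⱼ/|r−rⱼ| (the coil is a list of elementary
current elements rⱼ with moments mⱼ). Charge induced on each tissue
conductivity interface adds a Coulomb term, and enforcing continuity of
the normal current σ_in n·E_in = σ_out n·E_out yields a Fredholm equation
of the second kind for the scaled surface charge density ρ* = ρ/ε₀:

    ρ*(r)/2 − K(r) n(r)·∮_S (r−r′)/(4π|r−r′|³) ρ*(r′) dA′ = K(r) n(r)·E^p(r)

with conductivity contrast K = (σ_in−σ_out)/(σ_in+σ_out). Discretized with
piecewise-constant charge per triangle (exact 1/2 diagonal, analytic
facet-averaged near-field integrals, centroid monopoles far away), the
system A x = b is well conditioned and is solved two ways:

* **iteratively** — unrestarted GMRES, typically 20–40 iterations to a
  1e-6 relative residual;
* **directly** — one dense pivoted LU factorization per head model, reused
  for every coil position/orientation (each is just a new right-hand side).

Total fields anywhere follow from E = E^p + Σₙ ρ*ₙ Fₙ(r). Accuracy is
quantified with the relative 2-norm field errors
Error_total = ‖E−E′‖/‖E‖ and Error_mag = ‖|E|−|E′|‖/‖|E|‖.

Everything is verified against analytic multilayer-sphere oracles (uniform
applied field: ρ* = 3E₀cosθ and exact interior cancellation;
conductivity-profile independence and zero radial interior field under
inductive drive), so no external head data is needed. See the methods
vignette (`vignettes/charge-bem-methods.Rmd`) for the numerics.

## Worked example

A three-layer sphere head (scalp/skull/brain, radii 90/85/80 mm,
conductivities 0.33/0.01/0.33 S/m) under a figure-8 coil 5 mm above the
scalp, driven at dI/dt = 9.4e7 A/s:

```r
library(tmsbem)
sm   <- make_sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.01, 0.33),
                          subdivisions = 2)
coil <- make_figure8(didt = 9.4e7, height = 0.095)
fit  <- tms_fit(sm$model, coil, tol = 1e-6)
fit
#> TMS surface-charge fit (gmres)
#> head_model: 3 interfaces, 960 facets
#>   [1] sphere_r0.09: 320 facets, sigma_in=0.33 sigma_out=0 K=1
#>   [2] sphere_r0.085: 320 facets, sigma_in=0.01 sigma_out=0.33 K=-0.9412
#>   [3] sphere_r0.08: 320 facets, sigma_in=0.33 sigma_out=0.01 K=0.9412
#>   GMRES: 27 iterations, residual 6.72e-07
#>   rho* range [ -19.34 , 19.34 ] V/m

f <- predict(fit, points = sm$probes)   # interior probe shell
f
#> field_result: 1000 points; |E| range [ 0.3648 , 11.05 ] V/m
head(as.data.frame(f)[order(-as.data.frame(f)$mag), ], 3)
#>         x       y      z     Ex       Ey      Ez     mag
#> 1  0.0029  0.0000 0.0639 0.0000 -11.0524  0.0000 11.0524
#> 3  0.0006 -0.0064 0.0637 0.0438 -10.8846 -0.9694 10.9277
#> 2 -0.0037  0.0033 0.0638 0.1533 -10.8699  0.5157 10.8832
```

The strongest field on the probe shell (~11 V/m, a typical cortical-depth
TMS magnitude at this drive rate) sits directly under the coil crossing
and points along −y — tangentially, as induction demands. `coef(fit)`
returns ρ* per facet, `residuals(fit)` the normal-current continuity
violation (1.5 % area-weighted mean at this resolution, shrinking under
refinement), and `summary(fit)` adds the per-interface net charge
(zero to machine precision for a closed-loop coil).

For many coil placements, factor once and reuse:

```r
op   <- assemble_operator(sm$model)
fact <- factorize(op)                  # once per head model
sols <- solve_direct(fact, lapply(coils, function(cl)
          assemble_rhs(op, cl)), op = op)
```

A command-line pipeline (`inst/cli/tmsbem.R`, or `tmsbem_cli()` from R)
exposes `make-sphere`, `make-coil`, `factorize`, `solve`, `evaluate`,
`compare` and `run` subcommands over STL + JSON model files, plain-text
coil files and TSV field tables.

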