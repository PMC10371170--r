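---
title: "Charge-based BEM for TMS-induced fields: model, discretization, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based BEM for TMS-induced fields: model, discretization, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsbem)
```

## The physical model

Transcranial magnetic stimulation drives a coil with a fast current pulse;
in the quasistatic regime the electric field in the head at any instant is

$$E(r) = E^p(r) + \frac{1}{4\pi\varepsilon_0}\int_S
  \frac{r - r'}{|r-r'|^3}\,\rho(r')\,dA', \qquad r \notin S,$$

the sum of the coil's free-space *primary* field $E^p$ and the Coulomb
field of the charge density $\rho$ induced on the union $S$ of all tissue
conductivity interfaces. The charges arrange themselves so that the normal
current is continuous across every interface,
$\sigma_{in}\, n\cdot E_{in} = \sigma_{out}\, n\cdot E_{out}$, where the
one-sided fields differ from the principal-value field by the local sheet
jump $\mp n\rho/2\varepsilon_0$. Substituting gives a Fredholm integral
equation of the second kind for the charge,

$$\frac{\rho(r)}{2} - K(r)\, n(r)\cdot
  \int_S \frac{1}{4\pi}\frac{r-r'}{|r-r'|^3}\,\rho(r')\,dA'
  = K(r)\, n(r)\cdot E^p(r),
  \qquad K = \frac{\sigma_{in}-\sigma_{out}}{\sigma_{in}+\sigma_{out}},$$

with $|K| \le 1$. The identity-plus-compact structure makes the equation
well conditioned: unpreconditioned Krylov iterations converge in a few tens
of steps regardless of mesh size.

Everywhere in the package the *scaled* charge density
$\rho^* \equiv \rho/\varepsilon_0$ (units V/m) is stored, so
$\varepsilon_0$ never appears in assembled quantities and the jump term is
simply $\mp n\rho^*/2$. The primary field of a coil modeled as elementary
current elements $(r_j, m_j)$ with drive rate $dI/dt$ is
$E^p(r) = -(\mu_0/4\pi)\,(dI/dt)\sum_j m_j/|r-r_j|$, the time derivative
of the magnetostatic vector potential of the current path; $\mu_0/4\pi =
10^{-7}$ exactly in SI. Units are SI throughout (m, S/m, V/m, A/s); the
STL reader accepts a millimeter flag because head meshes commonly ship in
mm.

## Discretization

Each interface is a closed, outward-oriented triangle mesh; $\rho^*$ is
piecewise constant per facet (value $x_m$ on facet $t_m$ of area $A_m$).
Testing the equation against the indicator of each facet and normalizing by
$A_m$ yields

$$\tfrac12 x_m - K_m\, n_m \cdot \frac{1}{A_m}\int_{t_m}\!\!\sum_n x_n
  F_n(r)\, dA = K_m\, n_m\cdot \langle E^p\rangle_m,$$

where $F_n$ is the field of facet $n$ carrying unit $\rho^*$. Three
numerical choices matter:

* **Self term.** For a flat facet the principal-value field anywhere in its
  own plane is purely tangential, so the self entry is exactly $1/2$ — no
  singular integration is ever performed.
* **Near pairs** (centroid distance $\le$ `near_threshold` $\times
  \sqrt{\max(A_m, A_n)}$, default 5) use the closed-form field of a
  uniformly charged triangle — signed solid angle for the normal part
  (van Oosterom–Strackee) plus edge integrals of $1/R$ — averaged over the
  collocation facet $t_m$ with a symmetric 7-point degree-5 quadrature
  rule.
* **Far pairs** use the centroid monopole $A_n (r-c_n)/4\pi|r-c_n|^3$,
  whose error at five facet sizes is already below the discretization
  error; facet averaging is immaterial at that order and is skipped.

For edge-sharing pairs the exact facet average has an integrable log
singularity along the shared edge, which a fixed interior rule only
approximates (to roughly 15 % of those entries — entries that are
themselves small, $O(h)$, on smooth surfaces). The same rule is applied
at every refinement level deliberately: the rule error is then a
consistent part of the discretization family, cancels between levels in
self-convergence comparisons, and vanishes with $h$ in absolute terms.
A higher-order adjacent rule was evaluated and not adopted; it lowered
each level's absolute error but degraded the clean level-to-level
convergence that refinement studies rely on.

The facet averaging of the outer integral deserves a note, because pure
centroid collocation (evaluate the equation at $c_m$ only) is the simpler
textbook choice and the package exposes it as `outer_rule = 1`. On curved
surfaces the flat-facet polyhedron bends by a dihedral angle $O(h)$ just
outside each facet, and the one-point rule inherits that $O(h)$
consistency error: on a unit-field sphere benchmark the solution error
decayed only $\approx 2\times$ per 1:4 refinement. Averaging the analytic
near-field integrals over the collocation facet cancels the leading local
term — the same benchmark then gains $4$–$9\times$ per refinement — and is
what the dense and matrix-free assemblies use by default
(`outer_rule = 7`). The right-hand side applies the same rule to
$n_m \cdot E^p$.

Dense mode stores the $N \times N$ matrix (guarded by a configurable cap,
default $N \le 60\,000$); matrix-free mode stores only the sparse
near-field corrections and sums centroid monopoles pairwise on the fly at
each operator application, so memory stays $O(N)$ and the matrix-vector
product can later be swapped for a fast-multipole backend without touching
the solver.

## Solvers

`solve_iterative()` is unrestarted GMRES (Arnoldi with modified
Gram–Schmidt and Givens rotations) from a zero initial guess with a
relative-residual stop, default $10^{-6}$. On the synthetic sphere studies
it converges in 20–40 iterations, consistent with the second-kind
structure. `pracma::gmres` requires an explicit dense matrix, so the
package carries its own operator-form implementation and uses the
**pracma** one as an independent cross-check in the tests.

`factorize()` computes one pivoted dense LU decomposition (LAPACK via
**Matrix**) per head model; `solve_direct()` then serves any number of
right-hand sides — one per coil position/orientation — at the cost of
triangular solves only. An instrumentation counter
(`factorization_builds()`) lets tests assert the factor-once/solve-many
contract without timing anything. The factorization is bound to the model
by a 64-bit geometry/conductivity fingerprint and is serialized with R's
native binary format (`save_factorization()`); no HDF5 binding is required
and a reloaded factorization reproduces solves bitwise.

At desk scale the dense LU plays the role that a compressed hierarchical
inverse plays at head-model scale: the external contract (reusable
decomposition, many cheap solves) is identical, only the internal
representation differs.

## Field evaluation

Off-surface evaluation sums the same analytic-near/monopole-far facet
fields plus $E^p$. Points closer than $0.1\times$ the local facet size to
a facet centroid are rejected: naive summation is unstable there, and the
one-sided evaluator is the correct tool. One-sided fields are defined at
facet centroids (matching the piecewise-constant charge model): the self
facet contributes only $\mp n\rho^*/2$, so the out/in difference equals
$n\rho^*$ to machine precision — a structural identity the tests assert at
$10^{-14}$. The residual of the normal-current continuity condition,
area-weighted, is the post-solve diagnostic returned by
`residuals()`/`bc_residual()`; it shrinks under refinement but never hits
zero exactly on a discrete mesh.

## The synthetic study and what it does (not) show

No MRI-derived head model ships with the package; all quantitative claims
are made on concentric-sphere models, which have two independent oracles:

* **Uniform conservative field** on a single sphere in air: the
  separation-of-variables solution is $\rho^*(\theta) = 3E_0\cos\theta$
  with *exactly* zero total interior field. The package's uniform source
  is nonphysical as a coil (it is conservative) but exact for this check.
* **Inductive (coil) drive**: in any spherically symmetric conductor the
  interior total field is independent of the radial conductivity profile
  and has no radial component. Comparing a 1-shell and a 3-shell model —
  whose meshes share no facets — is therefore a genuine ground-truth-free
  accuracy check, and the interior field does *not* cancel, demonstrating
  that the solver distinguishes inductive from conservative excitation.

The default study conditions mirror a realistic TMS session at reduced
mesh size: radii 90/85/80 mm with scalp/skull/brain conductivities
0.33/0.01/0.33 S/m, a 70 mm figure-8 coil (two 35 mm loops, 64 segments
each) 5 mm above the scalp, $dI/dt = 9.4\times 10^7$ A/s, and ~1000
evaluation points on an interior shell at $0.8\times$ the innermost radius
(a stand-in for a cortical observation surface, placed well away from the
boundary so near-surface evaluation error cannot contaminate oracle
comparisons). Error metrics are the relative 2-norm errors of the vector
field and of its magnitude over an observation set; the region of interest
is a boundary-inclusive 4 cm diameter sphere under the coil.

Problem sizes were chosen so that the full test suite and the acceptance
script complete comfortably on one CPU: 1280 facets per interface
($N = 3840$, dense) for the base study, one and two 1:4 sphere-projected
refinements ($N = 15\,360$ and $N = 61\,440$, matrix-free) for
convergence references solved at tolerance $10^{-8}$.

What spheres cannot show: sensitivity to the thin, highly curved,
sometimes touching surfaces of real segmentations; anisotropic
conductivity (not modeled at all); and the absolute field values of any
particular subject. The refinement behavior and the iterative/direct
equivalence transfer, because neither depends on the geometry being a
sphere.

## Degenerate inputs and edge cases

Surfaces must be closed, oriented 2-manifolds: degenerate facets (area
$< 10^{-16}$ m² or aspect ratio $> 10^6$), repeated vertex indices,
non-manifold edges, inward orientation (negative signed volume) and
inconsistent nesting conductivities are all rejected at validation with
the offending facet/interface named. Vertex welding on STL read uses a
$10^{-9}$ m tolerance, far below any physical mesh scale. Observation
points coinciding with coil elements or triangle vertices raise
singularity errors rather than returning garbage. Zero right-hand sides
short-circuit to zero solutions in zero iterations. Touching or
intersecting interfaces are not supported: nesting is declared by the
model file's interface order, not inferred geometrically, and conductivity
consistency along that chain is checked instead.

## Known limitations

* Dense LU memory grows as $N^2$; beyond the cap only the iterative path
  is available. The matrix-free far-field sum is $O(N^2)$ per iteration —
  acceptable to $N \sim 10^5$ on one CPU, not beyond.
* On-surface quantities are facet-centroid quantities; no interpolation
  between centroids is attempted.
* The coil model is a list of current elements; skin-effect current
  redistribution must be encoded in element weights by the coil file's
  author.
* Uniform refinement only; no adaptive or ROI-selective refinement.
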