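---
title: "The mechanical inverse: inferring tensions and pressures from epithelial geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechanical inverse: inferring tensions and pressures from epithelial geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(epiforce)
library(dplyr)
```

## The model

An epithelial monolayer is idealized as a two-dimensional polygonal tiling:
cells are polygons, cell-cell interfaces are straight chords between
junction vertices, and the mechanics lives on this web. Each interface
$\langle ab\rangle$ between cells $a$ and $b$ carries an effective line
tension $T_{ab}$ (actomyosin contractility plus adhesion), and each cell a
two-dimensional pressure $P_a$ conjugate to its area. The mechanical energy
is

$$H \;=\; -\sum_{a} P_a A_a \;+\; \sum_{\langle ab\rangle} T_{ab}\,\ell_{ab},$$

and the force an interface exerts on one of its endpoint vertices is the
(minus) gradient of $H$: a pull of magnitude $T_{ab}$ along the chord
toward the other endpoint, plus half of the Young–Laplace pressure load
$(P_a - P_b)\,\ell_{ab}$ perpendicular to the chord (each endpoint carries
half). Signs are fixed by a left-cell convention: edges are stored directed
with `cell_left` on the left of the chord, the y axis pointing up.

The central assumption is *quasi-static force balance*: the tissue is close
enough to mechanical equilibrium that the interfacial forces meeting at
every junction sum to zero. Junctions are normally three-fold; higher-order
junctions (rosettes) simply sum more interface forces and are supported
throughout.

## The inverse problem

Given the observed vertex geometry, the balance conditions are *linear* in
the unknowns $q = (T, P)$: two equations per balanced junction. One extra
row fixes the arbitrary overall scale by constraining the mean tension to
one, giving the rectangular system $A q = b$ assembled by
`balance_system()` and solved by `solve_inverse()` via SVD pseudo-inverse
(minimum-norm least squares plus an orthonormal basis of the numerical
null space). Solutions are rescaled after solving so the mean implied
tension is exactly one: with a finite-weight scale row, an inconsistent
least-squares system would otherwise shrink the solution magnitude, while
the solution *direction* is independent of the scale-row weight.

Counting parameters against independent constraints gives the number of
free constants ("zero modes") that force balance can never determine:

* closed arrays (an island of cells; all junctions balanced; exterior
  pressure pinned to 0): $E + C - (2V - 3) = 4$ for three-valent arrays —
  the overall scale plus three boundary constants;
* toroidal (periodic) arrays: $E + C - (2V - 2) = 2$ — scale plus a uniform
  pressure shift;
* open arrays (a field-of-view patch; only junctions whose cells are all in
  view are balanced; interfaces bordering the out-of-view region carry no
  tension column): $E_{\rm int} + C - 2V_{\rm int}$, which for a
  well-formed three-valent patch equals the number of boundary cells plus
  one — the per-boundary-cell pressure freedoms play the role of boundary
  conditions.

These are *generic* counts, verified in the test suite against the
numerically measured null-space dimension. Two non-generic effects add
exact zero modes on top and deserve explicit mention:

* **Three-sided cells are soft modes.** For a triangle cell of *any* shape,
  its pressure and its three tensions can be adjusted jointly with no net
  force anywhere (the inscribed-circle degeneracy, of which triangles are
  the topologically guaranteed case). On generic toroidal geometry the
  measured null dimension is $\max(2,\, 1 + \#\text{triangles})$ — a rule
  the suite verifies across simulated tissues.
* **Exactly equilibrated geometry is special.** A geometry that *exactly*
  balances some tension set carries that set as an extra self-stress of the
  homogeneous system, and our Voronoi-derived tissues (below) can carry
  more than one. Real, noisy observations are generic and do not show
  this.

Because the full parameterization is badly conditioned (see below), two
reductions are provided: `constant_pressure` (pressure variation neglected;
tensions only; overdetermined least squares) and `cortical` (each interface
tension is the sum of the two adjacent cells' cortical tensions,
$T_{ab} = \zeta_a + \zeta_b$, leaving one tension-like and one pressure
parameter per cell — the reduction suited to tissues with strong per-cell
differentiation, such as sensory epithelia with two cell populations).
`solve_inverse_nonneg()` adds a tension-positivity constraint
(Lawson–Hanson nonnegative least squares after eliminating the free
pressure columns), which removes the small tail of negative tensions that
noise can produce.

## Error sensitivity

Since $b$ does not depend on the geometry, a perturbation $\delta r$ of the
vertices changes the solution to first order by
$\delta q = -A^{+}(\partial A \cdot \delta r)\,q$. `error_response()`
assembles this operator analytically (unit-chord derivatives
$(I - \hat u \hat u^{\top})/\ell$ for tension columns, a constant rotation
for pressure columns; the scale row is geometry-free), normalizes
displacements by the mean edge length, and reports its singular values as
dimensionless amplification factors; a finite-difference probe serves as
the test oracle. `sensitivity_report()` compares the full and reduced
problems on the same array.

Two observations, both reproduced by the tests at their respective scales:
the largest amplification of the full problem is *dramatically* suppressed
by parameter reduction (orders of magnitude on simulated tissues), and on
small closed arrays (tens of cells) the reduced problem also has a smaller
fraction of amplifying modes (singular values above one). At larger arrays
(hundreds of cells) that second, distributional statement inverts on our
tissue ensemble: the full spectrum concentrates into a few enormous
amplifications with a small bulk, so its *fraction* above one is small even
though its worst modes are far worse. The corresponding acceptance
assertion is left failing at the 200-cell scale rather than shrinking the
array until it passes; the fraction metric is also sensitive to how one
truncates near-zero singular values, and we deliberately use the plain
histogram mass above one.

## The synthetic-tissue generator

The in-silico validation needs equilibrium tissues with *known* tensions.
The generator (`generate_voronoi_tissue()`) draws uniform random seed
points in a periodic box of area equal to the cell count, tessellates them
with a periodic Voronoi diagram (implemented by half-plane clipping against
the 3×3 tiled neighbours; no computational-geometry dependency), and
assigns the *reciprocal* tension set

$$T_{ab} = |s_a - s_b|,$$

the distance between the two generating seeds (periodic copies taken
nearest the interface midpoint), normalized to mean one. By the reciprocal
(Maxwell–Cremona) correspondence between a Voronoi tessellation and its
Delaunay dual, this geometry is an *exact* equilibrium of the tension-only
energy: the three dual-triangle sides meeting at a junction, rotated by
90°, are exactly the three interface force vectors. Generated tissues have
verification residuals at rounding level ($\sim 10^{-13}$ of the mean
tension), uniform pressure (no area term in the energy), and a realized
tension coefficient of variation of about 0.48 (narrowing with optional
Lloyd regularization steps, `lloyd_iterations`).

Why not draw i.i.d. uniform tensions and relax, which sounds more natural?
Because a tension set drawn independently of the topology is *generically
incompatible with any straight-edge equilibrium*: gluing the per-junction
tension triangles into a consistent reciprocal diagram imposes a $2\pi$
angle-sum constraint around every cell, which i.i.d. tensions violate with
probability one. We verified this empirically at every spread from ±5% to
±50%: relaxation either stalls at frustrated junctions (a tension
exceeding the sum of its partners can never balance), drives runaway
regional collapse, or demands wholesale topological rearrangement. The
interface (`tension_distribution = c(lo, hi)`) is retained for
experimentation and aborts with an informative error. The relaxation
engine itself — capped Barzilai–Borwein descent through the rough
transient, an L-BFGS finish in the smooth regime with a revert-on-tangle
safeguard, rosette fusion for provably collapsing interfaces and cluster
extinction (T2) for dying cells, all moves irreversible — is exercised by
perturb-and-relax-back tests.

Anisotropic benchmark tissues are built by mapping the seed points with
$\mathrm{diag}(\lambda, 1/\lambda)$ *after* two Lloyd steps (`stretch`
argument): the local order introduced by Lloyd is what the stretch deforms
(an affinely mapped Poisson process is statistically unchanged, so
stretching unordered seeds does nothing). $\lambda = 1.25$ gives an
along/across tension-gap of roughly 15% relative to the compressed axis,
with exact equilibrium preserved.

What the generator deliberately does not emulate: curved interfaces (the
polygonal approximation is the model), pressure heterogeneity (no area
term), cell divisions or rearrangement dynamics, and the particular tissue
ensemble of any real embryo. Passing benchmarks therefore demonstrate
correctness of the inverse on exactly-equilibrated polygonal tissues with
reciprocal tension statistics — not performance on any specific imaging
dataset.

## The noise benchmark

`corrupt_vertices()` displaces every vertex by isotropic Gaussian noise
whose r.m.s. *magnitude* is a stated fraction of the mean edge length
(per-coordinate $\sigma = f\bar\ell/\sqrt2$), emulating segmentation and
biological positional error. `noise_curve()` runs the full protocol: per
replicate, generate a 400-cell tissue, corrupt at each level, run the
constant-pressure inverse, and record the Pearson correlation between true
and inferred tensions (both rescaled to mean one, as in
`recovery_scatter()`). Replicate seeds are derived deterministically from
the experiment seed.

On this ensemble the mean correlation is about 0.6 at 5% noise and about
0.5 at 10% (computed by `scripts/acceptance.R`; noiseless recovery is exact
to $r > 0.999$ and the degradation with noise is strictly monotone on
every seed). Error analysis shows why the absolute level sits below what
one might hope: the inference error concentrates in smooth, weakly
constrained long-wavelength modes (cell-averaged error carries ~80% of the
error standard deviation), and the reciprocal tension field — the only
ensemble that can be equilibrated exactly — is itself spatially smooth, so
signal and error overlap where the operator is weakest. A spatially rough
(i.i.d.) tension field would fare better, but no such field admits an
equilibrium tissue to benchmark against (see above). Sub-resolution
interfaces (shorter than the noise displacement) contribute garbage rows;
`fuse_short_edges()` can fold them into rosettes before inference, which
helps only marginally (~0.03 in $r$), confirming the smooth-mode picture.

## Downstream analyses

* `edge_tractions()`: the shear (traction) force transmitted across an
  interface, borne by the adhesion molecules coupling the two cortices.
  Cortical-tension continuity around each cell corner determines the
  per-cell cortical shares from the interfacial tensions, giving
  $\tau_{ab} = \tfrac12 (T_{ad} + T_{bc} - T_{ac} - T_{bd})$ with $c$ and
  $d$ the third cells at the two endpoints. The sign is tied to the stored
  edge axis; the test oracle solves the per-corner continuity systems
  independently. Uniform tension gives zero traction everywhere; rosette
  endpoints yield `NA`.
* `laplace_check()`: the inverse never uses interface curvatures, so
  measured curvatures give an independent validation via the Laplace law
  $P_{\rm left} - P_{\rm right} = T\kappa$ (curvature signed positive
  bowing away from the left cell). Reports the per-edge table, Pearson
  correlation, and through-origin slope; zero-variance inputs are flagged
  degenerate rather than producing a meaningless correlation.
* `anisotropy_report()`: splits interfaces by the acute angle between
  chord and a caller-supplied tissue axis (threshold π/4 by default,
  splitting the quadrant symmetrically; ties go to the "across" group) and
  reports group tension means, their ratio, empirical CDFs and a rank-based
  (Wilcoxon) two-sample test — rank-based because no distributional form is
  assumed.

## Numerical choices

* SVD cutoff for rank/null-space decisions: $10^{-8}$ of the largest
  singular value (configurable). The same pseudo-inverse backs the solver,
  the nonnegative solver's projection, and the error-response operator.
* Degenerate inputs: edges shorter than $10^{-9}$ of the mean edge length
  are rejected at validation; self-intersecting loops raise geometry
  errors; toroidal boxes must exceed three mean edge lengths so the
  minimum-image convention is unambiguous.
* Voronoi construction: corners are identified by their generating seed
  triple plus position (tolerance $10^{-7}$ of the box); cocircular
  degeneracies are retried with jittered seeds and a warning.
* Relaxation: convergence is declared when the maximum net junction force
  falls below `tol` (default $10^{-7}$) times the mean tension; the
  BB phase caps per-step vertex motion at a fraction of the shortest live
  edge to prevent tunnelling; collapse surgery fires only at descent
  stalls on interfaces that carry the stalled residual, never on transient
  dips.
* Benchmark sizes are chosen to keep the full suite within a few minutes:
  400 cells × 10 replicates for the noise curves, 200 cells for the
  spectrum comparison, 100-cell tissues for patch extraction, honeycombs
  for closed-form fixtures.

## Known limitations

* The tension ensemble is dictated by exact equilibrium (reciprocal set);
  correlations measured on differently generated tissues, or on real
  segmented data, can differ substantially in either direction.
* Tension and interface length are negatively correlated (about −0.4) in
  this ensemble; it is a property of equilibrated tension-only tilings,
  not an artifact of the inverse.
* Curvature is accepted as input only; no arc fitting from images is
  provided, and no image segmentation at all.
* No viscous/dynamic term: the inverse treats each snapshot as an
  independent quasi-static problem.
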