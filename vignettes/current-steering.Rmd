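---
title: "Modeling and steering tDCS electric fields toward cerebellar lobules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and steering tDCS electric fields toward cerebellar lobules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldsteer)
```

## The physical model

Transcranial direct-current stimulation (tDCS) injects weak direct
currents (up to a few mA) through scalp electrodes. At these
frequencies the head behaves as a purely resistive volume conductor,
so the potential obeys the quasistatic current-flow equation

$$\nabla\cdot(\sigma\nabla\Phi) = 0 \quad \text{in } \Omega,$$

with Neumann boundary conditions: the prescribed normal current
density $\sigma\nabla\Phi\cdot\hat n = J_e$ under the electrode
patches, and $\sigma\nabla\Phi\cdot\hat n = 0$ elsewhere on the
scalp. The electric field is $\vec E = -\nabla\Phi$; its magnitude
(`Enorm`, V/m) and its components along the RAS axes (X mediolateral,
Y posteroanterior, Z inferosuperior) are the quantities the package
reports per brain region. The solution of the Neumann problem is
unique up to an additive constant; the package fixes the gauge as
zero mean over the scalp-surface nodes.

Cerebellar tDCS is the motivating application: the cerebellar cortex
is strongly folded, lobules differ in function (motor control of the
lower limb maps to the posterior-inferior lobules VII--IX), and
published two-electrode montages deliver rather non-focal fields. The
package therefore couples a forward model (FEM over a tissue-labeled
head volume) to an atlas-style region extraction and a convex
current-steering optimizer.

## The synthetic phantom and what it does (not) emulate

Real subject pipelines segment MRI into scalp, skull, CSF, gray and
white matter. Here every stage runs instead on a synthetic
multi-shell spherical phantom (`build_shell_phantom()`): concentric
shells with the standard isotropic conductivities (scalp 0.465,
skull 0.010, CSF 1.654, gray matter 0.276, white matter 0.126 S/m).
The default shell radii (92, 86, 81, 79, 67 mm) are arbitrary but
anatomically ordered and of plausible thickness; they are
configuration defaults, not subject measurements.

The mesh is built by extruding an equiangular cubed-sphere surface
triangulation radially between discrete radial levels aligned exactly
with the shell interfaces, splitting each triangular prism into three
conforming tetrahedra (with the vertex-id-ordering diagonal rule) and
closing the innermost level with a fan to the center. Every shell
receives at least one full element layer regardless of the target
resolution, so even the 2 mm CSF shell is always represented;
constructions whose elements would become too flat (angular size many
times the thinnest shell) are rejected. The default target edge
length is 8 mm (about 144k tetrahedra), chosen so that a full
lead-field assembly runs in well under a minute while keeping the
interior potential error against the analytic solution below one
percent (see below).

A pseudo-cerebellum stands in for an atlas parcellation
(`build_parcellation()`): the posterior-inferior quadrant
($y<0, z<0$) of the gray-matter shell is tiled into 28 wedge regions
that mimic cerebellar atlas topology — 10 lobule bands (I--IV, V, VI,
Crus I, Crus II, VIIb, VIIIa, VIIIb, IX, X) for the left and right
hemispheres plus a midline vermis strip for the eight lower bands.
All remaining gray/white voxels form the pooled non-cerebellar brain
mask, giving 29 regions in total. Voxels are 1 mm$^3$ by default and
the labeling is purely analytic, hence deterministic.

What the phantom deliberately does *not* emulate: cortical and
cerebellar folding, anisotropic conductivity (white matter and skull
are strongly anisotropic in reality), subject-to-subject geometric
variability, and the true SUIT atlas geometry. Tests that pass on the
phantom therefore validate the *numerics* of the pipeline — solver
correctness, superposition, extraction, optimization — not the
anatomical accuracy of any particular field prediction. Real-head
conclusions additionally require a segmented subject model, which is
out of scope here.

## Verification against a closed-form solution

For concentric spherical shells the current-flow problem has a
Legendre-series solution (`potential_multishell()`): per harmonic
degree $n$ the radial factor in each shell is
$A_j (r/R)^n + B_j (r/R)^{-(n+1)}$, with coefficients fixed by
continuity of $\Phi$ and of $\sigma\,\partial\Phi/\partial r$ at the
interfaces, regularity at the center, and the point-electrode Neumann
expansion $I(2n+1)/(4\pi R^2)$ at the surface. Two numerical choices
matter: coefficients are rescaled per shell so that every power
entering the interface system is at most one in magnitude (the naive
form becomes numerically singular near degree 100), and the default
truncation (100 terms, with the last-degree contribution reported)
resolves interior points far better than 1e-8 — the point-electrode
series converges slowly only near the surface.

The FEM solver is verified against this oracle on the homogeneous
sphere with antipodal 1 cm disc electrodes at ±1 mA: at the default
8 mm resolution the relative L2 error of interior potentials
(sampled on shells at 0.2--0.8 of the radius, i.e. at least one
electrode diameter from the scalp, where the patch/point distinction
is negligible) is below 1%, and it decreases under uniform
refinement. The oracle uses point electrodes; FEM patches distribute
each electrode's current over the scalp facets within the electrode
radius proportionally to facet area — a deliberate simplification
(no contact impedance, no sponge/gel volume) that preserves the
injected current and the current density, the quantities the
downstream analysis consumes.

## Solver choices

The stiffness operator is the standard first-order tetrahedral
assembly, symmetric positive-semidefinite with the constant vector as
nullspace (units S/m and mm, so mA loads yield volts). Two solution
paths exist:

* `method = "cholesky"` (default): sparse supernodal Cholesky of the
  grounded system, then re-gauging to zero mean over scalp nodes.
  This is exact to roundoff — reciprocity and superposition hold at
  machine precision — and the factorization is reused across the many
  load vectors of a lead-field assembly, which is why it is the
  default rather than an iterative method.
* `method = "cg"`: deflated Jacobi-preconditioned conjugate
  gradients (relative residual 1e-8, at most 10,000 iterations),
  which never forms a factor and is preferred for the largest meshes
  (the refinement studies use it). Deflation projects the constant
  mode out of the iteration instead of grounding a node.

Either way the returned potentials carry the same scalp-mean gauge,
so the two methods agree to the iterative tolerance.

## Region extraction

Element fields are constant per first-order element, so rasterization
assigns each voxel the field of the element containing its center —
containment is exact for this element type, and no interpolation is
introduced. Point location uses the phantom's structured
parameterization (radial slab plus cubed-sphere cell, then exact
barycentric tests over the handful of candidate tetrahedra); voxels
on a chordal face within tolerance keep the nearest candidate, a
face-adjacent element whose field differs by O(h). Voxels outside the
mesh are masked as invalid, which is distinct from a zero field.

Region summaries (`lobule_means()`) are unweighted voxel averages of
Ex, Ey, Ez and of the per-voxel magnitude `Enorm`. Averaging
magnitudes rather than taking the magnitude of the mean is a
deliberate choice: it makes the summaries monotone
($\overline{\|E\|} \ge \|\overline{E}\|$, asserted in the tests) and
matches how field-strength tables are usually reported. Voxel-uniform
weighting (rather than element weighting) is fixed as the package
convention.

## Lead field and montage optimization

With linearity, the map from electrode currents to region-averaged
fields is a matrix per direction: `assemble_leadfield()` simulates
one bipolar montage per catalog electrode (+1 mA against the common
vertex reference at −1 mA, 1 cm discs) and stacks the region means as
columns of $LF_X, LF_Y, LF_Z$ (units (V/m)/mA). Predictions for any
zero-sum current vector follow by superposition and close against a
direct FEM solve of the same montage to better than 1e-6 relative.
The reference electrode needs no column; re-assembling against a
different reference changes columns but not predictions.

`optimize_montage()` solves the current-steering problem

$$\arg\min_x \|W\,(LF\,x - b)\|_2^2
\quad\text{s.t.}\quad \textstyle\sum_n x_n = 0,\;
\sum_n |x_n| \le 4\ \text{mA},$$

i.e. a desired region-field pattern $b$ under zero net current and a
total-current safety cap (4 mA total magnitude, hence at most 2 mA
total anodal). The L1 constraint is handled exactly by variable
splitting $x = p - q$, $p, q \ge 0$, giving a convex quadratic
program; a tiny ridge keeps the split (singular) Hessian strictly
positive definite for the QP solver, and an equality-constrained
polish on the detected active set removes the ridge bias, so the
solution matches a brute-force search to high accuracy. When the
unconstrained least-squares solution already satisfies the cap it is
returned directly (this is how a feasible planted target is recovered
to numerical precision). Returned solutions always satisfy the
constraints exactly: the reference current is set to the negated sum
and the vector is rescaled in the (rare) event of cap overshoot by
roundoff.

Design choices left open by the problem and fixed here:

* **Per-direction optimization is the default** (one montage per
  field direction); a stacked joint fit over several directions is
  available via `stacked = TRUE`.
* **No default target magnitude** is baked into the API —
  `uniform_target()` requires one. The demonstrations in this package
  use 0.3 V/m on the right posterior-inferior lobules; achieved
  fields scale with available current, so users should read the
  result as field-per-mA and rescale.
* **Region weights** default to 1 everywhere (`spillover_weight`),
  so off-target regions are penalized toward zero field at equal
  weight. Setting `spillover_weight = 0` ignores them entirely.
* **No per-electrode cap by default**: the safety statement
  constrains the totals; a per-electrode bound is available as an
  option.
* **Sparsification** (dropping electrodes below 1% of the cap and
  re-solving) is off by default; no cardinality constraint is
  imposed.

The electrode catalog default covers the scalp cap to 150° from the
vertex. This is intentional: cerebellar targets sit
posterior-inferiorly, and steering toward them requires candidate
positions below the inion line, as whole-head EEG-derived electrode
catalogs (and practical cerebellar montages, whose return electrodes
sit on the cheek or neck) provide. With adequate coverage, optimizing
a uniform field on the right lobules VIIb--IX places the peak
predicted field magnitude inside the target set; with sparse or
high-riding catalogs the peak drifts to adjacent bands (I--IV or X),
which is a faithful reflection of the physics, not a solver artifact.
The hotspot demonstration in the test-suite uses a 24-electrode
catalog for this reason; with hundreds of candidates (as a full EEG
catalog provides) the targeting sharpens further.

## Statistics layer

`field_observations()` turns a field volume plus parcellation into a
long table with one row per cerebellar voxel; `anova_eta()` fits the
fixed-effects linear model over the requested factors (lobule,
montage, head model; main effects plus pairwise interactions by
default) and reports classical eta-squared effect sizes
$\eta^2 = SS_{\text{term}} / SS_{\text{total}}$ — not partial
eta-squared, so the values of all terms are comparable and bounded by
one. Type III sums of squares (with sum-to-zero contrasts) are the
default because lobule voxel counts are inherently unbalanced; on
balanced designs all types coincide (asserted in the tests), and for
saturated or constant-response fits the implementation falls back to
the sequential decomposition, which is exact there. The observation
unit — one voxel, one row — is a package convention; voxel counts in
the tens of thousands make the p-values essentially decorative, and
the effect sizes are the quantity of interest.
`bonferroni_posthoc()` performs all pairwise mean comparisons at
Bonferroni-adjusted critical values from the fitted model's residual
variance.

## Degenerate inputs and numerical edge cases

* Montages with unbalanced currents are rejected (Neumann
  compatibility); a zero-current montage returns identically zero
  fields without solving.
* Electrodes too small to capture any scalp facet centroid couple to
  the nearest facet, so every electrode always maps to at least one
  facet.
* Regions with zero valid voxels, grids that do not overlap the
  mesh, mismatched field/parcellation affines, unknown region or
  electrode names, non-positive caps and empty ANOVA design cells
  are all rejected with messages naming the offending entity.
* The optimizer returns $x = 0$ with a note when the lead field is
  numerically rank-zero.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic
data built at run time: unit tests use a 14 mm phantom with 2 mm
voxels and a 6-electrode catalog; the end-to-end checks use the
default 8 mm phantom with 1 mm voxels (about 144k tetrahedra, 25k
nodes, 6.5M voxels), an 8-electrode catalog for the constraint and
superposition checks, a 24-electrode catalog for the targeting
demonstration, and one uniform refinement to 4 mm (about 1M
tetrahedra, solved by CG) for the convergence check. These sizes were
chosen as the smallest at which the verification gates hold with
comfortable margin.

## Known limitations

* Isotropic conductivities only; anisotropy (skull, white matter)
  changes cerebellar field estimates substantially and is not
  modeled.
* The spherical phantom has no folding: region-level fields on real
  anatomy depend on gyral geometry that the phantom cannot represent.
* Electrode patches are pure Neumann current sources; contact
  impedance and sponge volumes are not modeled.
* The pseudo-cerebellar parcellation preserves topology
  (left/right/vermis, superior-to-inferior band order), not the
  shapes or volumes of real lobules.
* Optimized montages are phantom-specific; on a subject head model
  the same pipeline applies but the currents will differ.
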