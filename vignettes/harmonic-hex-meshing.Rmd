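---
title: "Harmonic-field hexahedral meshing and orthotropic finite elements for scleral shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic-field hexahedral meshing and orthotropic finite elements for scleral shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmonichex)
```

## The problem

The posterior sclera — the stiff collagenous shell at the back of the eye —
is the load-bearing tissue through which intraocular pressure (IOP) acts on
the optic nerve head (ONH).  Finite-element studies of scleral biomechanics
want three things that are awkward to get together: (i) an all-hexahedral
mesh of a patient-specific, variable-thickness shell (thickness varies
roughly 3:1 between the posterior pole and the equator), (ii) mesh vertices
that lie exactly on the measured surfaces, and (iii) per-element material
axes for the predominantly circumferential collagen fibre architecture
around the ONH canal.

`harmonichex` implements a mesher that delivers all three from a single
construction.  A harmonic scalar field is solved on each bounding triangle
surface with Dirichlet values 0 on the ONH canal ring and 1 on the equator
ring.  Because a harmonic field has no interior extrema, its gradient
streamlines flow smoothly from one ring to the other; streamlines traced
from evenly spaced equator seeds, intersected with isocontours at evenly
spaced field values, tile each surface with a structured quadrilateral grid.
Stacking the outer grid, an interpolated mid-surface grid and the inner
grid yields hexahedra directly — no post-smoothing, no projection of a
template block mesh.  The same field supplies the material frames: the
isocontour tangent is the circumferential fibre direction, the gradient the
meridional one, and their cross product the thickness direction.

## The harmonic field

On a triangulated surface the Laplacian is discretized with the cotangent
("discrete harmonic") weights `w_ij = (cot a_ij + cot b_ij) / 2`, where the
two angles face edge `(i, j)` from its incident triangles; boundary edges
use their single cotangent.  Eliminating the constrained rows gives a
symmetric positive-definite sparse system, solved directly (sparse
Cholesky) up to 50,000 unknowns and otherwise by Jacobi-preconditioned
conjugate gradients to a relative residual of `1e-10`.  The direct default
makes small test cases reproducible to machine precision; the tolerance and
switch-over are engineering choices, not data-derived.

Obtuse triangles give negative cotangent weights.  They are kept — the
operator is the standard one — and their count is reported on the solved
field; an optional clamp is available but off by default, since clamping
changes the operator.  The discrete maximum principle (extrema only at
constrained vertices) is asserted in tests on the fixture meshes used here,
where it holds despite the flagged negative weights.

```{r field}
fix <- make_sclera_fixture(sclera_fixture_spec(n_circumferential = 48,
                                               n_meridional = 24))
f <- solve_harmonic(fix$outer)
f
```

## Tracing and mesh assembly

Because the interpolated field is linear per triangle, its gradient is
piecewise constant, and streamline integration is exact: inside a triangle
the path is a straight segment to the exiting edge, and the crossing point
transfers to the neighbour.  No Runge–Kutta stepping or step-size tuning is
involved.  Vertex hits are resolved by a deterministic `1e-12` nudge toward
the triangle interior; a trace that immediately re-crosses the same edge
(possible on obtuse configurations) escapes through the lower-valued edge
endpoint.  Traces stop at field value `1e-3` or at the canal boundary and
are then snapped onto the canal ring, so the mesh boundary lies exactly on
the input boundary.

Grid rows sit at evenly spaced field values — spacing even in scalar value,
not arc length — with the first and last rows resampled on the equator and
canal rings themselves.  The inner surface is seeded at the same normalized
arc-length parameters as the outer surface, with the phase chosen to
minimize the summed distance between matched equator points; this makes the
outer, middle and inner grids share one topology, which is what lets the
layers be stacked into hexahedra.  The mid-surface node layer is the exact
midpoint of matched outer/inner nodes, giving two element layers through
the thickness by default (`n_layers` generalizes this).

Conversion to 20-node serendipity elements adds one shared mid-edge node
per unique edge; mid-nodes of edges lying in the outer (inner) surface are
projected back onto that surface so the quadratic geometry follows the
curvature.  One practical guard: on a thin shell the projection sagitta of
a circumferential chord must stay below about half the layer thickness, or
the curved face folds through the element.  For the default fixture
(12 mm radius, 0.38 mm equatorial thickness, 2 layers) this means at least
about 26 streamlines; the package default of `n = 40` is comfortably above
it, and the constructor rejects folded elements by checking scaled
Jacobians.

Mesh quality is reported as dihedral-angle distortion: for each of the 12
edges of each hexahedron, the angle between the two adjacent bilinear
faces, evaluated from their outward normals at the shared edge midpoint,
minus 90 degrees in absolute value.  The estimator is chosen so a perfect
cube scores exactly zero; whether the reference statistics were tallied
per-edge or per-element is not documented anywhere we know of, so the
per-edge convention is used and stated.  On the default fixture all
distortions fall below 10 degrees (mean about 2.4, maximum about 7),
comfortably inside the published bounds for the method (at least 85% below
20 degrees, mean 7.8, maximum 43) — expected, since the synthetic fixture
is smoother than a scanned eye.

## The synthetic fixture

No scan is distributed with this package, so a synthetic two-surface
fixture stands in for it (and is labelled synthetic throughout).  The outer
surface is the posterior hemisphere of radius 12 mm — an adult eye is about
24 mm across — with a canal hole of geodesic radius 1.75 mm whose centre
sits 15 degrees off the posterior pole, encoding the observation that the
ONH is not at the pole.  The inner surface offsets each outer vertex
inward along the radial normal by a thickness that blends 1.1 mm at the
pole to 0.38 mm at the equator with a squared cosine in polar angle: only
the endpoint thicknesses are constrained by measurement, and the squared
cosine is the simplest smooth monotone blend with zero slope at both ends.
The mesh is generated in canal-centred spherical coordinates so that both
boundary rings are exact circles and every vertex lies exactly on the
sphere.  Optional seeded tangential jitter breaks the symmetry for
robustness testing; with the canal at the pole and zero jitter every
downstream quantity is rotationally symmetric, a strong end-to-end check
that the test-suite asserts to `1e-6`.

What the fixture does *not* emulate: scan noise, asphericity, local
thickness anomalies, and the ONH tissue plug itself.  Passing tests on the
fixture therefore demonstrate the correctness of the algorithms — exactness
of the tracing, mesh validity, solver convergence — not the clinical
accuracy of any particular eye model.

## Orthotropic elasticity

Material frames are assigned at each element centroid's projection onto the
outer surface: `y` is the interpolated field gradient normalized and
oriented toward the canal (meridional), `z` the interpolated outward
normal re-orthogonalized against `y` (thickness), and `x = y × z`
(circumferential, aligned with the isocontour winding).  Normals and
gradients are area-weighted vertex averages interpolated barycentrically,
which keeps the frames smooth on a faceted surface.

The elastic constants are `E_x = 8.6`, `E_y = 6`, `E_z = 2.5` MPa with a
single Poisson ratio 0.49 (near-incompressible; 0.5 itself would be
numerically singular), applied to all three coupling pairs with reciprocal
counterparts from symmetry.  Shear moduli are not available from the same
measurements; the closure `G_ij = sqrt(E_i E_j) / (2 (1 + nu))` is used
because it is the minimal rule that recovers the exact isotropic shear
modulus when the moduli coincide, and it yields a positive-definite
stiffness for these constants (verified at construction).  The isotropic
comparison material is `E = 3.8` MPa, the average of upper and lower
directional bounds of the orthotropic constants.

The fibre-rotation family r1..r10 rotates `x` and `y` about `z` by a
region-dependent angle: peripheral fibres by `min(10 k, 90)` degrees and
peripapillary fibres by ten degrees less (r1 = 0/10, r2 = 10/20, r3 =
20/30, ..., r10 = 80/90).  The published angle sequence pins down r1, r2,
r3 and r10; the capped linear rule above is the only one that matches all
four printed pairs, at the cost of r9 and r10 coinciding.  Canal-adjacent
elements rotate with the peripapillary angle, and the rotation is a hard
switch at the band boundary (a smooth blend exists as an option but is off
by default, matching the discrete per-region description).  Region bands
are field-value thresholds `u < 0.15` (ONH-adjacent), `0.15 <= u < 0.45`
(peripapillary), else peripheral — the region names are standard but their
quantitative boundaries are not published, so these defaults are package
choices, configurable in `label_regions()`.

The solver is deliberately linear (small strain): stiffness from 20-node
serendipity shape functions with full 3×3×3 Gauss quadrature (8-node path:
2×2×2 with mean-dilatation B-bar to suppress volumetric locking at
`nu = 0.49`), consistent pressure forces on the undeformed quadratic faces
(follower effects ignored, consistent with linearity), a deterministic
sparse Cholesky solve, and strain/stress recovery at the quadrature points.
IOP converts as 1 mmHg = 133.3224 Pa.  All of the comparative conclusions
the package reproduces are orderings and locations; a geometrically
nonlinear shell would change magnitudes but needs assumptions (constitutive
law, load stepping) that are out of scope here, and the linearization is
stated rather than silently approximated.

```{r solve, eval = FALSE}
shell <- build_shell_mesh(make_sclera_fixture(), n = 40, m = 34)
res <- solve_shell_model(shell, "r0", iop_mmhg = 30)
region_maxima(res, shell$labels)
```

## Validation oracles

* **Cylinder**: the harmonic field on a right cylinder with rims at 0 and 1
  is exactly linear in height on the symmetric triangulation; streamlines
  are vertical lines of length equal to the height.
* **Planar annulus**: the continuum solution is `log(r/r_in) /
  log(r_out/r_in)`; the discrete field matches within 2% and converges
  under refinement; streamlines are radial rays.
* **Patch test**: single- and 8-element distorted blocks under affine
  boundary displacement reproduce the constant strain state to `1e-9` for
  both element orders.
* **Lamé thick sphere**: an octant of a spherical shell under internal
  pressure (meshed independently of the harmonic mesher by a three-block
  decomposition of the spherical triangle — a single mapped block would
  degenerate at the pole) converges monotonically to the closed-form radial
  displacement, within 2% at the finest tested resolution.
* **Global equilibrium**: reactions balance applied loads to `1e-8`
  relative on every solve.
* **Frame independence**: an orthotropic material with equal moduli
  assembled with random per-element frames reproduces the frame-free
  isotropic solution to `1e-9`.

## Problem sizes and determinism

The default study meshes the fixture at `n = 40` streamlines and `m = 34`
levels (2,640 twenty-node elements, about 44,000 degrees of freedom) and
solves twelve models (isotropic, perfect circumferential, r1..r10); the
mesh-sensitivity check refines to `n = 60`, `m = 51` (6,000 elements).
These sizes reproduce the published element-count scale for the method
while keeping a full run on a single CPU in minutes.  The test-suite uses a
coarser fixture (48×24 surface grid, 28×14 mesh) for everything that does
not need the production resolution.  Every stage is deterministic for a
fixed seed: the only randomness is the optional fixture jitter, and the
pipeline manifest hashes are reproducible run-to-run.

## Known limitations

* Geometric and material nonlinearity, viscoelasticity and fibre-dispersion
  constitutive models are out of scope; magnitudes from the linear solver
  should not be read as clinical predictions.
* The global maximum principal stress of the clamped-equator shell sits at
  the clamp corner — a stress concentration that sharpens under refinement,
  so that quantity is mesh-sensitive by nature; displacement-based metrics
  converge cleanly.
* The mesher assumes the annular two-ring topology; surfaces with other
  boundary structures are rejected rather than guessed at.
* On very coarse meshes of thin shells the 20-node mid-node projection can
  fold elements (see the sagitta guard above); the mesher detects and
  reports this rather than repairing it.
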