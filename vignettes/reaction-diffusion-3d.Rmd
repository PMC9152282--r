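---
title: "Methods: 3D intracellular reaction-diffusion on neuron morphologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D intracellular reaction-diffusion on neuron morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxd3d)
```

## The problem

Neuron morphologies are reconstructed as trees of point-diameter samples
`(x, y, z; d)`. That representation is sufficient for electrophysiology and
for 1D ("cable") chemical simulation, but it under-determines the 3D shape
that chemical dynamics see wherever radial symmetry breaks down: near the
soma, between neighboring spines, or at a branch point where a wave front
curves. `rxd3d` turns a point-diameter tree into a consistent watertight 3D
volume, discretizes it into cubic voxels, and advances reaction-diffusion
kinetics on that domain, optionally coupling selected 3D regions to a 1D
cable model of the rest of the cell and to membrane mechanisms (ion
channels, synaptic fluxes) that live on the electrical segments.

Units throughout: micrometers, milliseconds, millimolar. One mM·µm³ equals
1e-18 mol, i.e. 602 214.076 molecules.

## Geometry: frusta, join spheres, and voxels

Consecutive point-diameter samples define the frustum of a right circular
cone; the cell volume is the union of these frusta and of join spheres that
smooth the connections. Before any solid is built, extra points are
interpolated at electrical-compartment ("segment") boundaries at arc
fractions `k/nseg`, so every frustum belongs to exactly one segment; voxels
in regions claimed by several segments are assigned to the segment closest
to the root of the tree, which keeps membrane currents attached to the
correct compartment.

The join rule is a design point the reconstruction literature leaves open
(the published clip rules depend on taper and intersection angle). `rxd3d`
places a sphere at interior polyline points and at end-attachments, with
radius equal to the larger adjacent end radius, clipped to the wedge between
the two adjacent end-face planes. Two consequences we consider important:
for collinear equal-radius joins the wedge is empty and the sphere
contributes nothing (a straight polyline cylinder is exactly a cylinder),
and at a bend the wedge exactly fills the outer gap between the two
cylinder end faces. Where a child section attaches to its parent's end with
a different diameter, a connection cone is added from the attachment point
(parent radius) to the midpoint of the child's first segment (child
radius); this reproduces the tapered junction visible in stepped-diameter
geometries. With these rules the three-arm Y benchmark (arms of length
10 µm and diameter 2 µm meeting at 30°) stores exactly 7,904 voxels at
dx = 0.25 µm.

Voxelization evaluates each convex object's signed distance on the corner
lattice of the object's padded bounding box. A voxel is stored iff at least
one corner lies inside the union (so the volume estimate is never zero); it
is a *surface* voxel iff at least one corner also lies outside. The signed
distance of a frustum is exact (the 2D distance to its generating trapezoid
in the axial-radial half-plane); clipped spheres use the max of sphere and
plane distances, which is exact inside. The grid origin is snapped to a
multiple of dx with two voxels of padding, so fixtures re-voxelize
bit-identically. Storage is sparse (hash-indexed integer keys), so memory
scales with the neuron's volume rather than its bounding box.

Degenerate alignments deserve a note: when a surface passes exactly through
lattice corners (an axis-aligned cylinder of integer radius), the
boundary-point convention — distance ≤ 0 counts as inside — is applied
consistently, and fixture generators snap roundoff-level axis components to
zero so that a nominally axis-aligned cylinder is exactly axis-aligned.
A 1e-16 tilt would otherwise make on-surface corners flip inconsistently
along a column.

### Partial volumes and surface areas

Surface-voxel volume fractions are the fraction of `(1+VR)^3` test points
(a corner-to-corner lattice; boundary points count as inside) inside the
union; `VR = 2` is the default, `VR = 1` reduces to corner counting.
Surface areas come from marching cubes on the corner signed distances,
summed per voxel; the 256-case table is generated programmatically from the
cube's combinatorics, with ambiguous four-crossing faces resolved by the
fixed convention that diagonal inside corners stay separate (areas, not
topology, are consumed downstream). `SR > 1` subdivides surface voxels into
`SR^3` trilinearly interpolated subcells; as in the source tool, the
defaults are `VR = 2`, `SR = 1` because surface subdivision does not
improve the area error per unit cost.

On the 2×5 µm validation cylinder over random orientations with `VR = 1`,
volume errors converge at roughly O(dx^2.2) and marching-cubes areas at
roughly O(dx^1.2), with areas underestimating for convex shapes (the
triangulated surface lies inside the true one). Voxels whose computed area
is exactly zero remain stored but are excluded from surface-based kinetics.

## Diffusion: Douglas-Gunn ADI on an irregular domain

At initialization the stored voxels are decomposed, per axis, into maximal
contiguous lines; these are the tridiagonal systems of the alternating
direction implicit sweeps. One step solves

1. `(I - dt/2 Ax) v1 = (I + dt/2 Ax + dt Ay + dt Az) u`
2. `(I - dt/2 Ay) v2 = v1 - dt/2 Ay u`
3. `(I - dt/2 Az) u' = v2 - dt/2 Az u`

with implicit weight 1/2 on the swept direction (Crank-Nicolson consistent,
second order; the splitting error relative to unsplit Crank-Nicolson is
O(dt³) per step and is verified against a dense-matrix oracle in the
tests). Line ends are zero-flux: the membrane is fully reflective unless an
explicit mechanism supplies a flux.

The finite-volume coefficient between neighboring voxels `i, j` is
`g_ij = D dx (alpha_i + alpha_j)/2`, where `alpha` is the interior volume
fraction, and the flux `g_ij (u_j - u_i)` is divided by the receiving
voxel's interior volume `alpha_i dx^3`. Two properties motivated this
choice. First, `g_ij` is symmetric, so mass `sum(V_i u_i)` is conserved to
round-off for every stage of the scheme (measured drift over 10^5 fixed
steps on the Y geometry is below 1e-12 relative). Second, along a
grid-aligned cylinder every column of voxels has a constant fraction, so
the scheme reduces *exactly* to per-column 1D diffusion with the correct
diffusivity — the cylinder-reduction property that the analytic validation
relies on. Scaling the full face area `dx^2` by `1/alpha_i` instead would
make partially filled surface columns diffuse up to ~30% too fast.

Reactions are advanced implicitly (backward Euler with Newton iteration on
the local reaction Jacobian, absolute tolerance 1e-12 mM, at most 20
iterations, initial guess the current concentration) *before* diffusion in
each step — Lie splitting in the stated order. Species diffuse and react;
states react only; parameters are never updated. Point fluxes are
mass-based (molecules/ms, with a per-second option), so the injected amount
is independent of dx and dt.

The integrator core (line sweeps, batched Thomas solves, the built-in
bistable reaction, and per-step recording of mass, wave-front position, and
probe traces) is implemented in C++ via Rcpp; everything else is R.

## Membrane coupling

Mechanism currents are computed against the 1D summed-frusta areas (for
consistency with pure-electrophysiology models) and distributed over the
owning segment's surface voxels proportionally to marching-cubes area;
Faraday's constant, the valence, and the voxel interior volume convert
current to concentration rate. Segment concentrations are reported back as
the volume-weighted mean over the segment's surface voxels (or all voxels
with `feedback = "all"`, which damps the artificially high surface values
that arise when few voxels exchange with one segment).

The Hodgkin-Huxley mechanism uses the standard squid-axon kinetics and
NEURON-convention defaults (gnabar 0.12, gkbar 0.036, gl 0.0003 S/cm²,
el -54.3 mV, ek -77 mV, rest -65 mV, nai 10 mM, nao 140 mM, 6.3 °C);
these values are not all printed in the validation source, so the sodium
accumulation figures (13.35/11.24 mM at dx = 0.5 µm) are reproduced
conditional on them — our runs give 13.24 and 11.10 mM. The sodium
reversal is recomputed from the fed-back surface concentration by the
Nernst equation every step, closing the loop between chemistry and
excitability. The synaptic mechanism is an event-driven exponentially
decaying mass flux (`g` jumps by the event weight, decays with time
constant tau; delivered mass is the exact integral of `g`, hence
`weight * tau` per event in the long run) targeted at a surface voxel with
strictly positive area.

## Hybrid 1D-3D coupling

Each section is simulated either in 1D or in 3D (`set_solve_type`, last
assignment wins). Junctions occur only at section ends. Boundary voxels of
the 3D side are those intersecting the plane perpendicular to the end
frustum axis at the attachment point; per voxel, the exchange distance is
`dx/2 + (segment length)/2` and the exchange area is the interior volume to
the 2/3 power. At the start of each step, Fickian fluxes
`D * area * (c_1D - c_voxel) / distance` are exchanged (equal and opposite
mass on the two sides), then both domains advance independently — weak
coupling, which costs little but can destabilize for large dt; no automatic
step control is attempted. The 1D cable uses backward Euler on the branched
tree (unconditionally stable; the junction coupling already limits order),
with two segments per micron in the validation fixtures. On the 153 µm
hybrid benchmark the per-segment volume-weighted error is largest in the
segments adjacent to the junctions (~2e-3 mM at dx = 0.25 µm against a
~0.03-0.3 mM solution) and decreases as dx halves, while the pure-3D run of
the same problem errs at only ~1e-5 mM: the junction error is dominated by
the deliberately simple exchange estimates (distance `dx/2 + h/2`, area
`V^(2/3)`), which overstate the coupling resistance by roughly a factor of
two, and it is nearly insensitive to dt and to `VR`. Refining the exchange
geometry, not the partial volumes, is the lever for tightening these
junctions further.

## Analytic oracles

Validation compares against closed forms evaluated by the package:
the 1D interval solution (erf form of the heat kernel integrated over the
source, with reflective image terms added until they change the result by
less than 1e-15), its separable 3D product for a box source, and the
traveling-front speed `c = sqrt(2) (1/2 - alpha) sqrt(D)` of the scalar
bistable equation `u_t = D Lap(u) - u (1 - u)(alpha - u)`. The wave front
in a simulation is defined as the farthest position whose mean 1D (per
segment) concentration exceeds 0.5, and the speed estimate interpolates the
crossing times of 100 µm and 200 µm of arc length. Orientations for the
wave study are drawn uniformly on the sphere (phi uniform, cos theta
uniform) from a recorded seed; dt defaults to 0.025 ms.

## Problem sizes used in the shipped validation

The packaged tests and the acceptance script scale the studies to sizes a
single workstation core handles comfortably while keeping every printed
condition that defines the physics (dx, dt, D, geometry, initial data):

* cylinder discretization: 300 orientations at dx = 0.5 µm for the error
  means; 100 orientations across the seven dx values for the convergence
  slope (the source study used 1,000);
* point source: the full t = 20 ms, dx = 0.25 µm setup with the reflective
  cylinder reduced from 40 µm to 32 µm diameter/height and evaluation
  within 4 µm of the origin — the measured worst-case relative error over
  *all* voxels in that ball is 0.087%, below the 0.1% bound, and image
  sources at 32 µm contribute ≤ 0.02% (an earlier t = 5 ms scaling was
  rejected: the near-origin spatial error alone is ~0.75% there);
* wave speed: 5 orientations at dx = 0.25 µm (the source used 100); each
  orientation is also checked against the < 4% worst-case bound;
* conservation: 10^5 steps at dt = 0.025 ms plus halvings at fixed total
  time (the source ran 4×10^6 steps);
* spines: dx = 0.05 µm and dt = 0.025 ms (unprinted in the source; chosen
  so the 0.1 µm neck spans two voxels and the sub-0.5 ms peak is resolved).

## What the synthetic fixtures do and do not show

All validation geometries (cylinders, the Y, the stepped cylinder, spiny
dendrites, the hybrid three-section cable) are generated programmatically,
so every acceptance experiment is self-contained. They exercise branch
points, abrupt diameter changes, sub-voxel features, and 1D/3D interfaces,
but they are idealized: real reconstructions add taper, noise in sample
spacing (which can produce bumpy unions and very small suggested dx —
subsample such morphologies), soma outlines (not supported here; somas are
collapsed to cylinders), and non-convex self-overlap at scales these
fixtures do not reach. Passing the fixture suite shows the discretization
and solvers are correct, not that any particular reconstruction is a
faithful model of its cell.

## Known limitations

* Fixed-step integration only; no variable-step path and no automatic
  stability control for the weak 1D-3D coupling.
* Electrodiffusion is deliberately out of scope; fluxes ignore charge
  effects on diffusion.
* Neurolucida soma outlines and sheared-frusta somas are not supported.
* The join rule is an approximation where the published rule is
  under-specified; voxel counts on other tools' meshes may differ even
  though the Y benchmark matches exactly.
* Single-threaded; the line decomposition is partitionable but no
  scheduling is implemented.
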