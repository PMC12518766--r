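---
title: "Automated lumbar-spine FE preprocessing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lumbar-spine FE preprocessing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spineforge)
```

spineforge turns labeled surface meshes of the lumbar spine — five
vertebrae `L1`–`L5` and four intervertebral discs `D1`–`D4`, as produced by
any CT segmentation tool — into a complete finite-element model: cortical
and cancellous bone per vertebra, nucleus pulposus and annulus fibrosus per
disc, geometric endplates, spring-element ligaments, cartilage at every
vertebra–disc interface, plus materials, contacts, boundary conditions and
load cases, exported as FEBio-format XML and legacy VTK. This vignette
explains the geometric model behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the synthetic test fixtures
do and do not establish about real data.

All lengths are millimetres; the anatomical frame is fixed as superior =
+z, anterior = +y, left = +x. Inputs in another pose should be rigidly
aligned first — several steps (the PCA sign conventions, the posterior
restriction of the posterior-longitudinal ligament, the lower-endplate
plane) interpret these axes anatomically.

## Cortical / cancellous separation

The cortical bone is modelled as a uniform-thickness shell: every vertex of
the vertebral surface moves inward along its normal by the cortical
thickness `t_core` (default 0.3 mm),

$$V_\mathrm{cancellous} = V_\mathrm{cortical} - t_\mathrm{core}\, n(v).$$

A per-face normal is ill-defined *at* a vertex shared by several faces, so
`n(v)` is the area-weighted average of the incident face normals,
renormalized; on a flat patch it reduces to the face normal. Two guards
make the construction robust on real vertebrae:

* **Thin features.** Where the inward ray meets the opposite wall within
  `2 t_core` (thin posterior processes), the local offset is clamped to 45%
  of that distance, preventing inversion. The uniform-thickness model says nothing about
  thin features; the clamp is this package's choice and is logged on the
  result.
* **Offset artifacts.** The raw offset can self-intersect at concave
  creases. Iterative Laplacian smoothing
  $v \leftarrow (1-\lambda)v + \lambda\,\overline{N(v)}$ (default
  $\lambda = 0.5$, 10 iterations; $0 < \lambda \le 1$) removes them; updates
  are synchronous (Jacobi-style) so the result does not depend on vertex
  order. If the smoothed surface still self-intersects, one retry with 50%
  more iterations is attempted before erroring. Because smoothing in
  concavities can push vertices back *out* through the outer wall,
  offending vertices are blended back toward their raw-offset positions
  until the core is strictly contained.

The number of smoothing iterations is a free parameter; the
default of 10 was chosen as the smallest round number that removed all
offset self-intersections on the synthetic fixtures, and both `lam` and
`iterations` are exposed in `bone_split_params()`.

**Volumes.** The shell is meshed as a prism layer between the matched outer
and core triangles (three tetrahedra per prism; quad walls split along the
diagonal leaving the quad's smallest vertex index, which makes neighbouring
prisms conform). The core is meshed by *star-kernel fan*: a kernel point
that sees every face (searched from the centroid, then by maximizing the
minimal inward face-plane distance) is connected to every surface triangle.
The fan's boundary is exactly the input surface and its total volume equals
the divergence-theorem surface volume to machine precision, so
shell + core = outer volume holds by construction. Surfaces that are not
star-shaped have no fan mesh and raise a clear error; within the pipeline
every solid is either star-shaped (vertebra cores, nucleus) or built by a
structured construction (shell, annulus, cartilage). When a remeshing
target is set, the *outer* surface is remeshed before offsetting so the two
surfaces always correspond.

## Nucleus / annulus separation

The disc's intrinsic orientation comes from PCA of its vertices
(covariance with the $1/(n-1)$ normalization): `u1, u2` span the
transverse plane, `u3` is the disc axis (least variance). Eigenvectors are
sign-ambiguous and eigenvalues of near-circular discs tie, so the frame is
pinned deterministically: `u3` points toward superior (+z), `u1` toward
anterior (+y), `u2 = u3 × u1`; within a tied eigenspace (where every
direction is an eigenvector) the axes are taken as the projections of the
global axes onto that eigenspace, which also makes axis-aligned inputs
exact.

The disc outline is the outer boundary of the vertices projected to the
`(u1, u2)` plane. How this
"projected boundary" is obtained is a genuine design choice; the package uses a concave hull — the
alpha shape at `alpha = 2 ×` median mesh edge length, computed from a 2-D
Delaunay triangulation with a convex-hull fallback — resampled to
`n_samples` points at equal arc length. Mirror-symmetric meshes project
coincident points, which are collapsed before triangulating.

The nucleus boundary is the outline scaled about its centroid,
$C_\mathrm{nucleus} = s\,C_\mathrm{disc}$. The scale factor is
deliberately user-defined; the default `s = 0.6` puts the nucleus
cross-section at ≈36% of the disc's, mid-range of reported anatomy, and is
exposed in `split_disc()`.

`build_nucleus_solid()` realizes "extrude and clip to the disc": the scaled
curve is swept along ±`u3` and capped, with the top and bottom of every
in-plane sample found by casting a `u3` ray against the disc surface — an
exact intersection computation for a swept cylinder against a disc sliced
by `u3`, which avoids a general mesh boolean. Face classification then
follows the published rule: a disc face with **any** vertex inside the
nucleus volume is a nucleus face, all-outside faces are annulus faces; the
partition is exhaustive and exclusive by construction. Membership itself is
evaluated against the *unclipped* extrusion (disc extent + 5% margin):
the clipped solid's caps lie exactly on the disc surface, which would make
cap-vertex containment a coin flip at the 10⁻³ mm level of facet sag, while
the unclipped cylinder gives the same footprint membership with a strict
margin.

**Stitching.** The nucleus face set splits at the mid-plane of its face
centroids (`z_threshold = (max z + min z)/2` along `u3`) into top and
bottom caps. Their boundary loops are traced combinatorially (walking the
face fan at pinch vertices) and joined by a nearest-neighbour zipper — a
greedy triangulated band between the two ordered loops, after aligning
starts and orientation. Joining the loops directly (rather than lofting
between resampled copies) is what makes the result exactly watertight: the
wall shares its nodes bitwise with the cap boundaries. The annulus surface
is the annulus face set closed by the same wall with reversed orientation,
so the nucleus–annulus interface exists as two coincident surfaces — the
form a stick-contact pair needs — while the shared nodes satisfy the
shared-boundary reading as well; both modelling conventions
are emitted. `loft_walls()` (equal-count cyclic-aligned lofting) is kept as
a standalone operation.

**Solids.** The nucleus surface is star-shaped and gets a fan mesh (its
volume therefore equals the surface volume exactly). The annulus is an
annular region, so it is meshed by a structured swept grid: angular
stations at the union of both boundary loops' arc-length parameters (every
wall node appears with its exact coordinates), wall columns interpolated
along the actual loop polylines, and the outer cross-section boundary —
wall top, cap, rim, cap, wall bottom — traced per station by in-plane rays
so the steep lateral wall and rim rounding are sampled directly. Nodes come
from transfinite interpolation between the wall column and that chain;
hexahedral cells are split into 12 tetrahedra through their centroid with
quad faces diagonalized from their smallest node id (conforming between
neighbours). At the default grid spacing this reproduces the annular
volume to ≈2%, giving a disc-level volume closure of ≈98% (the acceptance
gate is 3%).

## Endplates

The four-step recipe, in order: (1) keep vertices of upward faces
(face normal · L > 0, with the light direction `L` the least-variance PCA
axis, sign-fixed superior); (2) keep those above
`z_threshold = (max z + min z)/2`, z measured along `L` so the rule is
pose-invariant and identical to the global-z rule for axis-aligned input;
(3) single-linkage clustering at 1.5 mm — implemented as connected
components of the ≤1.5 mm proximity graph via a grid union–find, which is
exactly the single-linkage dendrogram cut without an n² distance matrix —
keeping the largest cluster (ties resolved toward the higher mean height);
(4) radial shrinkage about the cluster centroid in the plane orthogonal to
`L`, dropping vertices beyond the 70th percentile of radii. Percentile
definitions differ at small n; the package uses linear interpolation
between order statistics (the 70th percentile of radii 1..10 mm is 7.3 mm,
retaining exactly 7 points). The lower endplate repeats the recipe below a
plane 20 mm under the upper endplate plane, restricted to downward faces —
the plane-side rule alone would admit lateral-wall vertices on tall
specimens — and keeps points within 55% of the maximum radius. The 20 mm
offset is kept literal (configurable); it does not scale with vertebra
height.

## Ligaments

Attachment areas come from cutting planes through the vertebral center `O`
(the vertex centroid — the only center the geometric model defines), with
normals given in spherical coordinates,

$$N = r\,(\sin\phi\cos\theta,\; \sin\phi\sin\theta,\; \cos\phi),$$

angles in degrees (the published magnitudes, e.g. θ = 156°, are only
meaningful as degrees), and a vertex selected iff
$N \cdot (P - O) > 0$ (strict). A negative `r` — which the published table
uses without comment — algebraically reverses the selected side; the
selections for `±r` partition the off-plane vertices. The table is
spherical despite its caption naming cylindrical coordinates: its own
conversion formula is the spherical one, and that formula is what the
package implements. The triple order is (φ, θ, r).

`default_ligament_table()` carries the nine published plane rows (ALL
lower/upper, ITL left/right, CL lower/upper × left/right, SSL/ISL) plus
the posterior longitudinal ligament as the closest-N posterior points
around the center (N = 20 by default; the published rule leaves N and
laterality open, so both are configurable and the candidates are restricted
to y < center) and the ligamentum flavum anchored at midpoints between
adjacent vertebral centers, projected to each mesh's nearest posterior
vertices. Across a motion segment, `lower`-labeled rows select on the
upper vertebra and pair with `upper`-labeled rows on the lower vertebra;
single-row ligaments apply the same plane to both.

Each ligament instance becomes 10 linear springs. Nothing in the source
model says how springs are placed within an attachment area; the package
spreads anchors over the upper region by farthest-point sampling (seeded at
the vertex nearest the region centroid, hence deterministic) and pairs each
with its nearest vertex in the lower region; rest lengths are the current
distances. Spring stiffness is not derivable from the published modulus
alone, so the exporter uses k = E·A/L with E = 0.22 MPa and a configurable
effective cross-section A = 10 mm² per spring.

## Cartilage

For every vertebra–disc interface the contact region is the set of disc
faces whose centroid lies within `max_gap` (default 2.0 mm — above typical
segmentation gaps, below the disc height) of the endplate patch on its
facing side. The cartilage volume is built by projecting the endplate patch
along its plane normal onto the contact sub-mesh and filling the swept
prisms with tetrahedra; patch faces whose rays miss the disc or exceed
`max_gap` are trimmed, which realizes "only the portions of the disc
interacting with the endplates". The segment surface is the closed boundary
of that solid. Labels follow the vertebra+disc convention (`L1D1` between
L1 and the L1/L2 disc, `L2D1` between L2 and the same disc, …), eight
segments for a five-level stack. The cartilage conforms to the union of the
nucleus and annulus contact regions rather than to either part alone.

## Assembly and export

`assemble_model()` produces 26 parts for a full stack (5 cortical + 5
cancellous + 4 nucleus + 4 annulus + 8 cartilage), assigns the constitutive
set (cortical 12 000 MPa/0.3; cancellous 100 MPa/0.2; nucleus Mooney–Rivlin
c1 = 0.12, c2 = 0.09, k = 666.67 MPa; annulus 0.56/0.14/14.89 MPa;
cartilage 23.8 MPa/0.4; densities 1.0003 g/cm³; ligament springs
E = 0.22 MPa), and auto-generates contacts: stick nucleus↔annulus per
disc, tied cartilage↔endplate per interface, and one node-to-surface
definition per ligament instance, all with the 0.01 mm node tolerance.
Every node of the L5 lower endplate is fixed in all degrees of freedom; the
L1 upper and L5 lower endplates are rigid bodies (rigid materials bound to
node sets), and the four load cases — extension Mx = −7.5 N m with
Fz = −50 N, flexion Mx = 7.5 N m with Fz = −117.5 N, axial rotation
Mz = 5.5 N m with Fz = −72 N, lateral bending My = 7.8 N m with
Fz = −70 N — bind to the L1 upper endplate, each as a quasi-static step of
10 equal increments. "Stick" maps to the FEBio `sticky` contact, "tied" to
`tied-node-on-facet` and node-to-surface to `sliding-node-on-facet`.
Node coordinates are written with 12 significant digits so a write/read
cycle preserves them to better than 10⁻⁹ relative; solving the model is
out of scope.

## The synthetic spine

`make_lumbar_stack()` generates a deterministic five-level stack with the
geometric structure every stage keys on: each vertebra is a radial graph
over an icosphere — an ellipsoidal body (semi-axes 20 × 15 × 12 mm)
carrying a posterior arch of five angular-Gaussian protrusions (spinous,
two transverse, two pedicle-like; spinous length 25 mm) — and each disc a
rounded elliptical cylinder (superellipsoid, semi-axes 18 × 13 mm, height
10 mm) placed midway between its vertebrae with a 0.5 mm clearance. Radial
graphs are closed, manifold, self-intersection-free and star-shaped by
construction. Surface noise is a low-order smooth trigonometric field over
the sphere (amplitude 0.2 mm), seeded per structure and damped at the
z-poles so endplate clearances stay intact; with the seed fixed the whole
stack is byte-reproducible. The default resolution is icosphere
subdivision 4 (2562 vertices per structure), chosen so the surface vertex
spacing (≈0.8–1.4 mm) resolves the 1.5 mm endplate clustering threshold;
the full run stays desk-scale (≈1 minute).

What the fixtures do **not** emulate: real segmentation artifacts
(staircase aliasing, topological handles, disconnected fragments),
asymmetric or pathological anatomy, facet joint geometry, and vertebrae
whose posterior elements are thinner than 2·`t_core` everywhere. Passing
tests on the fixtures therefore establishes the geometric algorithms and
bookkeeping, not robustness to every segmentation defect; `fill_holes()`,
`largest_component()` and the thin-feature clamp are the entry points where
real-data repair would engage.

## Numerical conventions

* Degenerate faces (area < 10⁻¹⁰ mm²) are dropped at construction.
* Points within 10⁻⁹ mm of a closed surface are classified *inside*
  (deterministic downstream face classification); containment uses ray
  casting with a generalized-winding-number fallback when a ray grazes an
  edge.
* STL vertices are merged at 10⁻⁶ mm on read; mesh indices are 1-based in
  R, exported formats use their native conventions.
* Isotropic remeshing follows the split/collapse/flip/tangential-relax
  scheme with reprojection onto the input surface; contract: median edge
  within 25% of target, volume change < 1%, manifold and closed preserved.
* The anatomical sign conventions anchor PCA frames to the global axes, so
  pipeline stages commute with rigid motions only while no convention sign
  flips — exact for translations, and for rotations safely below 45°;
  the bone split is fully intrinsic and commutes with arbitrary rigid
  motions.

## Problem sizes used in the checks

The test-suite and acceptance computations run the synthetic stack at its
default resolution (2562 vertices per structure, ≈300 000 tetrahedra in
the assembled model), the reference-sphere checks at icosphere
subdivision 4 (radius 10 mm), randomized partition checks on 50
ellipsoidal discs of 320 faces each, and 100 random cutting planes plus
the 9 published ones for the half-space oracle.
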