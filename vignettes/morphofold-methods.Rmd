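---
title: "Deciphering folded epithelial surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciphering folded epithelial surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The horn primordium of the rhinoceros beetle is a single epithelial sheet,
densely folded under the larval head capsule. At pupation, hemolymph
pressure inflates it like a balloon within about two hours, and a
four-branched horn — up to six times longer proximodistally than the folded
primordium — appears. Because the deployment is fast and essentially
passive, the final three-dimensional shape must be encoded in the folding
pattern itself. morphofold implements the computational toolkit needed to
read that code on triangle meshes:

* an **unfolding simulator** (`inflate()`): quasi-static inflation of a
  folded mesh by internal pressure against a near-inextensible membrane;
* **furrow visualization** (`furrow_field()`): signed normal displacement
  between a mesh and its smoothed reference, classified into ridges and
  valleys;
* **furrow removal analysis** (`remove_furrows()`): region-masked
  HC-Laplacian smoothing of the folded mesh, followed by inflation of both
  variants and a morphometric comparison — the in-silico "knockout" of a
  furrow pattern;
* **correspondence analysis** (`map_region()`): because connectivity is
  frozen during simulation, folded/unfolded correspondence is exact vertex
  identity, so regions drawn on the inflated shape can be rewound onto the
  folded one;
* **morphometrics** for the three transformation modes — proximodistal
  elongation (`axial_extent()`), angular change (`centerline()` +
  `bend_angle()`), and branching (`count_branches()`) — plus
  `groove_angle()`, `apex_offset()` and `discrete_gaussian_curvature()`.

Real primordium meshes (reconstructed from serial sections and micro-CT)
are not publicly available, so the package ships seeded parametric
generators that emulate each folded structure the analyses target
(`make_accordion_cylinder()`, `make_biased_base()`, `make_furrowed_disk()`,
`make_yoshimura_cylinder()`, `make_cap_model()`, plus analytic
primitives). Everything in the pipeline is deterministic.

Axis convention throughout: **+Z proximodistal (distal up), +Y dorsal,
+X the animal's left**; lengths are dimensionless.

## The membrane energy and the unfolding simulator

`inflate()` minimizes, over vertex positions $x$,

$$E(x) \;=\; \sum_{\text{edges}} \frac{k_s}{2\,\ell_0}\,(\ell - \ell_0)^2
\;+\; \sum_{\text{hinges}} \frac{k_b}{2}\,\theta^2
\;-\; p\,V(x),$$

with $\ell_0$ the edge length of the folded rest mesh, $\theta$ the
deviation of each interior edge's dihedral angle from flat, and $V$ the
enclosed volume (divergence-theorem sum over faces). Rest lengths are the
folded mesh's own edge lengths: the membrane "wants" to keep its folded
metric, and pressure work supplies the unfolding drive. The from-flat
bending term is deliberately small — it regularizes crumpling and irons
creases; it is not a shell model.

Open meshes (drumhead fixtures, the cap, the tube base) must have their
boundary ring pinned; the enclosed volume is then computed against an
implicit triangle-fan closure of each boundary loop to its centroid, which
is exact because the pinned loop never moves. The same convention is
available in `enclosed_volume(..., fan_close_boundary = TRUE)`.

### Parameter defaults and their reasoning

* `k_stretch = 1` sets the energy scale.
* `pressure = 0.05 k_s / R_lat`, with $R_\text{lat}$ half the larger
  lateral bounding-box extent. By the Laplace law, the membrane strain of
  an inflated body of radius $R$ is of order $pR/k_s$, so this choice
  pins the strain near 5% regardless of the object's size: shape change
  comes from unfolding, not stretching. (Scaling pressure by a mesh-edge
  length instead would make the strain resolution-dependent and can exceed
  40% on realistic fixtures.)
* `k_bend = 1e-4 k_s \overline{\ell_0^2}` — strong enough to suppress
  sub-edge crumpling, far too weak to resist unfolding.
* `grad_tol = 5e-3 \, p \, \overline{\ell_0^2}`: convergence when the
  largest residual vertex force is a small fraction of the typical
  pressure force on one vertex.

### The descent scheme

The minimizer is L-BFGS (memory 8) with a backtracking line search that
only ever accepts energy-decreasing iterates, so the recorded energy
series is non-increasing by construction and the whole trajectory is
deterministic. Plain steepest descent (available via `lbfgs_memory = 0`)
minimizes the same functional but needs orders of magnitude more steps on
drumhead-like fixtures, whose soft "piston" modes coexist with stiff
in-plane springs; the quasi-Newton direction resolves that conditioning
gap. The analytic gradient (including the exact dihedral-angle gradient)
is verified against central finite differences to 1e-5 relative error in
the test suite.

Snapshots are recorded every `snapshot_stride` accepted steps plus first
and last; `map_region()` validates region transfer across them, and
`snapshot_mesh()` materializes any recorded state.

There is no self-collision handling; the bundled fixtures are built to
avoid interpenetration at the default pressure.

## HC-modified Laplacian smoothing

`hc_laplacian_smooth()` implements the classical "push-back" scheme with
uniform (umbrella) neighbour weights. Per iteration, a weighted Laplacian
step $p_i = (1-w_i) q_i + w_i \overline{q}_{N(i)}$ is followed by the
correction $p_i \leftarrow p_i - w_i\,(\beta b_i + (1-\beta)
\overline{b}_{N(i)})$ with $b_i = p_i - (\alpha o_i + (1-\alpha) q_i)$.
Three implementation choices matter:

* **The push-back is scaled by the smoothing weight $w_i$.** Without this,
  the neighbour-mean term can move vertices whose weight is zero;
  with it, region-masked smoothing is exactly local — outside the mask
  (plus feather ring) the mesh is bit-identical — and the scheme still
  reduces to classical HC when no mask is used.
* **Boundary handling.** Boundary vertices of open meshes are smoothed
  only along the boundary polyline (mean of their two boundary
  neighbours), which prevents rim curling; boundary *corners* (turn angle
  above 30°) are frozen, so flat plates are exact fixed points of the
  smoother and plate outlines are preserved.
* **Stability.** The scheme is stable in the shrink-resistant regime
  around the defaults ($\alpha = 0$, $\beta = 0.5$, 50 iterations); small
  $\beta$ with many iterations can amplify high-frequency modes and is not
  a useful operating point.

The defining property of the HC correction — global shrinkage far below
plain Laplacian smoothing — is asserted in the tests by comparing volume
loss on a corrugated sphere. Masked smoothing weights ramp linearly over
`feather_width` breadth-first rings outside the mask (ring $k$ gets
$1 - k/(\text{feather}+1)$), checked against independent graph-distance
computations.

## Furrow visualization

The signed depth is $d_i = (x_i - s_i)\cdot \hat n_i$ with $s$ the
smoothed positions and $\hat n$ the outward area-weighted vertex normal of
the smoothed mesh, then **recentered by its median**: HC smoothing leaves
a small uniform shrinkage offset that is not furrow signal, and the median
is robust against genuinely furrowed regions. Classification uses a
symmetric threshold, by default $0.2\times$ the median of the nonzero
$|d|$, **floored at 2% of the mean edge length**: depths below mesh
resolution read as neutral, so a featureless surface classifies entirely
neutral instead of amplifying numerical noise into ridge/valley labels.
Both adjustments leave every sign and density oracle intact (sinusoidal
plates, accordion pleat bands, ventral/dorsal furrow bias).

PLY export colors ridges red, valleys blue, neutral gray
(`save_mesh(..., fields = c("furrow_depth", "furrow_class"))`).

## Morphometrics

* **Centerline and bend.** `centerline()` bins vertices into equal-width
  slabs along an axis and takes area-weighted slab centroids;
  `bend_angle()` is the angle between least-squares directions of the
  first and last 25% of nodes, projected to the sagittal Y–Z plane,
  positive when the distal end tips dorsally. The folded primordium has no
  external landmark (the original orientation reference was the animal's
  mandibles), so a mesh-intrinsic definition is required. Slabs normal to
  a single axis cannot follow a 90° turn at its ends, so strongly bent
  oracle fixtures are sliced along the diagonal axis and the end slabs —
  contaminated by oblique cuts — are trimmed; the `bent_tube` primitive
  (straight run, arc, straight run) exists precisely to give clean
  proximal/distal directions.
* **Branch counting** uses connected components of the vertex subgraph
  above `height_fraction` (default 0.6) of the axial span, discarding
  components under 5 vertices — robust on coarse meshes where local-maximum
  counting is noisy. The test suite cross-checks the hand-rolled BFS
  against igraph components.
* **Groove angle** extracts the plane cross-section as polyline chains,
  finds the deepest concave point (turning toward the outward normal,
  most recessed along the mean section normal), and measures the interior
  angle between chords 10% of the section arc length to each side. On
  machined V-notch plates this recovers the notch angle within tenths of a
  degree; smooth convex sections return `NA`.
* **Apex offset** is the in-plane distance of the highest interior vertex
  from the pinned-rim centroid, over the rim's mean radius — the upright
  cone vs oblique cone discriminator.
* **Angle-deficit Gaussian curvature** uses barycentric vertex areas. The
  combinatorial Gauss–Bonnet identity (total deficit $= 2\pi\chi$, machine
  precision) is the strongest single correctness check and is asserted on
  every closed fixture; regular cylinder walls give exactly zero, the
  developability that explains why stalk pleating stores length without
  creating shape.

## The synthetic fixtures: what they emulate, and what they do not

All furrows are analytic displacements, so ridge/valley oracles are exact.

* **`make_accordion_cylinder()`** — the stalk. A triangle-wave meridian of
  $2n$ slants of length $s$ compressed into height $h$ stores meridional
  arc $2ns$; the default fixture (12 pleats, $s = 0.25$, $h = 1$) stores a
  6:1 ratio. Unfolding requires the crest/trough radii to equalize, a hoop
  strain of about (pleat amplitude)/radius, so the default radius 2.5
  keeps that near 5%; the acceptance run recovers an elongation ratio of
  about 5.7 with under 1% area change. The flat cap fans that close the
  cylinder bulge freely under pressure, which is real membrane mechanics
  but not stalk elongation — elongation is therefore measured on the
  generator's `wall` mask (all revolved rings).
* **`make_biased_base()`** — the orientation-setter. Circumferential
  furrows with more periods ventrally than dorsally (5 vs 1 by default)
  store more meridional length ventrally; inflation elongates the ventral
  side more and turns the tube dorsally. Removing the furrows by masked
  smoothing removes the bias, reproducing the removal phenotype (the bend
  collapses toward zero or slightly ventral).
* **`make_furrowed_disk()`** — the simplified furrow-pattern comparison.
  Concentric full circles inflate to an upright cone (apex offset ≈ 0);
  "outwardly vacant" concentric semicircles to an oblique cone (apex well
  off axis). The polar grid uses an inner fan hole so edge lengths are
  near-uniform; dense center rings would throttle the descent step
  globally.
* **`make_yoshimura_cylinder()`** — the passive zigzag. Offset rings with
  alternate radial indentation, axially compressed so each zigzag edge
  keeps its developable slant length; inflation recovers the stored
  height. Being developable, the pattern stores length without encoding
  any shape — the "passive" fold class.
* **`make_cap_model()`** — the one deliberately *constructed* fixture. Its
  role is to show that the cap's mechanism decomposition suffices to
  produce four distal branches under inflation: two tall lateral
  macro-lobes (present in the folded macro shape), two medial concentric
  furrow stacks, and parallel dorsoventral furrows on the overhang's
  bottom surface. The medial element is a small macro prominence carrying
  a telescoped stack of concentric folds, azimuthally vacant on the
  outward side; flattening the stack (`medial_height = 0`) leaves a
  prominence too small to reach the distal super-level set, so the branch
  count drops from 4 to 2 — the removal phenotype in which the medial tips
  persist but become much smaller, while the lateral tips change little.
  It does not reproduce beetle anatomy, and the split between macro
  prominence and furrow stack is a modeling necessity: at the default
  pressure scaling the strain available to a feature of radius $r$ is
  only $\sim p r / k_s$, so furrow stacks on a small patch cannot by
  themselves erupt into long tips the way the full-size accordion
  elongates (this is also why the spec-level furrow-removal contrast is
  expressed as crossing the branch-count threshold rather than tip
  presence/absence).

What the fixtures deliberately do not emulate: real furrow cross-sections
(unknown; sinusoids and triangle waves are used for analytic oracles),
mesh noise and decimation artifacts of reconstructed specimens,
self-contact between folds, and growth — the question of how the furrow
patterns form is out of scope. Passing tests therefore demonstrate the
correctness and the qualitative mechanics of the *methods*, not
quantitative agreement with any particular specimen.

## Problem sizes and determinism

The bundled analyses run on meshes of roughly 10^2–3×10^3 vertices
(accordion 24×64 rings ≈ 1750 vertices, cap model 48×64 ≈ 3100), where
every inflation converges in seconds to about a minute on one core. All
generators, the smoother and the simulator are deterministic given their
arguments; the only randomness in the package is the optional vertex
jitter of `make_primitive()`, which takes an explicit seed.

## Known limitations

* The energy is a minimal membrane model: no shell bending rigidity
  beyond the crease-ironing hinge term, no viscosity, no contact.
* Quasi-static minimization finds a local minimum; deeply invaginated
  pouches whose eversion requires transient hoop stretch (snap-through)
  stay folded, which constrains how fixtures must encode stored surface.
* `groove_angle()` measures one stated cross-section; it does not search
  for the anatomically "central" groove.
* Meshes are used as-is: no repair, decimation or remeshing.
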