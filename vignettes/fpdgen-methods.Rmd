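---
title: "Parametric support generation for fixed partial dentures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric support generation for fixed partial dentures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A 4-unit fixed partial denture (FPD) — a bridge from the first premolar to
the second molar — can be supported either by two prepared natural teeth or
by two implants.  To study how peri-support bone loss and bone quality
affect the stresses in such a restoration, one needs a *complete* solid
model: not just the scanned bridge, but the cement layers under its two
retainer crowns, the abutments (tooth roots with their periodontal
ligament, or titanium implant hardware), and a segment of mandibular bone
with the supports embedded and with crestal bone-loss defects of
controlled depth.  Building these by hand in a CAD system takes hours per
configuration; `fpdgen` generates them programmatically from a labeled FPD
mesh and a small set of clinical parameters, and writes solver-ready
labeled geometry plus a boundary-condition manifest.  The finite-element
solve itself is out of scope: the package ends where a structural solver
begins.

The input convention is a multi-solid ASCII STL with three named parts:
`surface` (the external bridge surface), `distal` and `mesial` (the two
open lumen surfaces, i.e. the concave undersides of the retainer crowns
that seat on the abutments).  Binary STL cannot carry solid names, which
is why the labeled interchange format is ASCII; single parts can be
written as binary.

## Pipeline

### Alignment

The two lumen margin curves (boundary loops of the open lumen meshes) are
extracted, and the centre of each is taken as the arithmetic mean of the
curve resampled uniformly by arc length to 256 points — resampling first
means that scanner-dependent vertex density cannot bias the centre.  The
minimal-volume oriented bounding box of the merged mesh is computed
(candidate axes from face normals with rotating-calipers rectangles in
each candidate plane, polished by a local rotation search; exact for
face-flush polyhedra, within a percent in general).  The box face nearest
the midpoint of the two lumen centres is the gingival face; ties resolve
to the lowest face index.  The local frame has its origin at the distal
lumen centre, z normal to the gingival face pointing occlusally, and x
along the mesiodistal line orthogonalised against z (the two directions
need not be orthogonal in a scan, and a frame must be; the
orthogonalisation keeps x as the in-plane projection of the lumen line).
One rigid motion maps this frame onto the global frame.

A purely box-derived gingival normal carries the numerical jitter of the
box optimiser, which would break the pose-invariance of the whole
pipeline.  The frame construction therefore refines the normal against
the mesh itself: an iterated support-plane fit (principal-plane fit to
the vertices within 0.15 mm of the extreme plane in the current
direction), adopted only if it agrees with the box normal.  With this
refinement, alignment is idempotent and pose-invariant to machine
precision on the synthetic fixtures.

### Support-type detection

One hundred planes are placed along the gingival-occlusal line of the
bounding box (equally spaced, endpoints included — the protocol then
removes end curves anyway, so the inclusive choice is immaterial), each
perpendicular to it.  Every closed intersection curve with a lumen is
retained; the curves of the first and the last plane that produced any
are dropped to guard against margin and apex artefacts.  For each curve
the circularity $4\pi A / Pe^2$ is computed on the curve resampled to 256
points and projected into its section plane (shoelace area, polygonal
perimeter); the circularity index CI is the arithmetic mean over the
retained curves.  The printed form of this index in the source literature
divides by $n-1$ while summing $n$ curves; only a true mean yields CI = 1
on perfect circles, so the mean is what is implemented.  A CI of 1
indicates a circle; the isoperimetric inequality caps the ratio at 1 for
any simple closed curve.  Both sides in $[0.97, 1]$ (inclusive) classify
the FPD as implant-supported, anything else as tooth-supported; a mixed
reading (one side each) classifies as tooth with a warning, since
homogeneous supports are the modelled case.

### Tooth support

*Cement layer.*  The lumen is offset into the cavity along its
area-weighted vertex normals by `d_cement` (0.1 mm default), keeping the
connectivity; the offset side is chosen automatically as the one that
moves the surface toward the margin-loop centre.  The two margin loops are
joined by a quad band with exact vertex correspondence, so the shell
closes combinatorially and the cement interface is *shared* vertex-for-
vertex with the abutment built beneath it.

*Premolar (single root).*  The root axis starts $\varepsilon$ = 0.15 mm
below the lowest point of the interior margin curve (the clearance keeps
the first section from intersecting the nonplanar margin) and runs
`d_tooth` = 16.3 mm in $-z$, divided into 20 stations uniformly in the
Bezier parameter.  The margin curve is projected onto each station plane
and scaled per axis about its own centroid by the cubic Bezier value
profiles $B_x$, $B_y$ (control points from the study configuration,
tapering from 1 at the cervix to 0.05 at the apex).  The scaling centre
is not specified in the source protocol; the projected-curve centroid
keeps the root centred under its crown.  Lofting through the stack and
capping the apex yields a watertight tooth solid whose apex plane sits at
$z_{\min} - \varepsilon - d_{tooth}$ exactly (a construction identity the
tests assert to $10^{-6}$).

*Molar (two roots).*  The same stack is duplicated and translated by
$\pm B_T(t)\, d_R$ in x.  $B_T$ starts at 0, so the two copies coincide at
the cervix and separate toward the apices; with the default profiles the
cross-section is one component near the lumen and two below the
furcation.  $d_R$ has no published value ("distance between furcation and
apex in x"); 4 mm makes two clearly separated molar roots at molar scale
and is a configuration default, not a literature value.  The two rooted
solids are merged by the signed-distance voxel Boolean (below).

*Periodontal ligament.*  The open root surface (lateral loft + apex cap)
is offset outward by `d_pdl` = 0.3 mm with the same
connectivity-preserving construction as the cement, and the margin loops
are banded shut.  The molar PDL is built in the distance field instead —
dilation of the root union minus the union, cut at the cervical level —
because the furcation is concave and a plain normal offset would
self-intersect there.

### Implant support

All implant-side solids are bodies of revolution (with the thread as an
angular modulation), built directly as closed ring stacks, which makes
them exactly watertight and lets mating surfaces share construction
datums.  The published dimension set is mutually consistent under the
following axial reading, which the package adopts: the abutment taper
(3.0 to 2.6 mm diameter) spans depths 1.0–1.5 mm below the margin-curve
minimum, the 1.0 mm plane being the implant neck plane; the abutment's
total length (7.0 mm) is measured from its dome cap; the implant's
internal bore steps lie at cumulative depths 0.5 / 4.0 / 5.0 / 5.3 mm
below the neck.  The bore-opening chamfer (radius 1.5 mm = half the
3.0 mm opening) then mates the abutment taper exactly.  The screw-seat
parameters (2.0 / 2.2 mm) are measured from the top of the screw-access
bore, which stops just below the cement layer.  Under this reading the
default 4.5 mm screw shaft fits the bores with clearance; under the
plausible alternatives it does not, which is the strongest argument
available for the chosen interpretation.  The `r_b` edge-break parameter
is accepted and validated but not geometrically realised — the adopted
bore interpretation leaves no flat internal step to blend; this is a
known limitation.

The thread is a 60-degree metric V-groove of depth $5H/8$
($H = \sqrt{3}\,p_t/2$) cut into the implant's radial height-field along
the helix (pitch 0.5 mm, 10 turns, starting 1.5 mm below the neck), with
linear run-in/out over half a turn at each end standing in for the
milling-toolpath extensions.  Cutting the height-field is by construction
the same surface as sweeping the V-profile along the helix and
subtracting it; `make_thread()` also exports the swept cutter solid
itself.  The wall is sampled at 0.025 mm axially inside the thread band
so the groove roots are resolved; a helix fitted to the root vertices
recovers the pitch to a fraction of a percent.

The screw has a cylindrical head (diameter 1.55 mm in the 1.6 mm access
bore), a conical underside matching the seat, and a 1.05 mm shaft
(under the 1.1 mm channel bore) of the configured length below the seat;
the only published screw parameter is its length, so the head shape is
the simplest solid satisfying the bore contract.

### Bone, insertion, defects

The synthetic mandibular segment is an extruded arc-spline cross-section:
flat crest (9 mm wide), filleted crest corners, outward-leaning flanks,
rounded base; 48 mm along the ridge.  Because the profile is lines and
tangent arcs, a constant inward offset is exact (radii shrink, lines
shift), which is how the cortical and transition interfaces are built as
nested watertight solids: cortical thickness per Misch quality (2.5 /
2.0 / 1.5 / 1.0 mm for D1–D4), transition thickness 0.29 mm.  The centre
curve runs along the flat crest.

Insertion marks two points on the centre curve at the FPD's lumen span,
projects them to the crest, builds the bone frame there, applies one
rigid motion to every part, and lifts the assembly by `d_bone` = 2.8 mm —
the gap between the distal lumen centre and the crestal surface.  The
cavity is then cut by a Boolean difference: the tooth cavity is bounded
by the PDL outer surfaces, the implant cavity by the implant bodies (all
interfaces downstream are bonded, so these are the surfaces in contact
with bone).

Crestal defects are saucer-shaped: a circular arc through
$(\pm w/2, 0)$ and $(0, -d)$ spanning the defect width $w$ = 10 mm
mesiodistally and the full buccal-oral width, with 0.4 mm fillets where
the saucer meets the intact crest (appended outside the rim corners, so
the arc span itself stays $w$).  Carving is implemented as a clip against
the defected crest surface $z = \mathrm{crest} - \delta(x)$: every vertex
above the cut is projected down onto it.  This is exactly idempotent,
exactly the identity at depth 0, and keeps the mesh closed (faces
flattened onto the cut surface may degenerate to zero area and are
deliberately kept).  Finally the PDL is intersected with the half-space
below the (possibly defected) crest, so only ligament in contact with
bone remains; deeper defects strictly shrink the trimmed PDL.

## Material models

The elastic registry carries the component constants used downstream:
titanium grade 4 (E = 104.5 GPa, nu = 0.37) for implant and abutment,
titanium grade 5 (114.0, 0.33) for the screw, glass-ionomer cement
(15.9, 0.33), polyurethane abutment tooth (3.525, 0.33), zirconia FPD
(210, 0.27), cortical bone (13.7, 0.3) and cancellous bone by quality
(9.5 / 5.5 / 1.6 / 0.69 GPa for D1–D4, nu = 0.3).

The graded transition zone interpolates the Young's modulus linearly from
13.7 GPa at the cortical boundary to the quality's cancellous value over
0.29 mm, constant outside; the implementation uses the convex-combination
form so both endpoints are exact to the last bit.

The periodontal ligament is first-order Ogden with $\mu_1$ = 0.006 MPa,
$\alpha_1$ = 29.8, $D_1$ = 0 (incompressible).  The source cites the
parameters without the energy convention; the classical form
$W = (\mu_1/\alpha_1)(\lambda_1^{\alpha_1} + \lambda_2^{\alpha_1} +
\lambda_3^{\alpha_1} - 3)$ is adopted, giving the uniaxial incompressible
Cauchy stress $\sigma(\lambda) = \mu_1(\lambda^{\alpha_1} -
\lambda^{-\alpha_1/2})$ with ground-state shear modulus
$\mu_0 = \mu_1 \alpha_1 / 2$.  The tests pin the convention by a
finite-difference check against the energy ($\sigma = \lambda\,
\mathrm{d}W/\mathrm{d}\lambda$ to $10^{-6}$ relative) and by the
small-strain tangent $E = 3\mu_0$, rather than by a literature stress
value, because the convention — not the numbers — is the open question.

## The mesh kernel and its numerical choices

No triangle-mesh kernel was available to build on, so the package carries
its own, with two Boolean paths:

- a **BSP (plane-splitting) Boolean** whose output vertices lie exactly on
  the input surfaces; after welding and T-junction repair it is used for
  modest inputs and is volume-exact (the box-pair identity
  $\mathrm{vol}(A-B) + \mathrm{vol}(A\cap B) = \mathrm{vol}(A)$ holds to
  machine precision);
- a **signed-distance voxel remesh**: parity-raycast sign, exact
  point-triangle distances within a narrow band of the surface, marching
  tetrahedra on the Freudenthal 6-tet decomposition.  Because the field is
  an exact distance near the surface, the extracted surface error is
  second order in the pitch; because marching tetrahedra is
  decomposition-consistent, the output is watertight by construction.
  This path handles the large or near-coincident inputs (molar root
  union, bone subtraction, PDL trim) at pitches of 0.05–0.1 mm.

Other conventions: millimetres everywhere; right-handed frames with +z
occlusal after alignment; lofts between free curves resample to 256
points by arc length, align the seam by the cyclic shift (with optional
reversal) minimising the sum of squared distances, and split quads along
the shorter diagonal — constructions that must close combinatorially
(cement, roots, PDL, abutment) use exact vertex correspondence instead of
resampling; vertex normals are area-weighted face-normal averages;
geometric coincidence tolerance is $10^{-9}$ mm; grids are padded and
given an irrational origin offset so columns avoid mesh vertices, with a
jitter-retry for the residual degenerate cases.

## The synthetic fixtures, and what passing them does (not) show

The scanned master model behind the original study is not available, so a
deterministic generator stands in for it.  The FPD fixture builds two
open lumen cups on a smooth 4-unit bridge hull: implant-type cups are
low-noise surfaces of revolution (CI about 0.997 in practice), tooth-type
cups superpose two- and four-lobed harmonics calibrated once so the CI
lands in the published tooth regime near 0.92, plus small seeded
harmonics (amplitude 0.01 tooth / 0.002 implant).  The hull's gingival
underside carries a genuinely flat facet — that is what makes bounding-box
based alignment exactly reproducible, and it is also the least realistic
feature of the fixture.  The bone fixture's crest is straight and flat.
Real scans have nonplanar margins everywhere, no flat facets, scanner
noise and unlabeled regions; passing the suite shows the *algorithms*
realise their contracts (thicknesses, datums, classifications,
watertightness, invariances), not that the pipeline is robust to raw
clinical scan pathology.  Sample sizes mirror the study grid: 2 support
types x 4 bone qualities x 4 bone-loss depths (0–3 mm), with 10 fixture
seeds per support type for the classifier.

All randomness flows through one seeded generator; identical seeds give
byte-identical STL output, and the generator restores the caller's RNG
state.

## Known limitations

- The lumen labeling itself (splitting a raw scan into surface/lumen
  parts) is out of scope, as it was for the original workflow.
- Only single straight roots and symmetric two-root molars; no
  dilacerated or three-rooted anatomy, no PDL fibre model.
- One implant geometry family (straight, as configured); no
  manufacturer-specific systems.
- The `r_b` bore-step blend is accepted but not realised (see above).
- The voxel Boolean's surface error is second order in the pitch but not
  zero: molar-side interpenetration checks are resolution-limited, while
  premolar-side checks are exact because those surfaces are shared
  vertex-for-vertex.
- The FEA solve, meshing into quadratic tetrahedra, mesh-quality metrics
  and any stress results are out of scope; the package's deliverable is
  the labeled geometry and the `assembly.json` manifest (materials,
  bonded pairs, fixed base, frictionless end faces, 105 N over three
  occlusal patches near the middle connector).
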