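# fpdgen

Parametric generation of tooth-type and implant-type supports for 4-unit
fixed partial dentures (FPDs), as watertight triangle meshes ready for
structural (finite-element) preprocessing.

## What it does, and for whom

A 4-unit bridge (first premolar to second molar) is supported either by
two prepared natural teeth or by two implants.  Predicting how
peri-support bone loss and bone quality affect the stresses in bridge and
bone requires a complete solid model — cement layers, tooth roots with
periodontal ligament (PDL) or titanium implant hardware, and a mandibular
bone segment with the supports embedded and crestal defects carved.
`fpdgen` automates that model construction for biomechanics groups and
dental-CAD researchers: from a labeled FPD mesh (multi-solid STL with
`surface`, `distal`, `mesial` parts) it

1. **aligns** the FPD to a canonical frame (lumen margin centres, minimal
   oriented bounding box, gingival-face detection);
2. **detects the support type** from the lumen cross-sections via the
   circularity index

   CI = mean over retained section curves of 4&pi;A/Pe&sup2;,

   which is 1 for circles; CI &in; [0.97, 1] on both lumens reads as
   implant support, anything else as tooth support;
3. **generates the support**: cement shells by normal offsetting; a
   single-root premolar and a two-root molar by cubic-Bezier-graded
   section scaling B<sub>x</sub>(t), B<sub>y</sub>(t) (and &plusmn;B<sub>T</sub>(t)&middot;d<sub>R</sub> root
   translation) lofted along the root axis; PDL shells of constant
   thickness; or abutment + implant body with a helical metric V-thread +
   abutment screw;
4. **inserts** the assembly into a layered bone segment (Misch qualities
   D1&ndash;D4: cortical thickness 2.5/2.0/1.5/1.0 mm, 0.29 mm graded
   transition zone) with a configurable crest gap, Boolean-subtracts the
   cavity, **carves saucer-shaped crestal defects** (depth 0&ndash;3 mm, width
   10 mm, 0.4 mm fillet) and trims the PDL to the bone;
5. **evaluates the material models** used downstream: the elastic
   registry, the linearly graded cortical&rarr;cancellous modulus, and the
   incompressible first-order Ogden PDL law
   &sigma;(&lambda;) = &mu;&#8321;(&lambda;^&alpha;&#8321; &minus; &lambda;^(&minus;&alpha;&#8321;/2)) with
   &mu;&#8321; = 0.006 MPa, &alpha;&#8321; = 29.8.

The finite-element solve itself is out of scope; the pipeline ends with
per-part STL export and an `assembly.json` manifest (material labels,
bonded interfaces, fixed base / frictionless sides / 105 N occlusal load
description).

Everything is built on the package's own mesh kernel (boundary loops,
minimal oriented boxes, plane sections, normal offsets, lofts, exact BSP
Booleans plus a signed-distance marching-tetrahedra Boolean, multi-solid
STL I/O).  Deterministic synthetic fixtures — a tooth-variant FPD with
non-circular lumens, an implant variant with near-circular lumens, and a
parametric mandible segment — stand in for scanned geometry.

## Worked example

```r
library(fpdgen)

fx  <- make_fpd_fixture("implant", seed = 1)   # synthetic scan, random pose
al  <- align_fpd(fx$fpd)
det <- detect_support(al$fpd)
sprintf("support type: %s  (CI distal %.4f, CI mesial %.4f)",
        det$support_type, det$ci_distal$ci, det$ci_mesial$ci)
#> "support type: implant  (CI distal 0.9998, CI mesial 0.9997)"

parts <- generate_implant_support(al)
g   <- attr(parts$implant_distal, "geom")
sec <- section_with_plane(parts$implant_distal,
                          frame3d(c(g$centre_xy, g$z_neck - 0.01)))
# neck diameter 5.000 mm, body length 8.0 mm, cement wall 0.0998 mm

bone <- make_bone_fixture("D2")
bf   <- build_bone_frame(bone, span = 30)
placed <- place_assembly(c(al$fpd[c("surface", "distal", "mesial")], parts),
                         frame3d(), bf, d_bone = 2.8, bone = bone)
bone <- subtract_assembly(bone, placed[c("implant_distal", "implant_mesial")])
bone <- carve_defect(bone, defect_spec(depth = 2,
                                       sites = c(bf$p_distal[1], bf$p_mesial[1])))
is_watertight(bone$outer)
#> TRUE
```

The detection line says both lumens are nearly perfect circles (CI about
1), so the bridge is implant-supported; the realised dimensions match the
configured ones (5.0 mm implant neck, 0.1 mm cement); and the bone
segment remains a closed solid after the cavity subtraction and the 2 mm
saucer defect.  `export_assembly(case, dir)` writes the labeled STLs and
the solver manifest.

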