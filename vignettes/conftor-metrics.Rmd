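---
title: "Conformational-vector metrics for ABC transporter structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational-vector metrics for ABC transporter structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conftor)
```

## The problem

ABC Type I exporters alternate between conformations — inward-facing
(with open or closed nucleotide-binding domains, NBDs), outward-facing,
and occluded — and the growing number of cryo-EM and crystal structures
makes qualitative, eyeball comparison of these states unreliable. This
package implements a small vocabulary of standardized, quantitative
measures built from *conftors* (conformational vectors): directed
segments between anchor points of annotated structural regions. An
anchor is either a single Calpha or the center of geometry (COG) of a
Calpha set; a conftor is the vector from an origin anchor to a tip
anchor. Angles between conftors and distances between their endpoints
are invariant under rigid-body motion of the structure, so conformations
can be compared *without* choosing a reference structure or
superposition — superposition (Kabsch) is only needed for visualization
frames and RMSD.

## The conftor registry

`builtinConftorRegistry()` defines the standard set for Type I
exporters. In the domain-swapped architecture, helices TH4–TH5 and
TH10–TH11 cross from one transmembrane domain (TMD) to the opposite
NBD; their end-COG vectors THX1 and THX2 are the workhorse
membrane-region conftors. THV1/THV2 are the single-helix variants along
TH4 and TH10. ICV/ICX continue the same helices below the membrane
(intracellular domains, ICDs); NBDV/NBDX run from coupling-helix (CH)
COGs to the first residue of strand S9, the last NBD strand; S6, WAH and
WAH1_SIG2/WAH2_SIG1 connect the two NBDs through their S6 strands,
Walker A helices and signature motifs (one per composite ATP site).

Membrane-region conftors point from the intracellular to the
extracellular helix end. Which physical end of an annotated range is
"intracellular" is decided by projection onto the membrane normal; when
no membrane model is supplied, the end closer to the COG of the
annotated NBD regions is taken as intracellular. If a sequence-anchored
TM conftor still violates the convention, origin and tip are swapped
and a warning is emitted.

Three genuinely open choices were resolved as follows and are
deliberately overridable through `conftorSpec()`/the annotation file:

* *Which regions feed which conftor.* ICV1/ICV2 default to ICD1/ICD3,
  ICX1/ICX2 to the pairs ICD1+ICD2 / ICD3+ICD4, and NBDX1/NBDX2 to
  CH1+CH2 → S9_1 and CH3+CH4 → S9_2. The registry only names regions;
  the per-structure annotation table decides which residue ranges (and
  hence which coupling helices contact which NBD) carry those names, so
  the domain-swap assignment is data, not code.
* *Helix-end anchors* default to the Calpha of the terminal residue of
  the annotated range, with a configurable window (COG over the window
  when > 1). A missing terminal Calpha is substituted by the nearest
  resolved residue up to 2 positions inward, with a warning — silent
  substitution would corrupt conftors, and unresolved cryo-EM termini
  are common.
* *Anchor vocabulary.* Besides `intracellular`/`extracellular`/`whole`,
  anchors accept the sequence ends `first`/`last`, because the NBD
  conftors are pinned to the *first residue* of S9 — a sequence-order
  notion, not a membrane-side one.

## Classification

The THX1–THX2 angle separates bottom-open inward-facing (46°), occluded
(26°) and the two remaining classes (39° and 35°); the ICV1–ICV2 angle
separates inward-facing (43°/38°), outward-facing (60°) and occluded
(53°). The THV angle only distinguishes occluded (≈23°) from everything
else (36–40°) and is carried for reference. `classifyConformation()`
assigns the nearest prototype in (THX, ICV) angle space (Euclidean
distance against the class-average signatures in
`conformationPrototypes()`). The class averages are separability
statistics, not a decision rule, so the rule here is the package's own
choice: nearest prototype with a 5° ambiguity margin between the two
best classes. When the ambiguous pair is the two inward-facing classes
and an NBDX ext length is available, the NBD separation breaks the tie:
above 40 Å (configurable) the structure is called bottom-open. The 40 Å
default is a heuristic — no published class-average ext lengths exist —
and is the one deliberately soft constant in the classifier.

`conftorLength()` exposes the NBD distance measures: `ext` is the
distance between the two origin anchors (coupling-helix COGs — the
NBD/TMD interface), `int` between the two tip anchors (S9 first
residues — the NBD bottom), `span` the length of a single conftor. The
ext/int naming mirrors which part of the NBDs the anchors sit on: the
interface stays put while the NBD bottoms approach each other during
closure, which is why the int distance is the natural trajectory
observable.

## Membrane placement metrics

The protein principal axis is the bisector of the *normalized* THX1 and
THX2 vectors (normalizing first makes the bisector well-defined for
unequal conftor lengths); the tilt is its angle to the membrane normal,
folded into [0°, 90°] because an axis has no sign. Membrane models come
from three sources: OPM-style DUMMY atoms (two boundary planes of `DUM`
pseudo-atoms; center = COG of all DUMMY atoms, normal = averaged
least-squares plane normal of the two layers oriented toward the layer
with greater mean z, thickness = plane separation along the normal),
leaflet bead sets (normal = unit vector between the upper and lower
leaflet PO4/NC3 bead COGs), or direct construction. Layer splitting
uses the sign of z after centering, which assumes the membrane is
roughly z-oriented, as OPM files are. `membraneZOffset()` reports the
*signed* distance between membrane centers along the reference normal
(positive = toward the extracellular side of the reference);
`comparePlacements()` reports signed z deltas but unsigned tilt deltas,
since tilt itself is a magnitude.

## Helix geometry

`helanalGeometry()` follows the classical sliding-window Calpha
construction: for every 4 consecutive Calpha, the two second-difference
vectors point radially toward the local helix axis and their cross
product (oriented along the chain) is the local axis; the angle between
successive second differences is the local twist and the projection of
the Calpha step onto the axis the local rise. A 9-residue window pairs
the local axes at its two ends — lag 5, since axes i and i+5 together
span residues i..i+8 — and their angle is the window's *bending angle*.
This pairing, rather than angles between successive overlapping window
axes, is what makes a sharp kink legible: a 30° kink yields a bending
angle of ≈30° at the windows straddling the junction, whereas
successive overlapping windows would dilute it to a few degrees each.
`detectBreaks()` simply thresholds the bending angles (default 20°),
which cleanly separates genuine helix breaks from the sub-degree
bending of an ideal helix.

Helix-end projections express each TM helix end in a 2D coordinate
frame of the membrane plane (deterministic in-plane basis: projection
of the lab x axis, or y when x is near-parallel to the normal). To
compare across structures, each structure is first superposed onto a
common reference over the shared annotated Calpha core and projected in
the *reference's* membrane frame; `compareEndProjections()` flags ends
displaced by more than 5 Å (default), chosen so a 10 Å displaced-helix
outlier flags robustly while ordinary conformational spread does not.
Whether the projection plane should be the membrane plane or the
reference's principal plane is not uniquely determined; the membrane
plane is the default and the frame is a parameter.

## Membrane-solvation grid configuration

`gridFromPqr()` generates Poisson–Boltzmann grid parameters for
APBSmem-style membrane-solvation scans, without running any solver: the
fine grid's z extent is −2·z_min + 40 Å (z_min the smallest z in the
PQR, which must be negative, i.e. the protein centered on the membrane
frame) so that the protein stays inside the fine grid across the whole
±20 Å membrane scan; medium and coarse grids are 2× and 5× the fine
grid; 161 grid points per axis; mobile ions 150 mM Na⁺/Cl⁻ with charges
+1/−1 and radii 0.95/1.81 Å. `emitScanPlan()` returns the membrane
z positions (default ±20 Å in 1 Å steps → 41 positions, 0 = the
reference placement). The template writer emits key=value fields
(including the `flooding` membrane-fill method) for an external solver.

## The synthetic generator, and what the tests do and do not show

`makeToyTransporter()` builds a 12-pseudo-helix assembly whose THX,
THV and ICV angles, NBD ext/int distances and membrane tilt take the
requested values *exactly* — helices are straight Calpha rods placed so
each metric is realized by construction, the assembly is tilted about
an in-plane axis while the OPM-style DUMMY membrane stays fixed.
Defaults describe a bottom-open inward-facing exporter (THX 46°, ICV
43°, NBD int 50 Å — the distance at which NBDs stabilize after closure
— ext 40 Å, tilt 0°, 30 Å membrane). `makeIdealHelix()` uses canonical
α-helix geometry (rise 1.5 Å, twist 100°/residue, radius 2.3 Å), and
`makeKinkedHelix()` rotates the second arm of an ideal helix about an
in-plane axis through the junction, so a 0° kink reproduces the ideal
helix bit-for-bit. `makeClosingTrajectory()` interpolates generator
parameters linearly across frames to emulate NBD closure.

These fixtures validate the *geometry engine*: anchor resolution, angle
and distance arithmetic, orientation conventions, invariances, and the
classifier against the published class signatures. They are not
chemically valid proteins; they contain no side chains, no bent or
broken TM helices (except where engineered), no annotation uncertainty
and no coordinate noise (unless `jitter` is set). Passing tests
therefore demonstrate correctness of the computation, not the
discriminative power of the conftor vocabulary on real structures —
the latter requires real PDB/OPM entries with curated annotations,
which is an online validation exercise by design.

Problem sizes used in the test and acceptance runs — a 5×4×3 grid of
toy transporters (60 structures of ~350 Calpha), 50 random point-set
pairs for the superposition oracle, 100 random rigid transforms for the
invariance sweep, 20-frame trajectories, 30-residue helices — were
chosen as the smallest sizes at which every property is exercised with
non-trivial geometry.

## Numerical choices

* Dot products are clipped to [−1, 1] before `acos`.
* Kabsch superposition uses SVD with the determinant correction that
  excludes reflections; collinear point sets (second singular value
  < 1e−8 of the first) are rejected rather than silently fitted.
* Conftors shorter than 0.5 Å are rejected as degenerate (anchor
  coincidence), and THX bisectors of antiparallel vectors are an error.
* Tie-breaks: altloc conformers keep the highest occupancy, ties going
  to altloc "A"; insertion codes sort after their base residue number.
* Tilt is folded into [0°, 90°]; all angles are reported in degrees,
  all lengths in Ångström.

## Known limitations

* The registry covers Type I exporters; no conftor set is provided for
  ABCG-type (Type II) transporters, whose architecture differs and for
  which too few distinct conformations exist to validate one.
* The THC3–THC9 naming space is reserved but ships without registry
  entries: their anchor constructions are structure-family-specific and
  should be supplied through `conftorSpec()` plus the annotation file.
* Residue equivalence across homologs comes entirely from the
  annotation table; no sequence alignment is performed.
* PDBTM/MEMPROTMD ingestion is limited to pre-extracted tilt/z tables
  (`comparePlacements()`); the package does not re-run TMDET or
  coarse-grained simulations, and it generates solver *configuration*
  only — no electrostatics are computed.
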