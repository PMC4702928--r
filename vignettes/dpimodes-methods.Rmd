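---
title: "Methods: contact detection, interaction modes and DNA shape in dpimodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact detection, interaction modes and DNA shape in dpimodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind
`dpimodes`: what each detector computes, which parameters matter and why
they have the defaults they do, what the synthetic-complex generator does
and does not emulate, and where the design was genuinely open.

## The analysis unit

The package analyzes *protein domain–DNA complex structures*: one
biological assembly, a domain-definition row (chain + inclusive author
residue range + domain and family identifiers, SCOP-style), and the
double-helical DNA present in the assembly. Waters are removed at load
(water-mediated contacts are out of scope); alternate locations are
reduced to the highest-occupancy conformer; only the first model of
multi-model entries is used. Covalent topology comes from embedded
heavy-atom templates of the standard residues with peptide and
phosphodiester links added when the link atoms are within 2.0 Å; unknown
residues fall back to a 2.0 Å distance rule and are kept so that they can
occlude contacts, while modified nucleotides are mapped to a parent base
through a small editable table.

## Duplex detection

Base pairs are detected geometrically rather than by an external helix
analysis program. A candidate pair must have a C1′–C1′ distance in
[8.5, 12.0] Å, base planes within 35°, and at least two inter-base N/O
distances ≤ 3.5 Å; candidates are accepted greedily (most hydrogen-bond
range atom pairs, then smallest mean distance) so that each nucleotide
pairs at most once. The windows are centred on Watson–Crick geometry
(C1′–C1′ ≈ 10.4 Å) but wide enough to accept non-canonical pairs that
satisfy the same criteria, since the classification does not restrict
pairing type. Pairs are chained into duplexes by stacking (adjacent
C1′–C1′ midpoints ≤ 5.5 Å); a single missing pair — a one-nucleotide loop
or base excision — may be bridged (≤ 11 Å) and is recorded as a gap;
longer breaks split the duplex. Runs shorter than 10 base pairs are
discarded, and only contacts to the surviving duplexes are typed. Pair
ordering within a duplex uses the principal axis of the pair midpoints,
which is robust for the gently curved helices the thresholds admit;
strongly kinked dimer-scale assemblies are ordered per contiguous run.

## DNA and protein elements

DNA atoms classify by name: backbone = deoxyribose + phosphate group
atoms; the major- and minor-groove lists are the published per-base atom
lists (e.g. adenine major {C5, C6, N6, N7, C8}, minor {N1, C2, N3, C4}).
Base atoms outside all lists — the glycosidic nitrogens — are
*unclassified*, and contacts through them are dropped from typing.

Protein residues are assigned helix/strand/loop from backbone
hydrogen-bond patterns in the Kabsch–Sander style: amide hydrogens are
reconstructed from the preceding carbonyl, the electrostatic energy model
defines bonds (E < −0.5 kcal/mol), n-turns give helices (two consecutive
4-turns → H, 3-turns → G, 5-turns → I) and bridge ladders give strands
(isolated bridges stay B). The element mapping is H, G, I → Helix;
E → Strand; B, T, C, S → Loop: π-helices are helices, but an isolated
β-bridge is not a strand segment. This internal assignment is
deterministic and rigid-body invariant, but it is not a clone of any
particular external program, and short 3₁₀ segments near termini are
exactly where assignment programs disagree; for replication studies the
`import_external_ss()` path reads Stride or DSSP reports and records the
source, so the assignment provenance of every mode is known.

## Contact criteria

Hydrogen bonds: two N/O atoms, one from the domain and one from duplex
DNA, closer than 3.7 Å, with hydrogen-bonding power above 0.1. The power
formula is a documented stand-in for the original database's unpublished
one, preserving its published decision boundary (cutoff 3.7 Å, threshold
0.1): `f_d(d) · g_a · g_b`, with `f_d` equal to 1 up to 3.0 Å and falling
linearly to 0 at 3.7 Å, and each `g` the cosine of the deviation between
the contact vector and the atom's idealized donor/acceptor direction (the
negated mean of unit vectors to its covalent neighbors), clipped to zero
beyond 90°. The formula is pluggable (`power_fun` argument). Ion pairs
such as lysine NZ–phosphate oxygen count as hydrogen bonds.

Hydrophobic contacts: two non-polar atoms closer than 5.4 Å, with a clear
line of sight, belonging to the same hydrophobic cluster. The non-polar
set is all protein carbon and sulphur atoms not covalently bonded to
oxygen or nitrogen, plus every DNA carbon. Clusters are single-linkage
components over this set with the same 5.4 Å/line-of-sight edge rule and
a minimum size of 5 atoms; linkage and size are configurable since the
reference clustering's parameters are unpublished.

The line-of-sight test asks whether another atom's van der Waals sphere
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å; hydrogens ignored) *separates*
the two atoms. The test segment runs between the two atomic surfaces —
the segment of centers shortened by each endpoint's own radius. Testing
the full center-to-center segment instead would be degenerate: a covalent
neighbor's sphere (radius ≈ 1.7 Å at bond length ≈ 1.5 Å) always engulfs
the endpoint itself, so *no* atom pair in a real molecule would ever pass
and no hydrophobic contact could exist. With the surface-to-surface
segment, a blocker must genuinely intrude between the two atoms; only the
two endpoint atoms themselves are exempt from blocking.

All distance comparisons are strict (< 3.7, < 5.4), matching the stated
criteria.

## Modes, classes, reports

A domain instance's interaction mode is the set of distinct contact types
over all its typed contacts (a domain touching two duplexes contributes
one mode over the union). Canonical ordering is H < S < L then
Bb < Mj < Mn; machine labels are ASCII (`H-Bb`), display labels render as
`(H - Bb)`. Per-domain unions accumulate types over structures ("seen
once = possible for the domain"); the family class is the intersection of
unions, computed only for families with at least three distinct domain
identifiers, with the empty intersection reported as miscellaneous.
`build_reports()` reproduces the two summary tables: modes × (families,
structures), sorted by family count, and classes × (families, structures,
domains).

## DNA shape in contact zones

The contact zone is the set of duplex nucleotides contacting the domain
plus every nucleotide within two chain positions, clipped at duplex ends
and bridged interruptions. Shape values are computed when the zone holds
at least three base pairs.

Base-pair frames are least-squares (Kabsch) fits of the embedded standard
base-pair templates onto the observed base atoms; by construction of the
templates the frame origin lies on the local helix axis, z runs along it
and x points toward the minor groove. The per-step local axis is the
step's first base-pair normal, so the mean angle between consecutive
local axes (the axis bend) is exactly zero for straight fiber DNA, and a
bend introduced at a single step contributes its full angle once. A
screw-axis extraction was considered and rejected: composing a 36° twist
with a small bend tilts the crossing step's screw axis by substantially
more than the bend itself, inflating the statistic.

Groove widths follow the phosphorus backbone: a cubic spline through the
P atoms of each strand, the minimal inter-spline distance among segments
whose midpoint lies on the given groove's side of the nearest base-pair
frame, minus 5.8 Å (twice the phosphate-group reduction used by the
reference method). On internally generated fiber B-DNA this yields
5.87 Å (minor) and 11.14 Å (major) against reference values of 5.9 and
11.4; the small major-groove deficit is inherent to the pure-minimum
definition, which slides slightly below the perpendicular rung toward the
side boundary. Depth is the mean radial offset of the two width-segment
endpoints from the local axis minus the radial offset of the groove-side
base-atom surface, plus a per-groove constant (−0.59 Å minor, +0.51 Å
major) anchored so that fiber B-DNA reproduces the reference depths
(≈ 4.7 and ≈ 3.75 Å). Depths may be negative (everted grooves); they are
validated by sign and monotonicity, not numerically. A groove is reported
as undefined (a dash in reports) when fewer than three P atoms flank it.

Aggregation is exactly two-level: per-domain means over structures, then
per-family average/minimum/maximum over domains, skipping undefined
values.

## The synthetic-complex generator

The generator exists so that every pipeline stage can be tested against
known ground truth without downloading structures. Its DNA is an
embedded fiber B-form repeating unit applied at 36°/3.38 Å per step
(both configurable): planar base geometries from the chemical component
dictionary, an isomorphous Watson–Crick pair solved by least squares
against standard hydrogen-bond lengths (C1′–C1′ 10.84 Å), the phosphate
helix pinned at fiber values (radius 8.91 Å, phase 95.2° from the pair
dyad, 2.08 Å axial offset), and a deoxyribose bridge solved under
standard bond-length/angle/chirality constraints that converged to the
classic fiber backbone torsion set (−42, −146, 31, 157, 149, −91). The
unit was validated for Watson–Crick hydrogen-bond lengths (2.83–3.04 Å),
absence of steric clashes, phosphodiester continuity and the reference
groove geometry. An optional single-step bend rotates all downstream
pairs about a local in-plane axis, for axis-bend tests.

Peptide probes are ideal fragments built from φ/ψ torsions: a 12-residue
glycine helix (−57°, −47°), a pair of 5-residue antiparallel strands
(−139°, 135°) rigidly docked by optimizing the Kabsch–Sander energies of
the four ladder hydrogen bonds, and a 5-residue extended loop (−75°,
145°). The contact residue carries a single side chain: serine (OG) or,
for the deep minor groove, lysine (NZ) for hydrogen-bond designs; leucine
(CD1) for hydrophobic designs. Placement aligns the side-chain arm with
an approach direction chosen from clearance-ranked candidate directions
(hydrogen-bond designs stay within 60° of the acceptor's idealized
direction, keeping the designed power ≥ 0.25, 2.5× the threshold), then
searches the free spin angle, side-chain rotamers and both duplex ends.
An orientation is accepted only when every stray atom pair that could
approach a contact criterion either realizes the designed type, involves
an unclassified DNA atom (dropped from typing), scores far below the
power threshold (< 0.05), or is robustly occluded; otherwise placement
fails with an error rather than silently weakening the ground truth.

Two limitations are deliberate. First, minor-groove *hydrophobic*
designs are unsupported: any non-polar atom within 5.4 Å of a
minor-groove floor atom is also within 5.4 Å of the backbone sugar
carbons that form the groove walls, so a "pure" minor-groove hydrophobic
contact cannot exist with safety margins; the generator realizes
minor-groove types through hydrogen bonds instead. Second, the fragments
are idealized — no rotamer libraries, no refinement, no sequence
diversity beyond the designed side chain — so passing fixture tests
demonstrates correctness of the detectors and the set algebra on clean
geometry, not robustness to crystallographic noise, missing atoms or
assignment ambiguity in real structures. For real data the
Stride/DSSP import path and the configurable thresholds are the relevant
controls.

Generator defaults (12-mer `GCGCAATTGCGC`, 36°/3.38 Å, probe seed
20151209) are fixed once; the test batteries (50 randomized fixtures, 20
family scenarios, 100 rigid transforms per fixture, oracle comparisons on
≤ 500-atom structures) use these conditions with fixed seeds. Problem
sizes were chosen as the smallest that exercise every code path — a
12-mer duplex already contains both grooves, both strands and both ends.

## Degenerate inputs and tie-breaks

Structures without DNA, or whose DNA falls below 10 bp, yield
non-interacting modes flagged as such. Residues with missing backbone
atoms are assigned Loop with a warning. Greedy pair acceptance breaks
ties by mean hydrogen-bond distance; frame fits require at least three
matched base atoms; groove sides are assigned by the sign of the
midpoint's coordinate along the nearest frame's minor-groove axis.
Domain instances contacting no duplex produce empty zones and undefined
shape values, which aggregation skips and reports render as dashes.

## Known limitations

- The hydrogen-bonding power formula is a stand-in with the published
  cutoff and threshold; absolute power values are not comparable to the
  original database's, only the accept/reject boundary semantics.
- The internal secondary-structure assignment can disagree with Stride
  exactly where published mode variation arises (short terminal 3₁₀
  segments); use the import path for replication.
- Groove width uses the pure minimal inter-spline distance; on ideal DNA
  the major groove reads ≈ 0.27 Å below the reference method.
- Coaxially stacked helices from different chains are split unless the
  stacking criteria hold across the junction.
- Corpus-scale results (mode/class counts over a structure-database
  snapshot) depend on the input corpus definition and are outside the
  package's scope; the corpus is an input.
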