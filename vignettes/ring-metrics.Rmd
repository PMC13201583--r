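---
title: "Quantitative metrics for two-tier hexameric helicase rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative metrics for two-tier hexameric helicase rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmetrics)
```

## Background

The replicative helicase engine of archaea and eukaryotes is the hexameric
MCM ring: six AAA+ ATPase subunits stacked as two tiers, an N-terminal
(OB-fold) tier and a C-terminal ATPase tier, encircling DNA in the central
channel.  Replication initiation requires the ring to locally melt fully
base-paired DNA.  Cryo-EM snapshots of MCM:DNA complexes capture this
progression as discrete states that differ in four measurable ways: how
many inter-subunit ATPase interfaces are tight, how far the two tiers are
rotated against each other, which cyclic arrangement ("setting") of the six
ATPase cores the ring adopts, and how many base pairs of the encircled
duplex have lost their partner.  `ringmetrics` implements these four
metrics as reproducible geometry on coordinate models, together with a
synthetic generator that manufactures rings and duplexes whose ground truth
is programmed exactly, so every metric is testable at desk scale.

## The four metrics

### Tight/loose interface classification

Each of the six ATPase sites is bipartite: subunit *i* contributes the
Walker-A motif, subunit *i+1* the arginine finger.  Two CA-CA distances
summarize the interface: the Walker-A P-loop proline to the residue four
before the arginine finger (ATP-site distance), and the h2i leucine to the
neighboring ps1-beta lysine (h2i-ps1b distance).  An interface is **tight**
iff both distances fall strictly below their thresholds (6.8 and
8.0 Angstrom; `interface_criteria()`).  Strict inequality follows the
definition of the criteria; values exactly at a threshold classify loose.
Because printed tables round to three decimals, classification is always
done on full-precision distances when coordinates are available, and
`classify_from_distance_table()` re-applies the rule to printed values.
Interfaces that border a disordered ATPase domain are reported
*unmeasurable*, never silently loose, and are excluded from the tight
count.

### Inter-tier dihedral

For each subunit a four-point torsion is computed: OB-fold anchor CA,
N-tier centroid, C-tier centroid, AAA+ anchor CA.  The tier centroids pool
the 107 OB-fold CAs and the 152 AAA+ core CAs of all six subunits.  A mean
dihedral above -15 degrees bins the ring *eclipsed* (tier interface seams
aligned), below -25 degrees *staggered*.  The band between is reported
*indeterminate* rather than force-binned; observed structures do not fall
in it, and an honest third label is preferable to an arbitrary tie-break.
The mean is the arithmetic mean after wrapping each angle into
(-180, 180]; a circular mean would differ only for angle spreads far
beyond anything observed (all real per-subunit values sit within a
±40-degree band), and the simpler statistic is transparent.  This is a
documented limitation for pathological inputs.

The torsion sign convention is the standard biomolecular one and is pinned
by construction in the tests: rotating the first point about the central
axis by +25 degrees and using the image as the fourth point yields exactly
+25 degrees.

Two modes supply the tier point sets.  *Direct* mode uses each chain's own
CAs within the anchor-set residue spans (the archaeal case, where every
subunit shares one numbering).  *Template* mode rigid-fits a reference
OB-fold and core onto each subunit and pools the transformed copies,
transferring the two dihedral anchors with the fitted transforms; this is
the route for heterohexamers whose per-subunit residue spans are not
shipped, and it requires a user-supplied residue correspondence.

### Six-setting core RMSD

The 152-residue AAA+ core is nearly invariant across MCM subunits, so the
collective arrangement of six cores can be compared between rings
irrespective of subunit identity.  `build_core_hexamer()` rigid-fits one
core template onto each chain and stores the transformed full template
copy, making all six copies exact rigid copies of one body (chains may be
partially disordered: at least 140 of the 152 corresponding CAs must
resolve, missing pairs are dropped from the fit, and the per-copy fit RMSD
is reported for audit).  `setting_rmsd()` relabels the reference copies by
one of the six cyclic rotations, concatenates all 912 CA pairs, and
performs a single global superposition; the RMSD of that one fit is the
setting score.  A per-copy-then-average alternative would hide collective
rearrangements, which are exactly what the comparison is for, so the
global definition is fixed as the package definition.  Settings are cyclic
rotations only - reflections are excluded because ring handedness is
physical.  Ties in the best setting break to the lowest index and are
visible in the returned table.

`bin_and_sort()` orders a set of analyzed structures the way the survey
figure does: eclipsed before staggered, sub-binned by best setting,
reverse-sorted by best RMSD, stable by structure id on ties.

### DNA melting and engagement

`find_register()` detects Watson-Crick pairs geometrically: complementary
bases with C1'-C1' <= 11.0 Angstrom and purine-N1 to pyrimidine-N3 <=
3.5 Angstrom.  The longest consistent antiparallel run defines the duplex
register; modeled nucleotides outside it whose register-implied partner is
unmodeled or fails the geometry are *unpaired*.  The numeric criteria are
package defaults chosen from canonical Watson-Crick geometry (C1'-C1'
about 10.4, N1-N3 about 2.9 Angstrom in B-DNA) because melting in the
source analyses was called by model inspection without a printed rule;
both are exposed in `contact_criteria()`.  "Melted" is operationalized as
"partner absent from the coordinate model", matching how disordered
complements manifest in deposited models; distorted-but-paired nucleotides
are not counted.  `melted_count()` counts unpaired tracked-strand
nucleotides contiguous with one duplex terminus (the ATPase-proximal one,
which for the generated fixtures is the tracked strand's 5' end - the
terminus is an explicit argument).

`engaged_nucleotides()` counts tracked-strand nucleotides having any
backbone phosphate/sugar atom within 3.6 Angstrom of a donor atom of the
conserved DNA-binding set: the ps1-beta lysine side-chain amine, the
following residue's backbone amide, the h2i hydroxyl side chain, and the
h2i backbone amide.  Engagement is monotone in the cutoff by construction.

## Residue anchors and ring direction

Anchor tables ship as editable YAML files under `inst/anchors/` (one per
species set) rather than hard-coded constants, so users can add species
whose anchors they derive by alignment; YAML is the package's structured
format because it round-trips cleanly through the installed tooling.  The
archaeal chimera set carries both construct and deposited numbering;
`map_chimera_numbering()` converts between them (the fused AAA+ domain is
offset by +1000 in depositions).  The eukaryotic sets carry the published
interface anchors for all six subunits of the yeast and human rings.  The
eukaryotic OB/core residue spans are not shipped - they derive from an
alignment that is not printed - so template-mode runs on heterohexamers
require a user-supplied correspondence, and the shipped configurations say
so.

Ring direction is fixed once: positions advance from the Walker-A face to
the arginine-finger face of the neighbor, the reference eukaryotic order
being Mcm2, 6, 4, 7, 3, 5 on chain positions A-F.  All interface notation,
dihedral signs and setting indices are defined relative to this
convention.

## The synthetic generator

`make_ring()` manufactures a two-tier ring with six (or n) subunits on a
circle (default radius 40 Angstrom, tier separation 45 Angstrom - typical
MCM dimensions).  Three properties hold to machine precision by
construction: the pooled tier centroids sit exactly on the ring axis; each
subunit's four-point dihedral equals its programmed twist (the C-tier
anchor is placed at azimuth theta_i + twist_i); and each interface's two
anchor distances equal the programmed values (partner anchors share an
azimuth and differ only in z).  Non-anchor pseudo-residues are a seeded
deterministic cloud, re-centered so every subunit's tier centroid is exact.
Pseudo-residues use real amino-acid names and the deposited numbering, so
fixtures exercise the same lookup paths as real depositions.  Identical
seeds give byte-identical mmCIF output.

`make_bdna()` builds an ideal B-DNA duplex (rise 3.38 Angstrom, twist 36
degrees per base pair) carrying P, C1', N1 and N3 atoms with canonical
cross-pair geometry, so the default pairing criteria succeed without
tuning.  `melted_5prime = m` omits the partners of the tracked strand's
first m nucleotides, emulating disordered melted complements.

What the generator does *not* emulate: side chains and sterics, density
quality, partial disorder gradients, sequence-dependent DNA geometry, and
the correlated deformations of real subunits.  Passing tests therefore
demonstrate that the metrics recover programmed geometry exactly and obey
their invariants - not that any particular real deposition will reproduce
a printed number; runs on real coordinate files use the same code paths
but depend on the user supplying those files.

## Numerical choices

* Superposition is the closed-form SVD (Kabsch) solution with a
  determinant guard excluding reflections; degenerate (collinear) inputs
  error.  Optimality is tested against a dense random-rotation search and
  an independent least-squares implementation.
* Classification thresholds are strict inequalities; classification uses
  full-precision distances, never re-rounded values.
* Multi-model files take model 1 with a warning; altlocs keep the
  highest-occupancy conformer (first on ties); insertion codes are
  rejected outright (none occur in the target structures) - a documented
  limitation rather than a guessed semantics.
* Tier-pool coverage floors: 90% of span residues per chain for
  centroids, 140/152 for core-hexamer fits; below the floor the chain (and
  with it the analysis) errors rather than silently degrading.
* The workflow scripts and test suite run on six-subunit rings with 259
  pseudo-residues per subunit and 24-30 bp duplexes; these sizes keep the
  whole suite deterministic and fast while exercising every code path at
  full hexamer scale.

## Known limitations

* No real depositions are bundled; analyses of deposited structures
  require local coordinate files.
* Eukaryotic setting-RMSD and template-mode runs need user-supplied core
  correspondences (see above).
* The arithmetic-mean dihedral is not a circular mean (pathological angle
  spreads only).
* Aromatic-wedge stacking geometry and non-Watson-Crick pairing
  (Hoogsteen, quadruplex) are out of scope.
* Heptamers are supported by the generator, but the interface and setting
  analyses are defined for hexamers.
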