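---
title: "Surveying DNA-protein pi-interactions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying DNA-protein pi-interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisurvey)
```

## The problem

Aromatic amino-acid side chains (Phe, Tyr, Trp, His) interact with DNA in two
geometrically distinct ways: with the nucleobase pi-system (pi-pi contacts,
from face-to-face stacking to edge-to-face T-shaped arrangements) and with
the deoxyribose sugar (C-H...pi and lone-pair...pi contacts of the sugar
"edge" against the aromatic face). Both families are individually weak
(a few to a few tens of kJ/mol) but abundant at DNA-protein interfaces, and
both are routinely missed or mislabelled by naive distance-only contact
definitions. `pisurvey` implements a reproducible geometric survey of both
families in crystallographic coordinates, plus preparation of truncated dimer
models for quantum-chemical evaluation of their strengths.

## Pipeline overview

1. **Input.** PDB coordinate files are parsed with `bio3d`. Only model 1 is
   used, and alternate locations are collapsed to one conformer per atom
   (highest occupancy, ties to altloc "A") so all downstream geometry is
   deterministic. A dataset manifest (CSV) can be filtered with
   `select_dataset()`: X-ray entries, resolution strictly better than 2.0 A,
   sequence identity below 90%, released before a cutoff date.
2. **Moiety extraction.** Fixed atom-name dictionaries define the aromatic
   rings (Phe/Tyr 6 atoms, His 5, Trp the full 9-atom bicyclic system),
   nucleobase rings (purine 9, pyrimidine 6) and the deoxyribose unit
   (C1'-C4' + O4', with C5'/O5'/O3'/P tracked). Residues with incomplete
   rings are skipped with a logged reason, never silently dropped or
   patched.
3. **Screening.** Every (aromatic ring, nucleobase ring) and (aromatic ring,
   deoxyribose) pair whose closest heavy-atom distance is strictly below
   5.0 A becomes a candidate. "Heavy atoms of the moiety" means ring atoms
   plus exocyclic substituents (Tyr OH, base carbonyl/amino/methyl groups;
   for sugars C1'-C5' and O4', excluding the backbone O5'/O3'/P).
4. **Validation and classification** (below).
5. **Aggregation.** `aggregate_contacts()` computes contact totals,
   per-structure distributions, frequency tables by residue, category, edge
   role, sugar class and atom labels, a 5-degree tilt histogram and a 0.1 A
   distance histogram.

## Validating a pi-pi contact

Published surveys of this kind rely on human visual inspection to decide
whether a screened pair is a genuine pi-interaction rather than, say, two
coplanar rings sitting side by side. That step cannot be reproduced exactly;
`pisurvey` substitutes an explicit geometric test whose thresholds live in
`validity_criteria()` and in the YAML config:

* a candidate is **valid** when at least `min_participating_atoms` (default
  2) ring atoms of one monomer lie within `max_perpendicular_height`
  (default 4.5 A) of the other monomer's best-fit plane **and** project
  inside its ring polygon expanded by `max_lateral_offset` (default 1.5 A).

The lateral-offset condition is what rejects the classic false positive:
coplanar side-by-side rings have near-zero mutual plane heights but project
far outside each other's polygons. The defaults were chosen to accept the
canonical stacked (rise ~3.4 A) and T-shaped archetypes and reject coplanar
and beyond-cutoff constructions; they are deliberately exposed because they
are a surrogate, not ground truth.

## Tilt classification and edge roles

The tilt angle omega is the angle between the two best-fit ring-plane
normals (smallest-singular-vector planes over the ring atoms only - never
exocyclic atoms), folded into [0, 90] degrees. Categories use half-open
bins so every angle has exactly one class:

* stacked: omega in [0, 20)
* inclined: omega in [20, 70)
* T-shaped: omega in [70, 90]

The source convention is ambiguous exactly at 20 and 70 degrees; the
half-open choice here is a documented tie-break, and the boundary behaviour
is pinned by tests.

For non-stacked contacts the **edge** monomer is the one whose ring atoms
pass the face-participation test against the other's plane (the edge pokes
at the face; the face's atoms project outside the edge ring's polygon). If
both pass, the monomer with more participating atoms is the edge; remaining
ties go to the nucleobase. Stacked contacts are face-to-face by definition.

## The sugar-edge taxonomy

Crystal structures at survey resolution have no hydrogens, so the seven
sugar hydrogens are built geometrically: ideal tetrahedral completion with
C-H 1.09 A / O-H 0.96 A / N-H 1.01 A (`build_hydrogens()`). This replaces
the quantum-mechanical proton optimization used in energy work; for
classification only directions matter, and the idealized positions are
deterministic and rigid-motion invariant.

Labels are H1a, H2a/H2b, H3, H4, H5a/H5b plus the ring oxygen O4'. At the
prochiral centers C2' and C5' the "a" hydrogen is the one on the positive
side of the chirality reference normal cross(O4'->C1', O4'->C4') (the sign
of the corresponding triple product). This convention is internal to the
package: the field's figures depict but do not define an a/b rule. It is
deterministic, invariant under rigid motion, and swaps under mirror
inversion, which is what the tests check. Note one consequence: with this
rule the two co-facial C1'/C2' hydrogens are H1a and H2a, so a two-proton
bridge involving C1' and C2' is labelled "H1a-H2a" here even where other
depictions would write H1a-H2b.

A sugar atom **participates** against an aromatic face when its
perpendicular height is at most 4.0 A and its projection falls within the
ring polygon + 1.5 A; hydrogens must additionally point at the ring - the
X-H vector within 60 degrees of the inward plane perpendicular
(C-H...pi directionality). O4' has no directionality condition. The
participating set determines the class:

| participating atoms | class |
|---|---|
| 1 H | single proton |
| 2 H | bridged |
| 3 H | face |
| O4' only | lone pair |
| O4' + >=1 H | lone pair-proton |

More than three participating hydrogens is classified as a face using the
three closest to the plane and noted in the contact's reason field. O3'/O5'
lone pairs are not scored by default (surveyed lone-pair contacts involve
O4'); a flag exists for exploration. A residue pair exhibiting both a
base-pi and a sugar-pi geometry yields two rows - the overlap is visible in
the tables rather than silently collapsed, and His is surveyed once (its
protonation variants exist only in the QM model preparation).

## QM model preparation and energy composites

`cap_nucleobase()`, `cap_amino_acid()` and `cap_sugar()` cut each monomer
out of its polymer context and cap the cut bonds with hydrogens: the
glycosidic bond becomes N-H (1.01 A, along the former C1' direction), the
amino-acid C-beta link becomes C-H, and the sugar loses its base and both
phosphorus atoms. The sugar's hydroxyl-defining dihedrals
angle(C4'-C5'-O5'-H) and angle(C4'-C3'-O3'-H) are frozen to the crystal O-P
torsions and recorded in the model (terminal residues without a phosphorus
fall back to a flagged default of 180 degrees). His is produced as three
variants (N-delta/N-epsilon neutral tautomers and the +1 cation:
imidazole C3H4N2, 9 atoms; imidazolium C3H5N2+, 10 atoms), Tyr as two
in-plane hydroxyl orientations (CW/CCW). `overlay_reference()` positions an
externally optimized (or the built-in idealized) monomer template in the
crystal frame by Kabsch RMS fitting of the ring heavy atoms, leaving its
internal geometry untouched. Dimers go out as standard XYZ with a JSON
sidecar carrying fragment ranges (for counterpoise bookkeeping), charges
and frozen dihedrals; no electronic-structure code is run by this package.

The arithmetic implemented for ingested engine energies:

* binding energy: Delta E = E_dimer - E_aa - E_nt, reported in kJ/mol
  (1 hartree = 2625.4996 kJ/mol);
* two-point CBS extrapolation of correlation energies at consecutive
  cardinal numbers X < Y: E_CBS = (Y^3 E_Y - X^3 E_X) / (Y^3 - X^3), with
  the mean-field reference taken at the larger basis (common practice where
  the reference basis is unstated);
* CCSD(T)/CBS composite: E = E_MP2/CBS + (E_CCSD(T),small - E_MP2,small).

All three are pinned by closed-form tests (the n^-3 series
E(n) = -1 + 0.5 n^-3 must extrapolate to exactly -1).

## The synthetic-structure generator

`build_pi_dimer()`, `build_sugar_fixture()` and `build_survey_corpus()`
generate coordinate fixtures with fully known ground truth, standing in for
a large downloaded crystal-structure corpus so every classifier is testable
offline. The generator emulates:

* idealized planar monomers placed at a controlled tilt (rotation about a
  ring bond free of heavy exocyclic substituents), with the closest
  heavy-atom separation solved to the requested value by bisection on a
  vertical shift - so requested omega and d_min are exact ground truth;
* a C2'-endo deoxyribose presenting a chosen atom set to an aromatic face,
  found by a deterministic orientation search that starts from the mean
  direction of the requested atoms and verifies that exactly the requested
  set participates;
* decoys: beyond-cutoff pairs, coplanar side-by-side traps, and sugars with
  all hydrogens averted;
* corpus composition following the frequencies observed in the published
  survey of DNA-protein complexes (pi-pi : sugar-pi roughly 60:40; within
  pi-pi, stacked ~58%, inclined ~29%, T-shaped ~13%, T-shaped edges mostly
  nucleobase; residue draws weighted toward T and Phe/Tyr), applied by
  largest-remainder allocation so requested mixtures are met exactly;
* per-structure random rigid motions, with optional Gaussian jitter
  (default 0).

What it does **not** emulate: real sugar-pucker variation, thermal
disorder, crowded interfaces where several moieties compete at marginal
geometry, modified bases, or coordinate error correlated with structure.
Passing the recovery tests therefore demonstrates that the geometric
machinery is self-consistent and exact on clean geometry - not that the
validation surrogate reproduces any particular human accept/reject decision
on borderline experimental contacts.

Determinism: a corpus is a pure function of (parameters, seed); regenerated
corpora are byte-identical, which is itself under test.

## Numerical choices and degenerate inputs

* Plane fits reject collinear point sets; tilt uses |n_a . n_b| so normal
  signs never matter.
* Kabsch superposition excludes reflections (determinant correction) and
  errors on length mismatches or degenerate point sets.
* Dihedrals follow the IUPAC sign convention, errors on coincident or
  collinear consecutive points.
* The distance screen is strictly `<` at the cutoff; candidate sets are
  monotone in the cutoff.
* Histogram bins are half-open with a closed last bin, so domain maxima
  (omega = 90) are counted once.
* Sugar fixtures snap to a nominal 2.8 A approach height; the orientation
  search may raise it in 0.3 A steps when a requested single atom cannot
  otherwise be isolated, and the realized height is what the manifest
  records.
* Problem sizes used by the shipped tests and acceptance script - corpora
  of 150-200 structures, 100-instance oracle comparisons, 50-fold rigid
  motions - were chosen as the smallest sizes that exercise every class
  and boundary.

## Known limitations

* mmCIF input is not implemented (no installed reader; PDB covers the
  survey corpus).
* Crystallographic symmetry mates are not expanded; deposited coordinates
  only. Contacts across symmetry interfaces are invisible.
* The visual-inspection surrogate is threshold-based; exact reproduction of
  a human survey's accept/reject decisions on borderline geometry is not
  claimed, and the thresholds are exposed in the config for sensitivity
  analysis.
* Hydrogens are idealized, not energy-optimized; sugar C-H directionality
  is therefore approximate at the ~1 degree level of the tetrahedral
  idealization.
* Binding energies are bookkeeping over an external engine's numbers; the
  package prepares geometries and composites but never computes energies.
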