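---
title: "Structural analysis of glycoprotein hormone receptor transmembrane domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of GPHR transmembrane domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gphrtmd)
```

# The analysis

The glycoprotein hormone receptors (GPHRs) — the thyroid-stimulating,
follicle-stimulating and luteinizing hormone receptors (TSHR, FSHR, LHR) —
are class A G protein-coupled receptors whose seven-helix transmembrane
domain (TMD) switches between an inactive and an active conformation. This
package implements the structural reading of that switch as a pipeline:
generic residue numbering anchored at conserved motifs, detection of the
local helix distortions that shape the bundle, distance-based
classification of inter-residue interactions, a small diagnostic panel
("activation fingerprint") that calls the conformational state, a rigid
comparison of an inactive/active pair in terms of per-helix movements and
TM6 rotation, and a qualitative annotator that rationalizes activating and
inactivating mutations from the interaction environment of the mutated
residue.

# Ballesteros-Weinstein numbering

Residues are labelled `helix.position` with the most conserved residue of
each helix fixed at position 50. The anchors are taken from the class A
sequence motifs: 2.50 is the Asp of `NLxxxD` (TM2), 3.50 the Arg of
`E/DR(Y|W)` (TM3), 6.50 the Pro of `C(W|M)xP` (TM6) and 7.50 the Pro of
`NPxxY` (TM7). TM1 and TM4 use the single conserved Asn/Trp inside the
annotated helix; both are user-overridable because some sequences carry
more than one candidate. The GPHRs lack the TM5 proline — they carry an
alanine at 5.50 (Ala593 in TSHR) — so the TM5 anchor is always supplied
explicitly for these receptors.

Within a helix, labels are plain arithmetic offsets from the anchor:
residue `n` gets position `50 + n - anchor`. No bulge or insertion
sub-labels are used; every published assignment for these receptors that
the package reproduces obeys plain arithmetic. Two TSHR positions appear
in the mutagenesis literature with inconsistent labels (Phe634 as 6.45 or
6.54, Asn670 as 7.40 or 7.45); the arithmetic from the motif anchors gives
6.45 and 7.45 and the package reports those.

When a motif matches more than once, hits inside the expected helix are
preferred and the first in sequence wins with a warning; a missing
required motif with no override is an error that names the helix.

## Packaged sequences are pinned reconstructions

The package ships no full-length receptor sequences. `gphr_sequence()`
returns a *synthetic pinned-residue reconstruction*: every residue
identity that published motif annotations and mutation tables place at a
specific author number is planted at that number, and all remaining
positions are leucine filler chosen so no spurious motif hit or anchor
candidate arises. Numbering, anchor inference and every label the package
reports depend only on the pinned positions, so the output matches the
genuine receptors at every annotated site; the filler positions carry no
information and should not be used as sequence.

# Helix geometry

**Axis fitting.** A window (default 7 residues, odd) slides along the CA
trace. Within each window the local axis direction is estimated from
second differences of consecutive CA positions: `u_i = CA_{i-1} - 2 CA_i +
CA_{i+1}` points radially toward the helix axis, and the cross product of
consecutive `u_i` lies along the axis (exactly so for an ideal helix).
Averaging these cross products over the window gives a direction that is
stable even for 5-residue windows, where a principal-component fit of the
raw coordinates is badly conditioned. Directions are oriented N-terminal
to C-terminal so kink signs never arise.

**Kinks.** The kink angle is the maximum angle between axis directions of
two windows separated by one full window length (so they share no residues
and straddle the apex); the apex is the residue at the centre of the
maximizing gap. The calling threshold is 15 degrees: ideal helices measure
below 5 degrees under the generator's coordinate noise and canonical
proline kinks run roughly 20-35 degrees, so the two populations separate
cleanly. The threshold is a package decision — the receptor literature
describes these kinks qualitatively, without printing angles.

**Bulges.** An alpha-bulge is detected from the backbone hydrogen-bond
registry, its defining feature: carbonyl O(i) is paired with amide N(i+4)
in a regular helix, and a bulge shifts at least one pairing to N(i+5).
The test is a heavy-atom O...N distance at most 3.5 Angstrom, so no
hydrogen positions are needed — deliberate, because the crystal templates
this pipeline is calibrated against are deposited without hydrogens. A
planted bulge also bends the helix noticeably; the kink detector will
report a large angle on a bulged helix, which is physically reasonable and
deliberately not suppressed.

# Interaction classification

Contacts are classified by the first matching rule on a fixed distance
ladder (all values Angstrom, all heavy-atom, no angle terms):

| tier | atoms | band |
|---|---|---|
| salt bridge | opposite charged-group N/O | <= 4.0 |
| hydrogen bond | donor-acceptor | <= 3.5 |
| weak polar | donor-acceptor | 3.5 - 4.0 |
| aromatic | ring atom pair | <= 4.5 |
| hydrophobic (strong) | apolar C pair | <= 4.0 |
| hydrophobic (weak) | apolar C pair | 4.0 - 4.5 |
| induced dipole | polar/charged vs apolar C | <= 4.5 |
| water-mediated possible | donor-acceptor | 4.0 - 6.0 |

The ladder is calibrated to worked distances from the GPHR modelling
literature: 3.4 between apolar carbons is an interaction, 3.8 between
side-chain N/O is a weak polar bond, 4.6 between tyrosine hydroxyls is
non-interacting but compatible with a bridging water, and 4.9 between
apolar carbons is nothing. The water-mediated band is always reported as a
flag alongside whatever else matched and never counts as a direct contact
on its own. Histidine is typed as donor, acceptor and aromatic — not
charged. Backbone amide/carbonyl atoms participate as donors/acceptors by
default (`atom_typing(include_backbone = FALSE)` disables this, and the
sparse-fixture tests use that mode). All cutoffs live in
`interaction_cutoffs()` and are overridable.

Contact maps cover inter-helix pairs plus intra-helix pairs more than four
residues apart, with a 16 Angstrom CA prefilter for speed.

# The activation fingerprint

Two features decide the state call, because they are the two the
structural literature treats as decisive and quantifies:

* **ionic lock** — minimum charged-group distance Arg3.50 to Asp/Glu6.30;
  present at <= 4.0 (inactive hallmark). If either position is not an
  ionizable pair the panel reports `not_applicable`.
* **tyrosine toggle** — minimum side-chain distance Tyr7.53 (NPxxY) to
  Tyr5.58; `bonded` <= 4.0, `water_mediated_possible` 4.0-6.0 (the active
  hallmark: the two tyrosines hydrogen-bond through a water),
  `apart` > 6.0.

The call is `inactive_like` when the lock is present, `active_like` when
the lock is demonstrably absent and the toggle is not apart, and
`indeterminate` otherwise. The hydrophobic-core panel (3.43 against
6.40/6.41/2.46, 5.50 against 3.40/3.44), the Asp2.50 hydrogen-bond network
(partners among 7.49, 7.46, 3.39) and the GPHR-specific 3.30-4.58 contact
are computed and reported but do not vote: no published distance threshold
exists for them, and a silent vote would be false precision. Missing
residues degrade the affected panel entry to `unavailable` rather than
failing.

# Conformational comparison

Structures are superposed by closed-form least-squares rotation
(reflection-guarded) over CA atoms matched by identical BW label. Helix
movements are then reported per helix end as the mean displacement of the
terminal turn (four matched residues — a single terminal CA is too
sensitive to fraying), decomposed against the bundle axis (principal axis
of all matched CA of the superposed pair, one shared frame for both
states) into radial (positive outward), axial (positive extracellular) and
tangential components. TM6 rotation is the azimuthal change of a marker
residue's side-chain centroid about the helix's own axis, positive
counter-clockwise viewed from the extracellular side; the default marker
is 6.29, the lysine at the TM6 cytoplasmic end in the TSHR.

When one helix moves and the superposition uses all seven helices, the
fit absorbs a fraction of the movement into the global frame; matching on
a static core (`core_selection` of unmoved helices) removes that bias and
is what the recovery analyses use. With the default all-helix core the
planted 5 Angstrom swing reads about 4.7-4.9 — worth knowing, not wrong.

# Mutation annotation

`predict_mutation_effect()` is deliberately heuristic, qualitative and
direction-only: it never predicts a fold change. For each conformation the
mutant residue type is scored against every interaction and near
neighbour in the wild-type profile: the best interaction the mutant could
sustain with that partner is found on the same distance ladder, with
distances adjusted by an idealized side-chain reach table — a longer side
chain may close distance toward a partner (polar gains are judged at the
observed distance, since the partner's arm is still in place), while
hydrophobic replacements pay or gain the full reach difference (this is
what lets an aromatic pair at 2.9 survive substitution to isoleucine while
the same pair at 3.6 does not). Induced-dipole and weak-hydrophobic
contributions count at half weight; weak polar at 0.75. The conformation
with the higher net change is called as stabilized; ties are neutral. The
score is a sum over an unordered set, so the call is deterministic and
order-independent.

Membrane-exposure arguments (for example a mutation shielding a
lipid-facing tyrosine hydroxyl) are outside the rule set — the package has
no membrane model. Such cases can still be expressed as an engineered
profile with the shielded partner as a neighbour, which is how the FSHR
A575V fixture is built, but the package itself never infers membrane
context.

The packaged phenotype tables are stored verbatim from the published
compilations, including their internal inconsistencies (the same BW label
attached to different author numbers in different receptors, one zero
fold-change entry); they are reference data, not curated input, and are
never cross-checked between receptors.

# The synthetic-structure generator

The generator exists so every stage is testable without downloads, since
the receptor homology models themselves are not deposited. It emulates:

* seven straight helices on a circle (radius 10.5 Angstrom, 30 residues,
  alternating topology, z+ = extracellular), each with full backbone and
  one idealized extended rotamer per residue type;
* per-helix BW anchors offset as in real receptors (3.50 near the
  intracellular end, 6.30 at the TM6 cytoplasmic end, and so on);
* plantable features applied in listed order: kinks (rotation of the
  helix past an apex), alpha-bulges (a three-residue torsion edit that
  shifts the hydrogen-bond registry to i+5), contact pairs (residues
  retyped, aimed, and the partner helix translated until the realizing
  distance is exact), spins and rigid motions;
* inactive/active pairs: a 3.0 Angstrom Arg3.50-Asp6.30 lock planted in
  the inactive state, toggle tyrosines aimed apart, and a movement plan of
  per-end radial/axial displacements plus TM6 spin applied as per-helix
  rigid motions in the active state. A rigid body cannot displace one
  helix end axially while holding the other still, so single-end plans
  anchor the transform at the planned end.

Coordinates carry Gaussian jitter (sd 0.05 Angstrom, seeded) applied
before feature realization, so planted quantities stay exact while
detector inputs are never noise-free. Everything is deterministic per
(spec, seed).

What the generator does *not* emulate — side-chain packing, rotamer
diversity, loops, lipids, waters, curvature of real helices, realistic
inter-helix contact networks — bounds what green tests mean: they show the
detectors and classifiers recover known planted structure under mild
noise, not that the pipeline's thresholds are optimal on experimental
coordinates. The crystal-template analysis (`crystal_distance_report()`)
is the real-data check; it needs the six public PDB entries and runs
whenever they are present locally or the archive is reachable.

# Numerical choices and problem sizes

* Alternate locations: highest occupancy wins, ties go to the
  alphabetically first altloc; model 1 only.
* Axis windows default to 7 residues; reach-adjusted distances in the
  mutation scorer are floored at 2.8 Angstrom (van der Waals contact).
* Planted contacts below 2.4 Angstrom are rejected as infeasible.
* Kink threshold 15 degrees; hydrogen-bond registry cutoff 3.5 Angstrom.
* Analyses and tests run on 30-residue helices (210-residue bundles),
  10-20 seeds per recovery study — sizes chosen so each study finishes in
  seconds while leaving the recovery tolerances (kink +-5 degrees,
  contact +-0.3 Angstrom, movement +-0.5 Angstrom, rotation +-2 degrees)
  non-trivial.

# Known limitations

* The crystal-template TM annotations carry standard anchor assignments
  for rhodopsin, the beta2 adrenergic and the M2 muscarinic receptor as
  explicit overrides; the motif-borne anchors are re-derived from each
  structure's own sequence at run time.
* The mutation annotator sees only the contacts and neighbours in the
  profile it is given; folding, expression and trafficking effects are out
  of scope by design.
* State calls rest on two features; a structure with an atypical lock or
  toggle geometry will come back `indeterminate` rather than guessed.
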