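---
title: "Restrained relaxation of design scaffolds: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained relaxation of design scaffolds: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffrelax)
```

## The problem

Crystal structures used as starting points ("scaffolds") for
computational protein design almost always contain a handful of residues
that score very poorly under a design force field: sidechains frozen in
strained rotamers, atom pairs slightly inside contact distance, small
lattice distortions. If such a structure is handed to fixed-backbone
design unmodified, the designer mutates those positions simply to escape
the strain, not because the native identity is a poor choice. If instead
the structure is energy-minimized without any tether, it drifts away
from the experimentally determined coordinates — often by more than an
Angstrom — and subsequent design over-fits the idealized model.

`scaffrelax` implements the middle path: cyclic sidechain repacking and
torsion-space minimization under restraints anchored to the input
coordinates, so that strain is relieved with minimal structural
deviation. The trade-off between the two goals is explored as a Pareto
frontier over restraint schemes and widths, and the consequence that
matters — whether design keeps native identities — is measured as
sequence recovery.

## Structure model

A structure is an ordered list of residues, each carrying the heavy
atoms of its amino-acid template in fixed order (N, CA, C, O, then
sidechain). Hydrogens are dropped at ingestion; all energies and RMSDs
are heavy-atom quantities. Templates provide ideal bond lengths and
angles (from the standard residue definitions) and define the torsional
degrees of freedom: backbone phi/psi and the sidechain chi angles.
Proline is modelled with a rigid ring (no free chi; its ring-closure
bond enters the exclusion graph).

Cartesian coordinates are the source of truth: refinement moves are
rigid rotations of the downstream atom set about actual bond axes, so
coordinates read from a PDB file (or deliberately perturbed by the
fixture generator) keep their internal geometry exactly; templates are
used to *build* fixtures and mutant sidechains, never to overwrite
observed coordinates. This gives torsion-space minimization without a
bonded energy term while preserving the input geometry — the property
the whole protocol is about.

PDB input follows common crystallographic conventions: alternate
locations resolve to the highest-occupancy conformer (ties by altLoc
letter), waters/heteroatoms/non-canonical residues are removed by
`clean_structure()` (non-canonicals with a warning), and only
single-chain files are accepted in this version.

## Energy model

The energy is intentionally small — four terms with closed forms — but
it preserves the two strain channels that dominate the difference
between raw and relaxed crystal structures: atom-pair repulsion and
rotamer strain.

* **rep** — clamped inverse-12 repulsion. For an atom pair at distance
  $d$ with contact distance $\sigma_{ij} = r_i + r_j$:
  $(\sigma/d)^{12} - 1$ for $d < \sigma$, zero outside, linearized below
  $0.6\,\sigma$ so gradients stay bounded inside severe overlaps.
  Per-element radii (C 1.50, N 1.34, O 1.32, S 1.63 Å) are calibrated so
  ideal-geometry secondary structure is exactly strain-free; the binding
  contact is the helix carbonyl-O to next-C′ pair at 2.90 Å.
  The *soft* mode used in the first design cycle shrinks all
  $\sigma_{ij}$ by 0.9.
* **atr** — a shallow 12-6 well of depth $\varepsilon = 0.2$ units with
  its minimum at $\sigma$, flat inside, switched smoothly to zero
  between 4.5 and 6 Å. It provides the packing reward that makes burial
  and pocket-filling meaningful.
* **rot** — rotamer strain: per chi, the squared angular distance to the
  nearest staggered well ($-60/60/180°$) over a width of 20°. For the
  terminal chi of His/Asn/Gln the 180°-flipped wells are equivalent, so
  a chemically indistinguishable amide/imidazole flip costs nothing.
* **cst** — the restraint energy (below), weighted by the ramping
  schedule.

Pairs within three bonds are excluded from rep/atr (computed on the real
bonded graph, including ring closures and the peptide bond). Pairwise
energies are split half/half between the partner residues, so the
per-residue and per-term decompositions each sum exactly to the total.
Energies are in arbitrary units, deliberately not labelled after any
published force field's scale.

## Restraints

Three schemes, all anchored to the cleaned input coordinates:

* **Harmonic coordinate** restraints, $f(d) = (d/\mathrm{sd})^2$, on
  backbone heavy atoms or all heavy atoms. `sd` is the width in
  Angstrom: smaller is stiffer.
* **Bounded coordinate** restraints: zero within `width`, the quadratic
  $((d-\mathrm{width})/\mathrm{sd})^2$ up to $\mathrm{width} +
  0.5\,\mathrm{sd}$ (value 0.25 there), then linear with slope
  $1/\mathrm{sd}$ — continuous with continuous first derivative.
* **Sidechain–sidechain distance** restraints: a harmonic restraint of
  width 2.0 Å on every unordered pair of sidechain heavy atoms in
  distinct residues within a cutoff (swept 3–8 Å), plus harmonic
  coordinate restraints of width 0.5 Å on the backbone.

Coordinate restraints on the flip-equivalent terminal atoms of
His/Asn/Gln score the closer of the two symmetric target assignments,
so a flip is not spuriously penalized.

## The relax protocol

`fast_relax()` runs five cycles; within each cycle the repulsive weight
ramps through 0.02, 0.25, 0.55, 1.0, and each stage repacks sidechains
and then minimizes all torsions. Low-repulsion stages let atoms pass
through mild overlaps; the full-weight final stage enforces the real
energy. Restraints keep weight 1 throughout by default (the restrained
protocol); `ramp_constraints = TRUE` instead fades them (1, 0.7, 0.3, 0)
as the repulsion rises, the convention appropriate when restraints are
experimental rather than coordinate-derived.

* **Repacking** is simulated annealing over residues (temperature ladder
  10, 3, 1, 0.3, 0 units, one pass per residue per temperature,
  Metropolis acceptance, as many proposals per visit as there are
  candidates) followed by greedy sweeps to quiescence, which guarantees
  the protocol never ends on an uphill move. Candidates per residue are
  the input rotamer, all chi-well combinations, the H/N/Q flips, and
  (optionally, `extra_rotamers`) ±10° sub-samples — the latter is off
  by default as it slows packing several-fold without improving RMSD.
* **Minimization** is quasi-Newton (L-BFGS-B) over all phi/psi/chi with
  analytic torsion-space gradients (Cartesian chain rule through the
  rotation axes), projected-gradient tolerance $10^{-4}$ units/degree,
  at most 500 iterations. A descent contract is enforced: if line
  search fails the input state is returned.

All randomness flows from one integer seed; identical seeds give
bit-identical trajectories.

## Metrics and the frontier

RMSD uses single-pass Kabsch superposition (no outlier rejection) over
all heavy atoms (or CA only), matching how relaxed and reference
structures are compared in practice; a flip-aware variant that resolves
H/N/Q terminal ambiguity before measuring is available but off by
default, so reported RMSDs count flips as deviation. Replicate runs
aggregate as the median over replicates per structure, then the
unweighted mean over structures; the median of an even count is the
midpoint of the central pair. A parameter setting is Pareto-dominated
if another setting is at least as good on both axes (mean RMSD, mean
energy per residue) and strictly better on one; ties on both axes are
all retained.

## Design and sequence recovery

Design shells follow the two-radius rule: residues with any heavy atom
within 6 Å of the site may change identity, those within 12 Å may
change rotamer only, the rest are fixed (site residues are fixed,
emulating a bound ligand). Design runs one soft-repulsion cycle then
one standard cycle, annealing over (identity × rotamer) at designable
positions with an optional chi minimization after each cycle; the
backbone never moves. Design uses a cooler annealing ladder (2, 1, 0.5,
0.25, 0) than repacking: identity moves reshape whole sidechains, and a
hot start lets early mutations entrench themselves as the shell adapts
around them.

Because the energy rewards contact, a design objective without a
counterweight would always choose the largest residue. Each identity
therefore pays a reference energy — the standard chemical-potential
device — fitted once by matching designed amino-acid composition to
native composition over relaxed strain-free fixtures, then frozen as
package constants. The reference term is constant under fixed sequence,
so refinement energies never include it.

Sequence recovery is the fraction of designable positions where design
keeps the native identity, reported over independent seeded runs. The
package's absolute recovery numbers are far below published values for
full-scale force fields — a four-term energy cannot encode most
identity preferences — but the *ordering* across pretreatments (no
relax < restrained relax < unrestrained relax) is the behaviour of
interest and is what the tests assert.

## The fixture generator

`fixture_suite()` builds deterministic ideal-geometry mini-proteins
(12–34 residues; helices and strands) with calibrated per-residue
default rotamers such that clean fixtures carry exactly zero repulsive
and rotamer strain. Defects emulate the high-energy residues of crystal
structures:

* `clash_rotamer` — sets a residue's chis to the well combination
  maximizing the repulsive energy;
* `chi_offset` — moves chi1 off-well by a stated angle (rotamer
  strain);
* `coord_noise` — Gaussian displacement of sidechain heavy atoms
  (sub-rotameric distortion that torsion moves cannot fully undo).

Planting must strictly increase the energy, or the generator errors.
Sizes were chosen to keep the full test suite within a small CPU
budget; the generator emulates local strain only — no solvent, ligands,
lattice contacts, missing density, or B-factor effects — so passing
tests demonstrate the protocol's mechanics, not force-field accuracy on
real crystal structures.

The case-study scaffold (`case_study_fixture()`) is a 33-residue
helix-hairpin with a hydrophobic core whose sequence was made
self-consistent with the package's own design procedure (iterated
fixed-backbone design on the relaxed fold) — the analog of a native
protein being near-optimal for its force field. A clashing rotamer
planted on a core glutamate strains the pocket of the studied
isoleucine; the neighbor sits outside the repack shell, so design
cannot repair it. On the raw input every isoleucine rotamer collides
and design substitutes the position; after restrained relax
(sub-0.1 Å average motion) the native is kept. The focused probe uses a
single standard-repulsion design cycle: the soft cycle exists to admit
near-clashing natives in bulk design, which is the opposite of what a
single-position discrimination experiment should do.

## Numerical choices

* Torsion placement and measurement use the standard NeRF construction
  and the textbook signed-dihedral convention (validated against
  real-protein torsion distributions during development).
* Minimizer: L-BFGS-B, `factr = 1e7`, `pgtol = min_tolerance`; with a
  near-zero restraint width (`sd = 1e-6`) restraint curvature reaches
  $10^{12}$ units/Å², which the clamped-gradient energy and bounded
  line search tolerate — the structure simply stays put.
* The repacker re-measures chi angles from coordinates before every
  rotation, so repeated rotations cannot accumulate drift.
* Degenerate inputs error early: empty structures, missing template
  atoms, non-finite coordinates, collinear superposition inputs,
  restraint references to absent atoms.

## Known limitations

* The energy has no solvation, electrostatics, or hydrogen-bond terms;
  absolute energies and recoveries are not comparable to full design
  force fields.
* Single chains only; no ligands or cofactors (point sites stand in
  for ligand-centric design shells).
* Backbone-only restraint runs can drift over 1 Å in all-atom RMSD on
  sidechain-perturbed fixtures — expected, and the reason the all-atom
  scheme is the default.
* Electron-density-derived restraints are out of scope; coordinate
  restraints to the deposited model are the supported proxy.
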