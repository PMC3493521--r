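---
title: "Methods: constrained Abeta42 oligomer assembly and ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained Abeta42 oligomer assembly and ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, numerical choices and design decisions
behind globulomeR, in the spirit of a methods section: what each procedure
assumes, which parameters matter, what the synthetic generator does and does
not emulate, and where the design was genuinely open.

## The modelling problem

Soluble Aβ42 dodecamers are experimentally characterised only indirectly:
roughly spherical particles of 40–60 Å diameter that appear to be dimers of
hexamers; a hydrophobic, H/D-exchange-protected C-terminus and a highly
mobile, exposed N-terminus; little or no regular inter-chain β-sheet; an
F19–L34 sidechain contact within NOE distance; a K28 sidechain amine that is
surface-positioned yet protected from cross-linking; and a charged C-terminal
carboxylate that resists burial. globulomeR encodes this evidence as
*constraints on a hierarchical rigid-body assembly* (dimer → C3 hexamer →
stacked dodecamer) and as an *analysis battery* that scores any model or
ensemble against the same observables.

## Structure model

Structures are flat atom tables plus an `n × 3` coordinate matrix in
Ångström, residues numbered 1–42 in the Aβ convention. PDB parsing and
writing are delegated to bio3d, with package policies layered on top:
alternate locations collapse to the highest-occupancy conformer (ties: first
encountered — a deterministic single-conformer model), elements come from
the element column with atom-name fallback (reliable hydrogen flagging is
required by amide rSASA), insertion codes are rejected (no in-scope
structure needs them), and files with two or more MODEL blocks become
trajectories (frame interval 10 ps by default, matching conventional
conformational sampling intervals). Transforms are validated proper
rotations (orthonormality and det +1 within 1e-9).

## The peptide builder and its frozen geometry

`build_peptide()` grows chains from internal coordinates (NeRF placement)
with ideal backbone geometry: N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
ω = 180°. Sidechains and hydrogens are reconstructed from a per-residue
internal-coordinate table (`inst/extdata/residue_geometry.tsv`) derived once
from ideal amino-acid reference geometry; reconstruction reproduces the
source coordinates to numerical precision, so generated structures have
standard stereochemistry at default rotamers. Backbone amide hydrogens are
placed on the in-plane bisector of N–CA and N–C(i−1) at 1.01 Å; the first
residue and prolines carry none (an N-terminal amine is not an amide). The
final residue carries a free carboxylate (O + OXT), which matters for the
charged-group filter.

Conformations: helix φ = −57°, ψ = −47°; extended φ = ψ = 180°; hairpin =
two β strands (φ = −135°, ψ = 135°) joined by a two-residue turn. The turn
was a genuinely open choice. A canonical type-I′ turn, combined with ideal
(untwisted) strands, produced steric clashes (nonbonded heavy-atom pairs
under 1 Å) and pulled the strands out of register; the shipped turn instead
uses a positive-φ two-residue geometry with adjusted flanking torsions,
frozen in `torsion_schedule()`, that yields a clash-free hairpin whose
strands pair at ≈ 5 Å (Cα 33–41 distance 4.6 Å for the 31–42 segment with
the turn at 37–38). This is a fixture-geometry decision, not a claim about
the true turn type.

The reference tripeptides for rSASA are uncapped flank–x–flank peptides in
fully extended conformation; flank A (AxA) is the default, flank G
selectable per call. Whether the original protocol used AxA or an
asymmetric G-x-A context is not decidable from the available description;
the symmetric convention is used and recorded in each result's
`reference_context`.

## The standard fixtures

`build_core_monomer()` produces the compact Aβ 17–42 monomer used
everywhere: strands 17–23, 30–36 and 39–42 in a three-stranded meander, a
broad central loop over 24–29, and the C-terminal hairpin turn at G37–G38.
The central-loop torsions were tuned once (random search plus local
refinement over the 14 loop torsions) against three construction targets —
no nonbonded heavy-atom pair under 2.8 Å, β-register pairing (Cα pairs
19/34, 21/32, 23/30 near 5 Å), and an F19–L34 minimum sidechain heavy-atom
distance under 6 Å (it is 3.6 Å) — then frozen as package constants. The
F19–L34 target mirrors the proximity constraint used when Aβ oligomer
monomers are modelled from the tetramer crystal form.

`standard_dodecamer_fixture()` assembles this monomer deterministically:
face-flipped sheet-stacking dimer (rise 10 Å, lateral offset 4 Å), C3 ring
of three dimers at ring radius 16 Å with the C-terminal hairpins pointing at
the axis, and a second, flipped hexamer stacked with 2 Å of z-extent
interdigitation and a 40° twist. Each parameter was chosen once, by scanning
for the most compact arrangement with no inter-chain heavy-atom pair below
≈ 2.9 Å while keeping inter-subunit contacts (< 5 Å) at every interface.
The core particle has Rg ≈ 22.5 Å (diameter ≈ 45 Å, inside the
experimental 40–60 Å window). Helical N-termini (residues 1–16) are grafted
at residue 17; the junction torsions (ψ16 = 90°, φ17 = −90°) were likewise
scanned once so all twelve helices radiate outward without steric overlap.
The fixture is deliberately idealised: exact symmetry, ideal geometry, no
sidechain repacking at interfaces.

## The synthetic ensemble

`simulate_trajectory()` adds independent Gaussian noise per atom coordinate
with residue-dependent σ, optionally rebuilding residues 1–16 each frame
with backbone torsions interpolated linearly from helical to extended
(grafted at residue 17). The default study conditions are σ = 0.4 Å for the
core (17–42) and σ = 1.2 Å for the N-terminus, 20 frames at 10 ps — an
ordered core (B = 8π²σ² ≈ 13 Å² at σ = 0.4, under the ~30 Å² threshold for
ordered residues) against a conspicuously mobile N-terminus, the
qualitative mobility profile reported for these systems. Production MD runs
are 2–3.5 ns sampled every 10 ps (200–350 frames); the 20-frame default
keeps the full battery desk-scale, and every statistic accepts longer
trajectories unchanged.

What the generator does **not** emulate: correlated motions, bonded-geometry
preservation under noise, solvent, or any energetics. Two consequences are
worth knowing. First, because noise displaces each atom independently,
covalently bonded hydrogens drift off their heavy atoms at large σ; the
trajectory-averaged SASA of a sterically self-shielded atom such as the K28
sidechain amine therefore *rises* relative to its rigid reference, and its
rSASA can exceed 1 (values are documented as unclamped). Ensemble rSASA
values from this generator are qualitative — useful for orderings
(buried vs exposed, before vs after unwinding), not for matching MD-derived
magnitudes. Second, passing tests on this generator demonstrates the
correctness of the estimators (a closed-form B = 8π²σ² is recovered within
5% at 2000 frames), not the realism of the dynamics.

## Assembly search and filters

`rigid_dock()` is a transparent exhaustive grid search: Euler ZYZ rotations
at `rot_step` (default 30°), Cartesian translations at `trans_step`
(default 1.5 Å) over the bounding shell where the two surfaces can touch,
with the mobile copy rotated about its own centroid. Contacts are
heavy-atom pairs under 5 Å, clashes under 2.5 Å, and the score is
contacts − 10·clashes — a deliberately simple surrogate for
surface-complementarity scoring that preserves the selection logic
(required C-terminal contacts plus steric feasibility) while remaining
verifiable against brute-force enumeration. Ties break by fewer clashes,
then lexicographic grid index, so candidate lists are byte-reproducible.
Candidates lacking the required number of contact pairs with *both*
partners in the C-terminal region (31–42) are discarded, following the
restriction that interfaces involve the respective C-terminal segments.
`symmetrize_c3()` scans 3-fold axes (quasi-uniform hemisphere directions ×
in-plane offsets) and scores one inter-copy interface — the three
interfaces of a C3 arrangement are congruent, so totals are exactly three
times the pair counts — and `stack_to_dodecamer()` scans the C2 flip family
(180° rotations about in-plane axes) crossed with axial translation.

The charged-group occlusion filter rejects a candidate when any charged
atom (LYS NZ, ARG NH1/NH2, ASP OD1/OD2, GLU OE1/OE2, or a C-terminal
OXT/O) falls below 10% relative accessibility in the complex while being at
or above it in the isolated subunit — i.e. the interface, not the fold,
buried it. Terminal carboxylate atoms are referenced against the C-terminal
position of the reference tripeptide rather than its central residue. In
the pipeline the filter is applied lazily in rank order (evaluation stops
once the requested number of models has passed), since greedy
maximum-contact placements frequently bury a carboxylate and are exactly
the artefactual solutions the filter exists to remove.

The pipeline's default grid (rot_step 90°, trans_step 3 Å, top 30 dimer
candidates, up to 4 accepted dodecamers) is the desk-scale configuration
used by the tests and the acceptance script; finer grids change runtime,
not code paths. No post-docking refinement is performed — candidates are
emitted rigid.

## Surface, contacts, packing

SASA uses Shrake–Rupley sphere sampling with a deterministic Fibonacci
sphere (960 points by default; an isolated sphere is reproduced essentially
exactly, and a two-sphere system is within 1% of the closed-form
spherical-cap value), probe 1.4 Å, Bondi radii with H = 1.20 Å (recorded in
every result for auditability); hydrogens are ordinary atoms with their own
radius. rSASA divides an atom's (frame-averaged) SASA by the same atom's
SASA in the reference tripeptide — averaging SASA over frames *before*
dividing, the reading most consistent with reporting average amide-proton
accessibility relative to a tripeptide. Protection uses a strict rSASA
< 10% threshold. Protection orderings on a helical fixture deserve care: a
geometrically ideal helix hydrogen-bonds (and thus occludes) its own amide
protons, so the *static* fixture over-protects the N-terminus — consistent
with the observation that much of an initial model's protection stems from
helical amide bonding and should decline as helices unwind. The pipeline
therefore reports *ensemble-averaged* protection over the unwinding
trajectory, where the C-terminal core (≈ 0.66) cleanly exceeds the
N-terminus (≈ 0.07), and start-window vs end-window protection shows the
decline.

Atomic contact energies sum a symmetric per-type pair energy over heavy-atom
pairs within 6 Å, crediting each pair to both residues (so the grand total
is twice the unordered-pair sum, and per-residue bars are self-contained).
Pairs within the same or sequence-adjacent residues of one chain are
excluded (exclusion = 1) to avoid covalent-neighbour bias; cross-chain pairs
always count. The shipped table is an 18-type **synthetic**
parameterization — backbone, aliphatic, aromatic, polar-adjacent and sp2
polar carbons, amide/charged/ring nitrogens, carbonyl/carboxylate/hydroxyl
oxygens, sulfur, with e(i,j) = (d_i + d_j)/2 from per-type desolvation
propensities — constructed so that hydrophobic contacts are negative
(hydrophobic stabilisation) and polar desolvation positive. It follows the
structure of published quasi-chemical ACE tables but its numbers are this
package's own; all machinery accepts any table in the same format, and the
correctness tests (brute-force pair enumeration) are independent of the
values.

Packing density marks an atom buried when its SASA at probe 1.4 Å is
exactly zero, then Monte-Carlo samples the atom's cell — points whose
surface distance (|x − c| − r) to the atom does not exceed that to any
neighbour, a power-diagram-like partition — inside a sampling sphere of
radius r + 2·probe + 0.2 Å (sufficient for buried atoms, whose cells are
closed off within probe reach in every direction). Density is the occupied
fraction of cell points; overlap regions are thereby assigned to the
nearest-surface atom. The estimator is verified against a dense-grid
integration oracle (within 0.02 on an FCC cluster) and is stable to ±0.01
when the sample count doubles. On the idealised dodecamer fixture the
buried-core mean is ≈ 0.74–0.75, at the lower edge of the 0.7–0.8 range
expected for well-packed protein cores — unsurprising for rigid
ideal-geometry chains without sidechain repacking. The ≈ 0.8 benchmark
against the Aβ(17–42) tetramer crystal structure requires the PDB entry
3MOQ, which is not redistributed; the corresponding acceptance test states
where to place it and fails (honestly) in its absence.

## Ensemble statistics

Kabsch superposition (SVD with a proper-rotation correction) underlies all
RMSD work; degenerate (collinear) point sets are rejected. For RMSD series
the fit selection equals the report selection (core Cα 17–42 for the core
series, all Cα for the total) — the fitting selection is not stated in the
protocols this package follows, so it is exposed as an argument with this
default. Rg is mass-weighted over heavy atoms (fixture hydrogen placement
is idealised, so hydrogens are excluded). B-factors average atom → residue
(mainchain) → chain position, over a trailing window (default last 100 ps,
the "late window" convention); the two-pass variance makes static input
exactly zero. The sidechain distance monitor is the per-frame minimum over
heavy sidechain-atom pairs — both the 6 Å construction constraint and the
7.5 Å NOE tolerance refer to sidechain proximity without naming atoms, so
the minimum-pair convention is adopted (and a mean of per-frame minima is
reported, flagged as an interpretation). Convergence diagnostics (cv =
sd/|mean|, OLS slope per ns) apply to any scalar series; with no force
field in scope the pipeline applies them to the core Rg series.

## Problem sizes and determinism

Default study sizes: 12 chains × 42 residues ≈ 7,600 atoms with hydrogens;
20-frame ensembles; 960-point SASA spheres; 2,000 Monte-Carlo samples per
buried atom; docking grids of order 10^5–10^6 placements. These were chosen
as the package's standard desk-scale configuration; every size is a
configuration field. All stochastic stages consume one seed
(`run_config(seed = )`), assembly is seed-free and fully deterministic, and
repeated runs are byte-identical.

## Known limitations

- The generator's independent per-atom noise breaks bonded geometry at
  large σ (see the K28 note above); orderings are meaningful, magnitudes of
  hydrogen-adjacent accessibilities are not.
- Built models are rigid-body assemblies without refinement; interfaces are
  not repacked, so absolute contact counts and packing densities at
  interfaces are conservative.
- The ACE table is synthetic; per-residue ACE signs and orderings are
  meaningful under its construction, absolute kcal/mol values are not
  literature-comparable.
- The manual curation present in interactive modelling protocols
  ("reasonable interactions", visual elimination of steric overlap) is
  replaced by the documented automatic filters; the two need not select
  identical models.
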