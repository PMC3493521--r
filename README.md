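# globulomeR

Constrained assembly and ensemble analysis of amyloid-β (Aβ42) oligomer
models in R.

Soluble Aβ42 dodecamers ("globulomers") are leading candidates for the
neurotoxic species in Alzheimer's disease, but no experimental structure
exists. A productive modelling strategy builds candidate dodecamers as a
*dimer of C3-symmetric hexamers*: compact monomers with a single C-terminal
β-hairpin (turn near G37–G38) are docked into dimers under the constraint
that interfaces involve the hydrophobic C-terminal segment (residues 31–42),
dimers are symmetrized into hexamers, hexamers are stacked into dodecamers,
and candidates that bury charged sidechains at an interface are discarded.
The resulting models are then judged by ensemble statistics against
experimental observables: particle size (radius of gyration, Rg),
hydrogen/deuterium-exchange protection of backbone amides, chemical
reactivity of the K28 sidechain amine, NOE-style sidechain proximities
(F19–L34 < 7.5 Å), hydrophobic burial (atomic contact energies), and core
packing density.

globulomeR implements that entire workflow for structural bioinformaticians
who want a reproducible, scriptable version of it:

- **Structure model** — a chain→residue→atom container with PDB input/output
  (multi-model PDB as the trajectory format), region/atom-class selections
  (N-terminus 1–17, central 18–30, C-terminus 31–42, core 17–42) and
  validated rigid transforms.
- **Synthetic generator** — an ideal-geometry peptide builder (helix,
  extended, β-hairpin; full heavy-atom sidechains and hydrogens), extended
  reference tripeptides (AxA/GxA-style), Cn-symmetric ring assemblies, a
  deterministic dodecamer fixture, and Gaussian-fluctuation trajectories
  with progressive N-terminal helix unwinding — so every analysis can be
  exercised without any external data.
- **Assembly** — exhaustive-grid rigid-body docking with a transparent score
  (contacts − 10·clashes), C3 symmetrization, hexamer stacking, and the
  charged-group occlusion filter (rSASA of LYS/ARG/ASP/GLU groups and
  C-terminal carboxylates).
- **Surface** — Shrake–Rupley SASA (Rcpp core), rSASA against extended
  reference tripeptides, amide protection fractions (rSASA < 10%), and
  interface buried surface area.
- **Contacts** — per-residue atomic contact (desolvation) energies within a
  6 Å cutoff, and Monte-Carlo packing density of buried atoms.
- **Ensemble** — Kabsch superposition, core/total RMSD series, Rg, B-factor
  profiles (B = 8π²⟨Δr²⟩/3), minimum sidechain-distance monitors, and
  coefficient-of-variation / slope convergence diagnostics.
- **Pipeline** — `run_build()`, `run_analyze()`, `run_full()` plus a thin
  command-line driver (`exec/globulomer`) with `fixture`, `build`,
  `analyze` and `full` subcommands, driven by a YAML run configuration.

The shipped atomic contact energy parameter table
(`inst/extdata/ace_table_synthetic18.tsv`) is a *synthetic* 18-type
parameterization (hydrophobic–hydrophobic contacts negative, polar contacts
positive); any table in the same documented format can be substituted.

## Worked example

```r
library(globulomeR)

cfg <- run_config(seed = 1)
res <- run_full(cfg)          # build models, simulate, analyze (~2 min)
print(res$report)
```

Output from this run:

```
<run_report>
  Rg (1-42) 23.9 A | Rg (17-42) 16.6 A
  RMSD core 0.69 A | total 11.32 A
  K28 NZ rSASA 2.42 | F19-L34 3.7 A (100% < 7.5 A)
  protection N 0.26 / central 0.60 / C 0.88 / total 0.55
  packing density 0.83 (1526 buried atoms)
```

Reading the numbers: the flexible, unwinding N-terminus inflates the total
RMSD (11.3 Å) while the constrained C-terminal core barely moves (0.69 Å);
the best-scoring built dodecamer is a compact particle (core Rg 16.6 Å,
total Rg 23.9 Å with the helical N-termini). Ensemble-averaged amide
protection rises from the exposed N-terminus (0.26) through the central
region to the buried C-terminal core (0.88), the F19–L34 sidechain contact
stays inside the 7.5 Å NOE tolerance in every frame, and the buried core
packs at 0.83 occupancy. The K28 sidechain amine stays solvent-accessible
(rSASA ≫ 10%); values above 1 arise because the generator's independent
per-atom noise displaces the bonded hydrogens that shield NZ in the rigid
reference tripeptide (see the methods vignette).

The same run from a shell:

```sh
Rscript exec/globulomer full --seed 1 --out runs/demo
```

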