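---
title: "Growing R-groups in a rigid pocket: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing R-groups in a rigid pocket: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lead optimisation in structure-based drug design usually proceeds through a
*congeneric series*: a fixed scaffold (the core), observed crystallographically
in the binding site, decorated with different substituents (R-groups). The
quantity of interest — the relative binding free energy between two members of
the series — can be computed by alchemical methods, but those calculations
need a sensible bound conformation of each new analogue as input. `growkit`
produces those conformations. It keeps the core exactly where the crystal
structure puts it, grows a chosen R-group from a marked hydrogen, enumerates
conformers of the grown region, refines them against a rigid receptor under a
hybrid mechanical-embedding potential, filters and scores the results, and
writes structures and atom maps ready for free-energy setup.

The deliberate restriction to a *rigid* receptor and a *restrained* core is
what makes the approach fast and robust: the search space is only the torsional
space of the new substituent, and the output pose is guaranteed to be
consistent with the experimentally observed binding mode.

## The energy model

The refinement energy is a three-term mechanical embedding:

$$E^{\mathrm{tot}} = E^{\mathrm{MM}}(R) + E^{\mathrm{MM}}(RL) + E(L)$$

* $E^{\mathrm{MM}}(R)$ — receptor internal energy. The receptor never moves,
  so this term is a constant, computed once.
* $E^{\mathrm{MM}}(RL)$ — the receptor–ligand coupling: pairwise Coulomb plus
  Lennard-Jones 12-6 over every receptor–ligand atom pair, with two scaling
  rules applied (below).
* $E(L)$ — the ligand intramolecular term. This slot is pluggable: the
  built-in molecular-mechanics backend, or any user-supplied callable
  `function(xyz) -> kcal/mol` (an ML potential, for instance). `backend_select()`
  implements the element gate: the ML slot is only used when every element of
  the ligand is in {H, C, N, O, F, S, Cl}; otherwise the classical backend is
  chosen and a warning names the offending elements.

Because the partition is strict, filling the "ML" slot with the same MM force
field must reproduce the plain single-point energy of the whole complex; the
test suite asserts this closure to $10^{-6}$ kcal/mol, and it is the right
first check for any user-supplied backend.

### The two scaling rules

The rigid-receptor approximation leaves no room for induced fit, and stripping
solvent removes dielectric screening. Both are compensated *implicitly* during
optimisation:

* **Lennard-Jones softening.** Each coupling pair's minimum-energy distance is
  multiplied by `lj_scale` (default **0.8**); well depths are unchanged. This
  is implemented by scaling the combined size parameter, so the law
  $\arg\min E_{LJ} = 0.8 \, r_{\min}$ holds exactly for every pair.
* **Dielectric screening.** All atomic charges entering the coupling term —
  on both partners — are multiplied by $1/\sqrt{\epsilon}$ with $\epsilon = 4$
  by default, so every pairwise Coulomb energy scales by $1/\epsilon$. Ligand
  intramolecular electrostatics are *not* scaled. Whether the original
  formulation scales receptor charges as well as ligand charges is ambiguous;
  scaling both is the reading implemented here, and it is what makes the
  $1/\epsilon$ net law exact.

Ranking uses the same scaled potential that was used for optimisation, so the
energies that drive selection are self-consistent.

## Workflow stages and the parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `restraint_k` | $10^4$ | kcal/mol/Å² | harmonic positional restraints on core heavy atoms |
| `clash_cutoff` | 1.0 | Å | strict `<` receptor–ligand contact rejection |
| `lj_scale` | 0.8 | — | coupling LJ minimum-distance scaling |
| `dielectric` | 4 | — | $\epsilon$; coupling charges scaled by $1/\sqrt{\epsilon}$ |
| `window` | 5.0 | kcal/mol | energy window for pose selection (boundary inclusive) |
| `n_conformers` | 6 | — | torsion-sampled starting geometries per ligand |
| `dedup_rmsd` | 0.5 | Å | near-duplicate removal on R-group heavy-atom RMSD |

**Growth.** `load_core()` validates the attachment hydrogen (growth is only
supported from hydrogens), `attach_rgroup()` deletes it together with one
hydrogen on the R-group's linking atom, forms the new single bond at the sum
of covalent radii along the former C–H vector, and copies the template
coordinates unchanged onto the core. Atom bookkeeping (the `core_map`, the
grown-atom set, additivity of formal charge, atom-count conservation) is
asserted by the test suite.

**Conformer enumeration.** Starting geometries come from seeded uniform
sampling of the torsions of rotatable bonds whose rotation moves only
flexible or grown atoms; the first conformer always keeps the build geometry.
This is a deliberate design choice over distance-geometry embedding: with the
core fixed, the only degrees of freedom worth sampling *are* those torsions,
torsion driving cannot disturb the restrained substructure, and it is exactly
reproducible under a seed. Each start is minimised in vacuum under the
intramolecular force field plus the core restraints, then near-duplicates are
removed (duplicates are detected *after* minimisation, when basins have
collapsed). With $k = 10^4$ kcal/mol/Å² the analytic displacement of a
restrained atom under residual forces of a few kcal/mol/Å is below
$10^{-3}$ Å; the measured worst-case core RMSD across the bundled library is
of that order.

**Core flexibility.** `extend_flexible()` moves named core atoms into the
unrestrained set — the mechanism used, for example, to let a linking
methylene rotate freely when a substituent needs to reorient.

**Pocket refinement.** Conformers that survive the strict 1 Å clash filter
are locally minimised with the receptor fixed and (by default) the core
restrained. Energies stored on the ensemble are the *unrestrained*
$E^{\mathrm{tot}}$ at the minimised geometry. The lowest-energy conformer and
all conformers within the 5 kcal/mol window are selected, sorted by energy
with ties broken by conformer index.

**Measurement.** `rgroup_rmsd()` computes R-group heavy-atom RMSD with *no*
superposition (the shared core already defines the frame), optionally
minimised over topological automorphisms that fix the non-R-group atoms — a
para-substituted phenyl flipped by 180° then measures 0. `dihedral()` returns
the signed torsion in $(-180, 180]$.

## The built-in molecular-mechanics backend

No general force-field engine is available as an R package, so `growkit`
implements a compact one designed for this workflow's needs (local relaxation
of a grown substituent around a fixed core, never global conformational
search):

* **Bonds and angles**: harmonic, anchored at the *reference geometry* — the
  merged build geometry whose fragment internals come from curated 3D
  structures ($k_b = 600$ kcal/mol/Å², $k_\theta = 80$ kcal/mol/rad²).
* **Torsional anchors**: $k_\phi (1 - \cos(\phi - \phi_0))$ terms on ring
  bonds and multiple bonds only ($k_\phi = 15$ kcal/mol), keeping rigid units
  rigid while acyclic single bonds rotate freely.
* **Nonbonded**: UFF van der Waals parameters (geometric combination) and
  Gasteiger partial charges for pairs three or more bonds apart; 1-4 pairs
  scaled by 0.5.

Analytic gradients for every term are verified against finite differences in
the test suite. The receptor–ligand coupling uses the same functional forms
with the scaling rules applied.

**Minimisation.** L-BFGS-B over the ligand coordinates only (the receptor is
rigid by construction, not by constraint forces). The stiff restraints make
the Hessian badly conditioned, so restrained systems are minimised in two
stages: restrained atoms frozen first, then a short all-atom polish; the
better of the two results is kept and energy never increases. The
projected-gradient tolerance is $10^{-3}$ kcal/mol/Å — tighter than typical
engine defaults, because van der Waals wells of depth ~0.1 kcal/mol are
otherwise left ~0.02 Å short of their minimum, visible against the analytic
LJ-scaling law. All interactions are computed in open boundary with no
cutoff: systems are single fixed complexes and small.

## Receptor handling

`load_receptor()` keeps the 20 standard amino acids plus common protonation
variants; waters and other heteroatoms are stripped unless named in
`keep_residues` (e.g. `"HOH 305"` to retain a bridging water as part of the
rigid receptor). Alternate locations other than "A" are dropped.
`fix_receptor()` reconstructs missing backbone carbonyl oxygens from local
N/CA/C geometry and adds hydrogens at pH 7 through Open Babel's protonation
model; original heavy-atom records are kept verbatim, and perceived
protonation-state formal charges are adopted. `parameterise_receptor()`
assigns Gasteiger partial charges (normalised so the total is the nearest
integer) and element-keyed UFF Lennard-Jones parameters.

This is an electronegativity-equalisation charge model, not a protein force
field: per-atom charges differ from curated biomolecular parameter sets, and
per-residue sums are only integral for isolated residues. For the package's
purpose — a *scaled, screened* coupling term in a pose-ranking potential —
this resolution is appropriate, but receptor energetics should not be
over-interpreted. Loop rebuilding and hydrogen-bond-network optimisation are
out of scope.

## Property filters and scoring

`ro5_report()` uses Lipinski's original N/O counting (HBD = O–H + N–H bonds,
HBA = N + O atoms), average molecular weight, and an atom-contribution logP.
`sa_score()` is an Ertl-style synthetic accessibility score: mean
log-frequency of each heavy atom's radius-2 circular environment in a bundled
frequency snapshot, minus penalties for size, stereo centres, macrocycles and
fused/spiro ring atoms, mapped to [1, 10]. The bundled table is a snapshot
built from ~150 common drug-like molecules (`tools/make_sa_table.R`), so
scores are approximate and the table file is swappable; the score's value is
in *ranking* grown analogues, not in absolute calibration. The PAINS / NIH /
unwanted-substructure catalogs are pinned plain-text SMARTS snapshots with
provenance headers; matching is exact substructure search, so the monotone
property (a supermolecule of a flagged molecule is flagged) holds by
construction.

`score_poses()` wraps an external CNN scorer behind a score-only contract
(`<exe> -r receptor.pdb -l poses.sdf --score_only`), parses per-pose score
and predicted-pK fields from stdout, and never moves a pose. A missing scorer
degrades to unscored records with a warning, so the pipeline completes
without it; a deterministic mock scorer ships with the package for tests.
Predicted pK converts to a free energy by $\Delta G = -RT\ln(10)\,\mathrm{p}K$
at 298.15 K.

## Synthetic fixtures, and what passing tests do not show

`make_toy_pocket()` builds a deterministic shell of ~60 parameterised C/N/O
atoms (minimum separation 2.8 Å, net charge zero) around an empty cavity —
enough geometry to exercise clash filtering, coupling energetics, restrained
refinement and selection at desk scale. It is *not* a protein: no secondary
structure, no directional hydrogen bonding, no buried polar network. Tests
passing on toy pockets demonstrate the machinery (term partition, scaling
laws, restraint fidelity, determinism, file contracts), not predictive
accuracy on real binding sites, which additionally depends on the quality of
the ligand force field or ML backend and of receptor charges. The bundled
R-group library (~25 fragments as frozen 3D SDF files with a TSV index)
stands in for the large curated medicinal-chemistry libraries and includes a
bromo fragment specifically to exercise the ML element-gate fallback.

Problem sizes used by the test suite and the acceptance script: 27-member
library grown on a benzene core, 4–6 conformers per ligand, a 60-atom pocket;
an end-to-end run at these sizes takes on the order of a minute on one CPU.

## Numerical and design choices

* Atom indices are 1-based throughout the API, following R convention; file
  writers use each format's native numbering.
* Open Babel's 3D builder is stochastic, so bundled fragments are shipped as
  frozen SDF text; given fixed inputs, the pipeline itself is exactly
  deterministic (seeded torsion sampling, deterministic minimiser), and a
  rerun with the same seed produces byte-identical SDF output.
* Core hydrogens are not restrained (heavy atoms only): hydrogen placement
  differs between tools while the pose comparisons that matter are heavy-atom.
* The maximum common substructure is the maximum clique of the modular
  product graph (elements must match, ring atoms map to ring atoms, bond
  classes match with aromatic ring bonds pooled so Kekulé alternation is
  invisible). Ties are broken by lowest index sum, then by lexicographically
  smallest target sequence, so self-comparison returns the identity map.
* Clash filtering considers *all* atoms including hydrogens and uses strict
  `<` at the cutoff; the selection window is inclusive at its boundary.
* Duplicate conformers are removed after vacuum minimisation, keeping the
  lower-energy representative of each near-duplicate pair.

## Known limitations

* The built-in MM backend anchors bonds and angles at the build geometry; it
  relaxes and ranks substituent conformations but is not a transferable
  force field, and its absolute energies are not comparable across molecules.
* Receptor charges are Gasteiger, not a biomolecular force field.
* Growth is only from hydrogen positions; linker replacement and scaffold
  hopping are out of scope, as is running the alchemical free-energy
  calculations themselves — the package prepares their inputs.
* The stereochemistry of grown fragments is whatever the fragment geometry
  encodes; no stereo enumeration is performed.
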