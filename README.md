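# growkit

Structure-guided R-group growth for congeneric ligand series, in R.

Given a receptor structure, a ligand core in its crystallographic pose, and a
library of substituents, `growkit` builds each analogue by replacing a marked
core hydrogen, enumerates conformers of the grown region while the core is
held in place, refines them against the rigid receptor, filters and scores
the designs, and writes poses, property tables and maximum-common-substructure
atom maps ready for relative binding free energy (FEP) setup. It is aimed at
computational chemists preparing congeneric series for alchemical free-energy
calculations, where each new analogue needs a bound conformation consistent
with the observed binding mode.

## The model

Conformers are relaxed under a hybrid *mechanical embedding* potential

```
E_tot = E_MM(R) + E_MM(RL) + E(L)
```

where the receptor term `E_MM(R)` is constant (all receptor atoms fixed), the
coupling term `E_MM(RL)` is pairwise Coulomb + Lennard-Jones 12-6, and the
ligand intramolecular term `E(L)` comes from the built-in MM backend or any
pluggable callable (an ML potential, gated on its supported elements
H/C/N/O/F/S/Cl, with automatic fallback to MM). Two scalings compensate the
rigid-receptor, no-solvent approximations during optimisation:

* Lennard-Jones minimum-energy distances of receptor–ligand pairs are scaled
  by **0.8**, making room for growth in a rigid pocket;
* all charges entering the coupling term are scaled by **1/√ε** with ε = 4,
  so pairwise Coulomb energies are screened by 1/ε.

Core heavy atoms are held at the template coordinates by stiff harmonic
restraints (k = 10⁴ kcal/mol/Å²). Conformers closer than 1 Å to any receptor
atom are discarded; after refinement the lowest-energy pose and everything
within 5 kcal/mol of it are selected.

## Worked example

Grow a propoxy group on a benzene core inside a synthetic toy pocket (no
downloads needed — the core, the ~25-member R-group library and the pocket
generator ship with the package):

```r
library(growkit)

pocket <- make_toy_pocket(seed = 1)
core   <- load_core(growkit_example("core_benzene.sdf"), attachment_h = 7)
lib    <- toy_rgroup_library()

lig <- attach_rgroup(core, lib$propoxy)
lig
#> <gk_ligand> benzene_propoxy (C9H12O): 22 atoms, 11 grown, ensemble: none

lig <- enumerate_conformers(lig, embed_config(n_conformers = 6, seed = 42))
pot <- build_hybrid_potential(lig, pocket$receptor)
pot
#> <gk_potential> backend=mm, lj_scale=0.80, epsilon=4.0, E_MM(R)=0.1117

ens <- clash_filter(lig$ensemble, pocket$receptor)
ens <- minimise_in_pocket(ens, pot)
ens <- select_low_energy(ens)        # 5 kcal/mol window
round(ens$energy[attr(ens, "selection")] - min(ens$energy), 2)
#> [1] 0.00 0.53 0.60 0.86 1.63 2.05
```

All six torsion-sampled conformers survive the clash filter here and land
within 2.1 kcal/mol of the best pose, so all are selected for output. The
drug-likeness report and (mock-)CNN rescoring:

```r
ro5_report(lig)
#>       mw clogp hbd hba ro5_violations ro5_compliant
#> 1 136.19  2.48   0   1              0          TRUE

lig$ensemble <- ens
score_poses(lig, pocket$receptor)[1:2, ]   # bundled mock scorer
#>   pose cnn_pose_score cnn_affinity   dg_pred
#> 1    2         0.7198       6.6935 -9.131587
#> 2    5         0.7237       6.8303 -9.318216
```

`cnn_affinity` is a predicted pK; `dg_pred = -RT ln(10) · pK` converts it to
kcal/mol. With a real scorer installed, pass
`scorer_spec("gnina")` instead of the mock.

The whole batch — every library member grown, refined, filtered, reported
and written to disk (per-ligand pose SDFs, complex PDBs, `properties.csv`,
`scores.csv`, and a machine-readable `run_log.json`) — is one call:

```r
res <- run_grow(workflow_config(
  receptor = pocket$receptor, core = core, rgroups = lib,
  n_conformers = 6, seed = 42, scorer = "mock", out = "growkit_out"))

# FEP preparation for one perturbation edge:
write_fep_inputs(res$ligands$methyl, res$ligands$ethyl,
                 pocket$receptor, "growkit_out/fep")
```

A thin command-line front end with the same surface lives at
`inst/scripts/growkit` (`grow`, `props`, `score`, `fixtures` subcommands).

## Scope

`growkit` prepares structures; it does not run alchemical simulations,
re-train or ship a CNN scorer (the scorer is an external, optional binary
behind a documented contract), rebuild missing loops, or grow from
non-hydrogen positions.
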