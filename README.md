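# memscan

Trajectory analysis for peripheral membrane proteins and their lipophilic
substrates, built around the workflow used to study carotenoid cleavage
dioxygenases (CCD4-type enzymes): globular Fe²⁺ enzymes whose two
amphipathic helices dip into one leaflet of a membrane to extract
carotenoids into a hydrophobic tunnel leading to the active site.

`memscan` is for structural bioinformaticians who already have (or can
synthesize) coordinates and trajectories and want the downstream numbers:
how deep does the protein sit in the bilayer, what does the membrane do to
its flexibility, how strongly does each substrate bind, and which double
bond of the bound carotenoid sits closest to the catalytic iron.

## What it computes

**Membrane penetration geometry.** The phosphates are split into two
leaflet sets: MP2 on the side the protein inserts into, MP1 opposite.
Per frame *t*,

    Thickness_t = <Z_MP1> - <Z_MP2>
    Depth_t     = max(Z_prot, heavy atoms) - <Z_MP2>
    RPD_t       = 100 * Depth_t / Thickness_t

**Fluctuation contrast.** Per-residue RMSF after Kabsch superposition onto
an iteratively refined mean structure, and the membrane-minus-solvent
contrast ΔRMSF_i = ⟨RMSF_i⟩_memb − ⟨RMSF_i⟩_sol (negative values mean the
membrane rigidifies the residue).

**Interaction-energy partition.** U_ab = U − U_a − U_b over nonbonded
terms — a 12-6 Lennard-Jones potential (ε_ab = √(ε_a ε_b),
R_min,ab = R_min,a + R_min,b) plus Coulomb (k_e = 1389.35 kJ mol⁻¹ Å e⁻²) —
split into ELECT and VDW components with trajectory mean ± SD.

**MM/PBSA binding free energy.**

    ΔG_binding = <ΔMM_gas + ΔG_polar + ΔG_nonpolar - TΔS>,   TΔS = 0 by policy

with ΔG_polar from an in-package finite-difference linearized
Poisson–Boltzmann solver (validated against the Born ion closed form) and
ΔG_nonpolar = γ·SASA + b from deterministic Shrake–Rupley surface areas.

**Interface contacts.** Buried protein–membrane contact surface area,
geometric hydrogen-bond series (3.5 Å / 150° defaults), contacting-residue
lists.

**Active-site geometry.** Distances from the labeled carotenoid carbons
C7, C8, C9, C10, C15, C15′ to the Fe²⁺ ion, assignment of the putative
cleavage site to the nearest double bond (C15=C15′ → symmetric cleavage,
otherwise asymmetric), and substrate ranking by binding energy.

**Implicit-slab insertion.** A rigid-body optimizer that minimizes an
ASA-weighted transfer free energy over depth, tilt and azimuth against a
hydrophobic slab (0.2 Å depth steps), reporting the optimal pose, the
inclination of the first principal axis, and the residues in contact with
the slab.

A synthetic-system generator (`make_bilayer`, `make_protein_and_ligand`,
`make_trajectory`) produces coarse bead models with exact ground truth
(39 Å phosphate-to-phosphate bilayers, prescribed per-residue fluctuation
amplitudes, fixed carbon–Fe offsets), so the entire pipeline is testable
without a simulation engine. Published reference tables for the CCD4
systems (insertion geometry, energy partitions, active-site distances)
ship with the package and power literature consistency checks.

## Worked example

```r
library(memscan)

bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 36,
                                phosphate_separation = 39,
                                jitter_sigma = 0.5, seed = 1))
pr <- make_protein_and_ligand(n_residues = 40,
                              helix_spans = list(c(10, 18), c(25, 33)),
                              seed = 1)
cx <- insert_into_bilayer(pr, bl, penetration = 10)
nres <- length(unique(paste(cx$atoms$chain, cx$atoms$resid)))
tr <- make_trajectory(cx, fluctuation_spec(rep(0.3, nres), 50, seed = 2))

penetration_series(tr, "name P", "group protein")
#> Membrane penetration over 50 frames:
#>   thickness 38.96 (+/- 0.08) A
#>   depth     10.15 (+/- 0.21) A
#>   RPD       26.06 (+/- 0.55) %

energy_series(tr, "group protein", "group ligand", stride = 5)
#> Interaction energy over 10 frames (kJ/mol):
#>   ELECT     -0.23 (+/- 0.28)
#>   VDW       -1.09 (+/- 0.09)
#>   TOTAL     -1.32 (+/- 0.28)

d <- carbon_fe_distances(tr, "group ligand", "group fe")
d
#> Carbon-Fe distances (A): C7=7.26  C8=6.77  C9=6.69  C10=6.61  C15=9.29  C15'=10.16
assign_cleavage_site(d)
#> Cleavage call: C9=C10 (asymmetric) - scores: C7=C8 7.02, C9=C10 6.65, C15=C15' 9.72
```

The bilayer was built 39 Å thick and the protein placed 10 Å into one
leaflet, and the per-frame geometry recovers both (the ±SD reflects the
0.3–0.5 Å jitter prescribed for the fixture). The ligand's C9=C10 bond was
constructed nearest the iron, and the cleavage-site call reads that back
as an asymmetric cut — the same logic that, applied to the published
distance tables, classifies each enzyme–carotenoid complex.

A YAML-driven end-to-end run (`run_analysis`) and a thin CLI
(`exec/memscan` with subcommands `synth`, `run`, `membrane`, `site`,
`ref-check`) wrap the same functions; every run writes per-stage TSVs, a
JSON summary and its resolved configuration for provenance.

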