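---
title: "Methods: membrane penetration, energetics and active-site geometry in memscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane penetration, energetics and active-site geometry in memscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscan)
```

`memscan` packages the post-processing stack for molecular-dynamics studies
of peripheral membrane enzymes — concretely, carotenoid cleavage
dioxygenases whose amphipathic helices penetrate one leaflet of a
thylakoid-like bilayer while a carotenoid substrate sits in a tunnel ending
at a catalytic Fe²⁺. This vignette records the models the package
implements, the defaults it chooses where the underlying methodology is
conventionally under-specified, and what its synthetic test systems do and
do not establish about real data.

## Data model and units

Coordinates are Angstrom, energies kJ/mol, charges elementary units, times
ps. A `MolecularSystem` is an ordered atom table (name, residue, chain,
element, coordinates, optional charge and Lennard-Jones parameters) plus
named index groups; a `Trajectory` adds an `n_atoms x 3 x n_frames` array
with strictly increasing frame times. Residue numbering is preserved as
read; nothing is renumbered.

Lennard-Jones parameters are stored per atom as `rmin` — the *half*
minimum-distance contribution, so the pair minimum is `rmin_a + rmin_b` —
and `epsilon >= 0` in kJ/mol. This matches the CHARMM convention of listing
Rmin/2, and it is why a PQR radius column maps directly onto `rmin`. The
prime in C15′ is not representable in PDB atom-name columns, so the atom is
named `C15P` in files; display methods print it as C15′.

PDB, PQR and DCD reading go through bio3d; the multi-MODEL PDB and
CHARMM-dialect DCD writers are implemented in-package (bio3d has no
writers for those) and are round-trip tested against the bio3d readers.
Elements missing from a PDB are inferred from atom names, with exact
matches for metals first; genuinely ambiguous names raise an error rather
than guessing.

## Membrane penetration geometry

Phosphate atoms are split by the sign of their Z coordinate about the joint
phosphate mean into two leaflet sets. MP2 is the leaflet whose mean Z lies
nearer the protein's center of geometry — the side the protein inserts
into — and MP1 is the opposite leaflet. The assignment is recomputed every
frame: lipids can in principle flip between leaflets, and recomputation is
the safer contract at negligible cost. Frames are canonicalized so that
mean Z(MP1) > mean Z(MP2); when the protein sits above the membrane the
whole frame's Z is negated, which makes every downstream quantity invariant
under a Z-mirror.

Per frame, thickness is the difference of leaflet mean phosphate Z values;
depth is the maximum protein Z over *heavy* atoms minus the MP2 mean; RPD
is their ratio in percent. The heavy-atom convention is adopted everywhere
(a protruding hydrogen should not define penetration depth). Thickness,
depth and RPD are reported per frame with mean ± SD; the RPD identity
`rpd = 100 * depth / thickness` holds to 1e-9 relative and is tested as an
invariant together with translation and mirror invariance.

## RMSF and the membrane-solvent contrast

Superposition uses the Kabsch algorithm (SVD with a determinant correction
so the rotation is always proper). The RMSF reference is an iteratively
refined mean structure — fit all frames to frame 1, average, re-fit to the
mean, re-average — rather than frame 1 itself; the mean-structure
convention is the one consistent with the RMSF definition
`RMSF_i = sqrt(<|r_i - <r_i>|^2>)`. Residue values are unweighted means of
the per-atom RMSF over the residue's atoms (configurable by selection;
mass-weighting is deliberately not applied since bead fixtures have no
masses and the choice is immaterial for the contrasts of interest).

ΔRMSF subtracts a solvated profile from a membrane-bound profile on the
residue intersection only. Residues present in one profile but not the
other are reported as missing, never silently zero — a zero would read as
"no change", which is exactly the wrong default.

## Nonbonded energetics

The interaction energy between two disjoint atom sets is the sum of
pairwise 12-6 Lennard-Jones and Coulomb terms over cross pairs. For a
nonbonded-only model this equals U − U_a − U_b, because intra-set terms
cancel in the difference; the equivalence is tested against a scripted
double-loop oracle at 1e-9 relative. Combining rules are the CHARMM-style
geometric mean for ε and sum of half-Rmin for the pair minimum. The
Coulomb constant is 1389.35 kJ mol⁻¹ Å e⁻² with relative permittivity 1.

A plain truncation cutoff is available for parity with MD setups that used
12 Å; the default is the full double sum. Truncation is not equivalent to
the Ewald treatment used during dynamics, and no switching function is
applied — for post-hoc interaction analysis the untruncated sum is the
well-defined quantity. Fe²⁺ passes through the identical nonbonded path as
every other atom (the unbound-ion scheme); there is deliberately no
special-case code for it.

## SASA and the Poisson-Boltzmann solver

Shrake-Rupley surface areas use a deterministic golden-spiral point set
(default 960 points for analytic validation, 240 in trajectory loops), so
results are exactly reproducible with no RNG. The isolated sphere is
recovered to 0.5% and the two-sphere overlap to 1% of the closed-form
spherical-cap area.

The polar solvation term solves the linearized Poisson-Boltzmann equation
on a cubic finite-difference grid:

* dielectric interior = union of atom spheres at `eps_in` (default 2.0),
  exterior `eps_out` (default 78.54) — the usual implicit-solvent
  convention when the original calculation's settings are unreported;
* face dielectrics are harmonic means of three samples along each grid
  edge, a smoothed-boundary scheme that restores near-quadratic
  convergence on the Born ion;
* charges spread trilinearly to the eight surrounding nodes and potentials
  read back with the same weights;
* Dirichlet boundary from the analytic Coulomb (or Debye-Hückel when ionic
  strength is nonzero) potential of the charge set;
* matrix-free conjugate-gradient solve to a 1e-6 relative residual;
* the reported energy is the solvated solve minus a uniform-`eps_in`
  reference solve on the identical grid, which cancels the grid
  self-energy exactly.

Ionic strength defaults to 0 (plain Poisson); the linear (not nonlinear)
equation is solved. On a Born ion (q = 1 e, a = 2 Å, 1/78.54) the solver is
within 2.8% of the closed form at 0.8 Å spacing and 0.3% at 0.4 Å, and the
error shrinks monotonically with refinement — that convergence, not any
fitted constant, is the solver's validation. Atoms must clear the grid
boundary by at least 6 Å; non-convergence raises an error with the residual
rather than returning a number.

## MM/PBSA assembly

The single-trajectory protocol extracts complex, receptor and ligand
geometries from the same frame. ΔMM_gas is the nonbonded
complex − receptor − ligand difference (identical to the interaction
energy above in this model); ΔG_polar and ΔG_nonpolar are
complex − receptor − ligand differences of the solvation terms;
ΔG_nonpolar = γ·SASA + b with γ = 0.0227 kJ mol⁻¹ Å⁻² and b = 0 by default
(common MM/PBSA practice; both configurable). The entropy term is zero by
policy — for a congeneric series the entropic contributions approximately
cancel in relative comparisons — and it is *reported* as an explicit zero
column rather than omitted, so the policy is visible in every output. The
per-frame closure `g_binding = mm_gas + g_polar + g_nonpolar - t_ds` is
enforced at 1e-9 and tested. Every frame is used by default; a stride is
available for long trajectories.

## Interface contacts

The contact surface area is the buried-area form
`SASA(P) + SASA(M) - SASA(P∪M)` — the total buried surface summed over
both sides of the interface. The magnitude of the two-sided convention is
the one consistent with a two-helix membrane footprint of a few thousand
Å²; a single-sided variant (half) sits behind a flag and reports label the
convention used. Hydrogen bonds use geometric criteria — heavy donor-
acceptor distance ≤ 3.5 Å and D–H···A angle ≥ 150° — which are the common
MD-analysis defaults and fully configurable, since geometric H-bond
definitions are conventions, not measurements. Donor/acceptor identities
come from the fixture manifest for synthetic systems (decoupling chemistry
perception from detection geometry) or name-based rules for real files.
Contacting residues are those with any heavy atom strictly within 4.5 Å of
the other set.

## Active-site distances and cleavage calls

Distances are plain Euclidean norms from the six labeled carotenoid
carbons to the Fe²⁺ position, averaged over frames when a trajectory is
given (trajectory-level calls use mean distances, not per-frame majority
votes — one distance set per complex is the form in which such results are
reported and compared). Each candidate double bond is scored by the mean
of its two carbon distances: the score is a property of the *bond*, which
is the chemically meaningful unit, and on the packaged reference tables it
reproduces every per-complex site implied by the tables' minimum-distance
cells. The nearest bond wins; C15=C15′ means symmetric cleavage, C7=C8 or
C9=C10 asymmetric. A best-to-second gap at or below 0.3 Å — the printed
precision of such tables — returns an explicit ambiguous call. Substrate
ranking sorts binding energies ascending (most negative first) with
deterministic lexicographic tie-breaks and a tie flag.

## Implicit-slab insertion

The insertion optimizer treats the protein as a rigid body against an
implicit hydrophobic slab of half-width 15 Å with a 3 Å linear interface
ramp: f(z) = 1 in the core, 0 beyond the ramp. The pose energy is
`sum(sigma_res * ASA_atom * f(z_atom))`, where per-atom accessible areas
are computed once on the isolated protein (pose-independent for a rigid
body) and `sigma_res` is a shipped per-residue transfer coefficient —
water-to-octanol side-chain transfer energies in the Wimley-White spirit
divided by a reference exposed area, negative for apolar residues. This is
intentionally a simplified transfer model, not a full implicit-solvation
treatment: depths, tilts and energies it produces are qualitative
reference magnitudes, and the packaged reference insertion table is used
for arithmetic consistency checks, not as a numerical validation surface.

Optimization is an exhaustive, deterministic grid search over depth
(default 0.2 Å steps, matching the stepped-descent convention for such
protocols), tilt (2°, spanning 0-180°) and azimuth (30°, spanning 0-360°),
rather than a descent — exhaustive search is testable against a trivially
scripted oracle and cheap at these problem sizes. Ties break toward the
smallest azimuth, then tilt, then depth. The depth range always includes a
fully withdrawn pose, so a protein with no favorable face reports exactly
ΔG = 0 outside the slab; the reported angle is between the first principal
axis of the posed coordinates and the slab plane, in [0°, 90°].

## The synthetic generator: what it emulates, and what it does not

The generator builds the study conditions directly: a planar two-leaflet
bilayer whose mean phosphate planes sit exactly `phosphate_separation`
apart (39 Å by default, the initial phosphate-to-phosphate thickness of
the membrane model being emulated), with one `P` marker and two tail beads
per lipid at ~65 Å² per lipid; a globular shell protein with two coarse
helices protruding toward the membrane; a linear carotenoid-like carbon
chain whose C9=C10 midpoint sits nearest an Fe bead at a fixed 6.5 Å
offset; and Gaussian trajectories with prescribed per-residue displacement
amplitudes (expected per-atom RMSF = σ√3) plus optional rigid drift. All
randomness is seeded; generators are pure functions of their spec, and
every ground-truth quantity is recorded in a JSON manifest that the tests
assert against.

These are coarse bead models. They carry phosphate markers, polarity
classes, charges and radii — everything the analyses consume — but no
lipid chemistry, no torsional dynamics, no water. Passing tests therefore
establish that the *operations* are correct (geometry, energetics,
statistics, optimizers against oracles and closed forms), not that any
biological conclusion transfers; conclusions about real systems still
require real trajectories. The published-table checks play the
complementary role: they verify the package's arithmetic and decision
logic on the actual reported numbers (energy-partition identities, column
means, minima, cleavage calls, rankings). Headline trajectory averages
from microsecond-scale simulations of unreleased structural models are not
reproducible at test scale and are deliberately not acceptance surfaces;
two reference-table rows show a 0.01 kJ/mol partition deviation consistent
with last-digit rounding, which the worked-example report tolerates at
0.015 kJ/mol while the in-code identity remains exact.

## Problem sizes and numerical choices

The test and validation runs use deliberately small systems: bilayers of
25-128 lipids per leaflet, proteins of 30-60 residues, trajectories of
2-50 frames for pipeline checks and 2000 frames for RMSF parameter
recovery, PB grids of 0.4-0.8 Å spacing on single-ion and few-atom
systems, and SASA at 240-960 points. These sizes were chosen so every
oracle comparison is exact or statistically sharp (the 2000-frame fixture
pins RMSF recovery within 5%); all operations scale to realistic systems
with the same code paths.

Degenerate inputs fail loudly and early: zero-atom systems, duplicate
serials, non-finite coordinates, all phosphates in one leaflet, collinear
superposition sets, coincident atom pairs in energy sums, missing
parameters or transfer coefficients, empty selections in a pipeline
configuration (validated before any stage runs). Duplicate parameter-table
keys keep the last row with a warning, matching the common
last-definition-wins convention of such files.

## Known limitations

* The PB solver is linear, single-grid CG; no multigrid, no nonlinear
  term, no Stern layer. It is accurate at the grid spacings used here but
  not tuned for very large solutes.
* The slab model has no electrostatic term and a single hydrophobicity
  scale; curved membranes and lipid-type-specific slabs are out of scope.
* H-bond perception on real structures is name-rule based; no bond
  topology is read.
* The interaction-energy cutoff is a plain truncation, documented as
  non-equivalent to the Ewald electrostatics used during dynamics.
* Entropy is never estimated; the MM/PBSA column exists to make the
  omission explicit.
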