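---
title: "Ensemble analysis of amyloid-beta monomers and dimers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis of amyloid-beta monomers and dimers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abensemble)
```

# The scientific setting

Amyloid β-protein (Aβ) is intrinsically disordered: no single structure
describes it, and any analysis must be a statistics over a
conformational ensemble. The two physiologically dominant alloforms,
Aβ40 and Aβ42 (`DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV` + `IA`),
differ by two C-terminal residues yet assemble and harm neurons
differently, and dimerization — the first assembly step — is where
structural differences between them sharpen. This package implements
the ensemble statistics used to quantify such differences: contact
geometry, salt-bridge propensities, solvent exposure, empirical
free-energy landscapes, solvation structure, and convergence
diagnostics, together with a coarse-grained-to-atomistic reconstruction
and a synthetic-ensemble generator that makes the entire pipeline
testable without trajectory data.

All internal coordinates are Angstrom (the PDB native unit). Reporting
follows the field's conventions where they differ: RMSD and clustering
cutoffs in nm, SASA in nm². Residues are numbered 1-based, D1…A42.

# Containers and statistical convention

A `conformation` is one frame: an atom table (peptide id, residue
index/code, atom name, element, fixed vdW radius and mass from an
internal element table, so results never depend on the installation)
plus an n×3 coordinate matrix. An `ensemble` is a list of trajectories
sharing a topology, each with strictly increasing frame times and the
analysis window applied half-open at the start, `(t_start, t_end]`. At
a 50 ps recording interval, a (20, 50] ns window therefore holds
exactly 600 frames per 50 ns trajectory — the convention consistent
with per-condition conformation counts such as 44 trajectories →
26,400 conformations.

Frames within one MD trajectory are autocorrelated, so the package has
a single statistical convention used everywhere (`mean_sem()`):
trajectory means are computed first and treated as independent samples;
the reported mean is the mean of trajectory means, and
SEM = sd(trajectory means)/√k. SEM is exactly zero iff all trajectory
means coincide, and is reported as unavailable (never as 0) for a
single trajectory.

# The analyses

## Contacts and center-of-mass geometry

Two residues on different peptides are in contact when their Cα atoms
are strictly closer than the cutoff; ties at the cutoff are
non-contacts. The default cutoff is 7.5 Å — the convention of the
discrete-molecular-dynamics literature this style of analysis descends
from — with a second configurable cutoff (default 8.0 Å) for the
robustness check that contact numbers are insensitive to the choice
when no Cα pair falls in the gap between the two values. Contact maps
average the pair indicator over frames; intramolecular maps in dimers
average over the two peptides, and intermolecular maps are symmetrized
over peptide order so chain labeling in the input file cannot matter.

The per-residue distance from the center of mass uses the mass-weighted
CM of all peptide atoms (waters and ions never enter the container).
The NT-CM distance — from the N-terminal Cα (D1) to the assembly CM —
serves as an effective radius: in quasi-spherical Aβ assemblies the
N-terminus is the most solvent-exposed region, so this distance tracks
overall size.

## Salt bridges

A salt bridge between a positive residue (R5, K16, K28) and a negative
one (D1, E3, D7, E11, E22, D23) is present in a frame when the minimum
over side-chain N to side-chain O atom-pair distances is below the
cutoff. Backbone N/O and the charged termini are excluded: the tables
enumerate side-chain pairs only. The 4.0 Å default is a standard
salt-bridge criterion and is configurable; it is a package default, not
an externally fixed constant, and the run log says so explicitly.

Propensity is the percentage of observed time the bridge exists,
computed per trajectory and averaged with the trajectory-level SEM. In
dimers a pair is intrapeptide when both partners sit on one peptide
(occurrences on either peptide pool into a single statistic — the
pooled convention) and interpeptide otherwise; for monomers the
interpeptide class is structurally absent and reported as `NA`, not 0.
`aggregate_table()` assembles the standard layout: six pair rows per
positive residue, a `TOTAL` row per positive residue (the plain column
sum — totals can exceed 100% because the six bridges are not mutually
exclusive), and an `Average TOTAL` row (mean of the three totals).
Aggregates are computed from unrounded values and rounded half-up only
for display; this is why a displayed intra 26 + inter 0 can sit next to
a displayed total of 27.

## Solvent accessible surface area

`sasa_per_residue()` implements Shrake–Rupley sampling: a deterministic
960-point Fibonacci sphere at radius `vdW + probe` (probe 1.4 Å, a
water-sized sphere) around every atom, with points occluded by any
other probe-expanded atom discarded. The fixed point set makes areas
exactly reproducible; the discretization cost is a rotation dependence
below ~0.5% for aggregate areas (individual deeply-buried atoms can see
up to ~2%). Isolated-atom areas match 4π(r+1.4)² to better than 1%, and
two-sphere configurations match the analytic cap formula to 2%. The
hydrophobic reaction coordinate sums the per-residue areas over a
configurable hydrophobic set, default {A, V, L, I, M, F} — the
conservative standard choice; G and Y are excluded by default.

## Free-energy landscapes and representatives

`compute_pmf()` bins two per-frame reaction coordinates (for dimers,
typically contact number vs NT-CM distance) into an n×n histogram
(default 40×40 spanning the data range, last bin right-closed) and
Boltzmann-inverts occupancies: `pmf = −ln(N_i/N)` in kT, shifted so the
global minimum is 0. Empty bins are reported as *not sampled* (`NA`),
never as a large finite value — a masked bin is missing data, not a
barrier. `exp(−pmf_raw)` recovers the empirical frequencies exactly.

Representative structures come from the frames within `depth` kT
(default 0.1) of the PMF minimum, clustered by the GROMOS neighbor-count
algorithm: the frame with the most neighbors within the RMSD cutoff
(default 0.3 nm, Cα atoms, optimal Kabsch superposition) becomes a
centroid, its cluster is removed, and the procedure repeats. All ties
break to the lowest frame index, making the output deterministic and
permutation-invariant. A single representative of a disordered ensemble
is a visualization aid, not a summary — the package's profile and table
outputs are the primary results.

## Solvation structure

`water_rdf()` histograms, per frame, the distance of every water oxygen
to the *nearest heavy atom* of a residue. The reference point is a
declared design choice (the natural reading of "water around a
residue"); bulk density for normalization is estimated from the outer
20% of the radial range rather than the box volume, which tolerates
irregular solvation shells. First-shell counts integrate the raw counts
to the first minimum after the first maximum of g(r); a minimum only
counts as a shell boundary when the trough is genuinely depleted
(g < 0.8) with appreciable peak contrast (peak > 1.2 × trough) and when
the peak bin carries non-negligible statistics — otherwise the profile
is treated as structureless and a 3.5 Å fallback radius is used, with a
flag. Profile differences are classified at the peak of the symmetrized
mean profile: with D = |g_a − g_b| and S = sem_a + sem_b, `**` means
D > 1.1·S (clearly non-overlapping error bars), `*` means S < D ≤ 1.1·S
(touching, within a 10% band), anything else is no difference. The 10%
band makes a visual judgement quantitative and symmetric.

## Convergence diagnostics

`rmsd_series()` monitors the Cα RMSD of every frame against the
trajectory's first frame (the reference choice is a documented default;
an average-structure reference is equally valid and pluggable).
`select_extreme_trajectories()` returns the highest and lowest
time-averaged-RMSD trajectories to bound the ensemble spread.
`convergence_check()` evaluates a per-residue statistic over increasing
time windows or trajectory counts and declares convergence when the
last inter-level change drops below tolerance (0.5 Å default for
distance-from-CM profiles) — monotone in the tolerance by construction.

Secondary structure is consumed, not computed: an external assigner
(STRIDE-like) provides per-frame, per-residue labels as a plain text
stream (one line per frame, one letter per residue, T/E/H/C).
`ss_propensity()` turns them into per-residue class percentages that
partition to exactly 100%, with trajectory-level SEM.

## Coarse-grained reconstruction

Four-bead conformations (N, Cα, C′ backbone beads plus one side-chain
bead, absent for Gly) are rebuilt in two stages. *Grafting* places
backbone heavy atoms on the beads, adds the carbonyl O at idealized
geometry, and rigidly sets each residue's united-atom side-chain
template with its centroid on the side-chain bead, oriented along the
Cα→bead axis. Templates carry the exact heavy-atom composition of each
residue; their internal geometry is deliberately schematic (a compact
helical layout at ~1.5 Å spacing) — the contract is composition, clash
relief and the bead bound, not rotamer realism. *Relaxation* is
Metropolis Monte Carlo on a soft-sphere clash energy
E = Σ max(0, σ−d)² with σ = 0.9·(r_i + r_j), over pairs of different
residues excluding covalently constrained adjacent backbone pairs. Two
phases mirror the standard procedure: rigid side-chain moves, then
small single-atom backbone displacements guarded so the Cα virtual
bonds stay in 2.8–4.5 Å. Every move that would push the mapped bead
positions (N/Cα/C′ atoms and side-chain centroids, no re-superposition)
beyond `max_cg_rmsd` (default 2.0 Å, configurable) of the source beads
is rejected; zero-gain moves are rejected too, so a clash-free input
passes through bit-identically. The best-energy structure seen is
returned, making the final energy never exceed the initial one. The
default schedule is 10,000 proposed moves; the contract properties are
schedule-independent, and tests use shorter explicit schedules.

# The synthetic-ensemble generators

The generators define the study conditions for all tests. They
reproduce the *statistical structure* the analyses assume — not
physical dynamics, water hydrogens, or force-field energetics.

- **Monomers**: one self-avoiding Cα walk per trajectory (bond 3.8 Å,
  non-adjacent pairs ≥ 4.0 Å), one side-chain pseudo-atom per non-Gly
  residue carrying the N/O labels salt-bridge detection needs. Frame 1
  is the unperturbed base; later frames add Gaussian jitter (0.3 Å)
  and, when a target radius of gyration is set, an exact per-frame
  rescale about the CM. Per-trajectory seeds are `seed + index`, so
  trajectory subsets reproduce exactly.
- **Dimers**: two inward-directed walks from opposite sides of the
  assembly; the pull toward the center whenever the chain is > 8 Å out
  buries the C-terminal third while residues 1–5 stay peripheral —
  exposed N-termini and buried C-termini by construction. The second
  chain is slid along the assembly axis per frame until the interpeptide
  contact number lands within ±2 of the target, with bounded retries.
- **Telegraph salt bridges**: a two-state Markov chain per pair and
  trajectory with stationary occupancy p and mean ON dwell (default 10
  frames); ON frames place the side-chain N at cutoff−1 Å from the O,
  OFF frames at cutoff+3 Å. The occupancy estimator's sampling variance
  is the Bernoulli variance inflated by (1+ρ)/(1−ρ) with
  ρ = 1 − q_on − q_off, which is what the recovery checks use as their
  yardstick.
- **Water shells**: a Poisson point process of the requested density in
  a cube, with positions within 2.6 Å of any solute heavy atom
  rejected.
- **Four-bead chains**: idealized N/Cα/C′ geometry on a self-avoiding
  trace plus a side-chain bead at 2 Å; the `min_sep` argument controls
  chain openness (at ≥ 6 Å, glycine-only chains are clash-free after
  grafting).

What the generators do *not* emulate — realistic dihedral statistics,
cooperative folding, explicit water structure beyond uniformity,
force-field energetics — bounds what passing tests show about real MD
data: they validate the estimators and bookkeeping, not biological
conclusions.

# Numerical choices and problem sizes

- Contact cutoffs (7.5/8.0 Å), salt-bridge cutoff (4.0 Å), PMF bin
  count (40), cluster cutoff (0.3 nm), basin depth (0.1 kT) and the MC
  schedule are package defaults, exposed in the single flat
  configuration and echoed into every run log.
- The PMF-vs-Gaussian validation uses 10⁵ samples on a 25×25 grid and
  compares only bins with ≥ 800 counts: the shot noise of −ln N is
  ~N^(−1/2), so 800 counts bound the noise at ~3.5% ≈ 0.11 kT (3σ),
  which is what makes a 0.15 kT agreement check meaningful. Sparser
  bins test nothing but Poisson noise.
- Telegraph recovery runs 10 trajectories × 600 frames (one analysis
  window's worth per trajectory); clustering validation plants bundles
  of 5 and 3 with 0.05 nm internal spread at > 1 nm separation;
  reconstruction is validated in batches of full-length Aβ42 chains
  with short explicit MC schedules, since the contract (composition,
  monotone best energy, bead bound) is schedule-independent.
- Degenerate inputs are explicit: empty atom selections, monomer input
  to dimer-only analyses, windows outside the trajectory span, zero
  frames for a PMF, occupancies outside [0, 1] and non-positive MC
  schedules are errors; single-trajectory SEMs are flagged unavailable;
  structureless RDFs fall back with a flag rather than inventing a
  shell.

# Known limitations

- Pure-R pairwise loops (GROMOS clustering, per-frame salt-bridge
  scans) are comfortable at the tested scales (hundreds of frames for
  clustering, thousands for propensities) but would want blocking or
  compiled kernels for millions of frames.
- The RDF shell-volume normalization treats shells around the
  nearest-atom distance as spherical, which is exact for point-like
  references and approximate for extended residues; the tail-based bulk
  estimate absorbs most of the bias.
- Side-chain templates are schematic; reconstructed structures are
  meant as inputs for downstream refinement (e.g. hydrogen addition and
  minimization by external tools), not as final models.
- The secondary-structure assigner is external by design; only its
  label stream is consumed.
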