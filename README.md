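# abensemble

Structural analysis of amyloid β-protein (Aβ40/Aβ42) monomer and dimer
conformational ensembles sampled by molecular dynamics.

Aβ dimer formation is the first step of the assembly into the toxic
oligomers implicated in Alzheimer's disease, and the two predominant
alloforms — Aβ40 and Aβ42, which differ only by the C-terminal residues
I41–A42 — follow distinct assembly pathways. Characterizing how tertiary
and quaternary structure changes on dimerization requires ensemble-level
statistics over many trajectories, not single structures. This package
provides those statistics for anyone analyzing MD (or MD-like) ensembles
of disordered peptides:

- **Contact analysis** — interpeptide contact number (residue pairs with
  Cα–Cα distance < cutoff, default 7.5 Å) and intra/intermolecular
  contact maps with SEM.
- **Center-of-mass geometry** — per-residue distance from the assembly
  CM, the NT-CM distance (distance of the N-terminal Cα from the CM,
  an effective radius of a quasi-spherical assembly), radius of
  gyration.
- **Salt bridges** — a bridge between a positive residue (R5, K16, K28)
  and a negative residue (D1, E3, D7, E11, E22, D23) exists whenever any
  side-chain N atom lies within a cutoff (default 4.0 Å) of any
  side-chain O atom. Propensity = 100 × (time present)/(time observed),
  assembled into tables with per-positive-residue `TOTAL` rows and an
  `Average TOTAL` row.
- **SASA** — Shrake–Rupley solvent accessible surface area with a
  960-point deterministic sphere, per residue and summed over the
  hydrophobic set, the reaction coordinate for hydrophobic burial.
- **Free-energy landscapes** — 2D potential of mean force
  `PMF_i = −ln(N_i/N)` (in kT) over two reaction coordinates, with
  lowest-basin frame selection and GROMOS-style pairwise-RMSD clustering
  (Kabsch superposition) for representative conformations.
- **Solvation** — per-residue water radial distribution functions,
  first-shell counts, and a quantitative SEM-overlap classification of
  profile differences (`**` / `*` / none).
- **Convergence diagnostics** — RMSD time series, extreme-trajectory
  selection, and profile convergence over time windows or trajectory
  counts. The single statistical convention throughout is the
  trajectory-level SEM: trajectory means are independent samples.
- **CG reconstruction** — four-bead (N, Cα, C′, side-chain bead)
  coarse-grained conformations are rebuilt as united-atom structures by
  side-chain template grafting plus Monte Carlo clash relief under a
  hard bead-RMSD bound.
- **Synthetic ensembles** — seeded generators for disordered monomers,
  quasi-spherical dimers with buried C-termini, two-state (telegraph)
  salt-bridge dynamics with prescribed occupancy, uniform water shells,
  and four-bead chains, so every stage is testable without trajectory
  data.

## Worked example

```r
library(abensemble)

spec <- alloform("Ab42")
cfg  <- generator_config(seed = 42, n_trajectories = 4,
                         frames_per_trajectory = 50,
                         target_contact_number = 20)
e <- gen_dimer_ensemble(cfg, spec)

cn <- unlist(map_frames(e, contact_number))
nt <- unlist(map_frames(e, function(f) mean(nt_cm_distance(f))))
prof <- residue_cm_distances(e)

g <- compute_pmf(cn, nt, n_bins = 12,
                 x_name = "contact_number", y_name = "nt_cm")
basin <- lowest_basin_frames(g, depth = 0.1)
```

This prints / yields:

```
frames: 200
contact number mean: 21.2  range: 19 22
NT-CM distance mean: 33.3 A
D1  dist from CM: 33.3 +/- 0.1  A
A42 dist from CM: 11.3 +/- 0.2  A
PMF grid: 12 x 12 bins, 200 frames, 35 occupied bins
basin frames: 33
```

The generated dimers hit the requested interface size (contact number
20 ± 2), and the per-residue profile shows the constructed architecture:
the N-terminal D1 sits far from the center of mass (solvent-exposed,
33 Å) while the C-terminal A42 is buried (11 Å) — the quasi-spherical
arrangement with exposed N-termini that the NT-CM coordinate is designed
to measure. The PMF bins the 200 frames over the two reaction
coordinates; the 33 frames within 0.1 kT of the global minimum would be
passed to `gromos_cluster()` and the centroid of the largest cluster
taken as the representative conformation.

A full configuration-driven run (profiles, salt-bridge tables, contact
maps, PMF + representative structure, convergence report, manifest with
checksums) is:

```r
run_pipeline(default_run_config(), output_dir = "run1")
```

or from a shell: `Rscript inst/cli/analyze.R --config run.yaml --output run1`.

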