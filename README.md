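# trajkit

Analysis toolkit for molecular-dynamics trajectories of multi-domain
proteins and their complexes — the comparative workflow used to ask how a
ligand or a protein partner changes a receptor: domain flexibility (RMSD
distributions, RMSF profiles, per-residue difference maps), interface
complementarity (buried area, gap volume, gap index), inter-helix angles
framing binding sites, conformational substates, interaction occupancy,
ligand mobility and exposure, and principal component analysis of
collective motion. A synthetic-trajectory generator with recorded ground
truth validates every stage end to end.

## The quantities at the core

For two parts A and B of a complex AB, the buried area on complexation is

    ΔASA = (ASA_A + ASA_B − ASA_AB) / 2

with accessible areas from Shrake–Rupley sampling (probe 1.4 Å). The gap
volume V_gap is the volume of the empty region enclosed between the parts
(a sphere-packing construction integrated on a grid), and the interface
complementarity statistic is the

    gap index = V_gap / ΔASA      [Å]

— low values (≈1–5 across typical protein–protein interfaces) mean tight,
complementary packing. Domain flexibility uses Kabsch superposition:
per-frame RMSD against the iteratively converged average structure, and
per-atom/per-residue RMSF about it. Helix-pair angles are measured between
total-least-squares axes fitted through local helix origins of the Cα
trace, signed N→C so opening and closing are distinguished. Collective
motion is the eigensystem of the mass-weighted covariance of superposed
backbone coordinates; substates come from neighbor-counting (GROMOS-style)
clustering of the pairwise frame-RMSD graph.

## Worked example

Simulate a two-domain complex with a bound ring ligand, run the full
analysis, and read off the headline numbers:

```r
library(trajkit)

cfg  <- generator_config(seed = 5, n_frames = 70, noise_sigma = 0.08,
                         ligand = list(present = TRUE, n_atoms = 10L,
                                       ions = TRUE, jitter = 0.25))
sys  <- build_two_domain_system(cfg)
traj <- generate_trajectory(sys, cfg)$trajectory

bundle <- run_system(run_config(
  "apo", traj, discard = 10,
  domains     = list(C1 = "chain A", C2 = "chain B"),
  helix_pairs = list(
    alpha_C1 = list("chain A and resid 408-420",
                    "chain A and resid 468-475"),
    alpha_C2 = list("chain B and resid 910-918",
                    "chain B and resid 978-988")),
  interface    = list(part_A = "chain A", part_B = "chain B"),
  ligand       = "resname LIG", receptor_fit = "chain A,B",
  cluster_cutoff = 1.0, stride = 12))

s <- summary_table(bundle)
s[c("angle_mean_alpha_C1", "angle_mean_alpha_C2",
    "gap_index_mean", "ligand_rmsd_mean")]
#> $angle_mean_alpha_C1
#> [1] 25.86505
#> $angle_mean_alpha_C2
#> [1] 43.98312
#> $gap_index_mean
#> [1] 3.501402
#> $ligand_rmsd_mean
#> [1] 0.4375331
```

The helix pairs sit at their constructed 26° and 44°; the interface's gap
index of ≈3.5 Å is in the loose half of the typical 1–5 Å protein–protein
band; the ligand rattles by ≈0.44 Å about its mean pose. Comparing two
systems (`compare_systems()`) adds per-residue displacement and ΔRMSF maps
plus signed deltas of every scalar — e.g. an engineered tighter-interface
variant shows a negative Δgap-index.

A thin command-line front end over the same functions ships in
`inst/cli/trajkit.R` (`simulate`, `run`, `compare` subcommands on YAML
configs).

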