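# diccr

Distance-correlation analysis of concerted domain motion in molecular
dynamics trajectories of multi-domain proteins.

## What it is for

Large multi-domain proteins — the motivating system is NPC1, the 1278-residue
lysosomal cholesterol transporter whose lumenal NTD/MLD/CTD domains ride on a
transmembrane bundle containing the sterol-sensing domain — move as loosely
coupled rigid bodies. Disease mutations such as P691S can disrupt the
*communication* between domains without much changing how far each domain
fluctuates. `diccr` quantifies that communication and localizes where it
changes:

* **DiCC matrices** — the distance correlation coefficient between every pair
  of domain position series. For series {A}, {B} over n frames, with
  double-centered inter-frame distance matrices â, b̂:

  ν(A,B) = (1/n²) Σᵢⱼ âᵢⱼ b̂ᵢⱼ,  DiCC = √( ν(A,B) / √(ν(A,A)·ν(B,B)) )

  (Székely–Rizzo distance correlation: 1 for fully dependent motion, near 0
  for independent motion, invariant to rigid motion and scaling of either
  series).
* **ΔDiCC** — the cellwise |DiCC₁ − DiCC₂| between two conditions (wild type
  vs mutant), with a ranked report of the most-changed domain pairs.
* **Supporting geometry** — Kabsch superposition, per-domain backbone RMSD
  series under a single global fit, ligand atom-pair distance series and net
  centroid displacement, residue contact shells (inclusive 5.0/3.0 Å
  cutoffs), and geometric hydrogen-bond networks (heavy-atom distance
  ≤ 3.5 Å, occupancy over frames).
* **A synthetic trajectory generator** — rigid pseudo-domains with a
  prescribed inter-domain coupling matrix, per-atom jitter and a drifting,
  diffusing ligand, used to validate every stage at desk scale with
  bit-reproducible seeds.

Structures are read from PDB, trajectories from multi-model PDB or
CHARMM/NAMD-dialect DCD (via bio3d, plus a built-in DCD writer).

## Worked example

```r
library(diccr)

## generate a coupled two-domain system with a drifting ligand
spec <- synthetic_spec(domain_sizes = c(20, 20),
                       coupling = coupling_matrix(2, 0.9),
                       seed = 42)
sys  <- build_synthetic_system(spec)
traj <- simulate_trajectory(sys, spec)

## inter-domain coupling (lab-frame synthetic data: no alignment needed)
m <- domain_dicc_matrix(traj, synthetic_domains(spec))
print(m)
#> DiCC matrix (2 domains, 100 frames, mode domain-vector)
#>       D1    D2
#> D1 1.000 0.916
#> D2 0.916 1.000

## ligand translocation
lig <- atom_selection(which(sys$atoms$residue_name == "LIG"), "ligand")
net_displacement(traj, lig)
#> [1] 13.32

## compare the published wild-type and P691S reference matrices
res <- run_compare(system.file("extdata", "npc1_dicc_wt.csv", package = "diccr"),
                   system.file("extdata", "npc1_dicc_p691s.csv", package = "diccr"),
                   out_dir = tempdir())
head(res$ranking, 3)
#>   domain_a domain_b delta
#> 1      CTD CytLoops 0.209
#> 2      TMD CytLoops 0.179
#> 3      NTD CytLoops 0.119
```

The DiCC of 0.916 reflects the prescribed coupling of 0.9 between the two
domain centers (the statistic carries a small positive finite-sample bias at
100 frames). The ligand covers ~13 Å because its 9.9 Å directed drift is
superimposed on a diffusive walk. The ranked ΔDiCC report reproduces the
published comparison for NPC1: the largest change in inter-domain coupling
between wild type and P691S is CTD–cytosolic loops at 0.209.

A command-line dispatcher with the same functionality ships at
`inst/exec/diccr` (subcommands `synth`, `dicc`, `delta`, `rmsd`, `track`,
`contacts`, `hbonds`, all driven by a YAML run config).

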