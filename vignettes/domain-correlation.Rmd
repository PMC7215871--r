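---
title: "Quantifying concerted domain motion with distance correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concerted domain motion with distance correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diccr)
```

## The problem

Large multi-domain membrane proteins such as NPC1 — the lysosomal
cholesterol transporter whose lumenal domains (NTD, MLD, CTD) sit atop a
transmembrane bundle containing the sterol-sensing domain — move as loosely
coupled rigid bodies. Whether a point mutation disrupts the *communication*
between domains is not visible in per-domain RMSD alone: two domains can
each fluctuate by 2–3 Å while moving either in concert or independently.
`diccr` quantifies that coupling with the distance correlation coefficient
(DiCC) between domain position series, and locates where coupling changes
between two conditions (e.g. wild type versus the disease-associated P691S
mutant) through the cellwise difference of their DiCC matrices.

## The statistic

For a domain we form a *position series*: one configuration vector per
trajectory frame (by default the concatenated coordinates of the domain's
backbone atoms, dimension $3N$). Given two series $\{A\}$ and $\{B\}$ over
$n$ frames, let $a_{ij} = \lVert A_i - A_j \rVert$ be the inter-frame
distance matrix of $A$, and double-center it:

$$\hat a_{ij} = a_{ij} - \bar a_{i\cdot} - \bar a_{\cdot j} + \bar a_{\cdot\cdot}.$$

The sample distance covariance (Székely, Rizzo & Bakirov 2007) is the
V-statistic

$$\nu(A,B) = \frac{1}{n^2} \sum_{ij} \hat a_{ij}\, \hat b_{ij},$$

and the distance correlation is

$$\mathrm{DiCC}(A,B) \;=\; \sqrt{\frac{\nu(A,B)}{\sqrt{\nu(A,A)\,\nu(B,B)}}}.$$

DiCC is 1 for fully dependent motion and near 0 for independent motion. It
is built entirely from inter-frame distances, so it is invariant to rigid
rotation, translation, reflection and positive scaling applied uniformly to
either series — the property that makes it preferable to Cartesian
cross-correlation matrices, which are angle-sensitive. Some applications
report the squared statistic $R^2$ rather than $R$; `distance_correlation()`
and `domain_dicc_matrix()` expose a `squared` flag, defaulting to $R$, which
keeps the matrix in $[0,1]$ with a printed diagonal of 1.00.

Numerical conventions: a negative $\nu$ produced by floating-point
cancellation is clamped to 0 before the square root; a series with zero
distance variance (a domain that never moves) makes the statistic undefined
and the cell is reported as `NA`, never as 0.

Two series constructions are provided by `domain_dicc_matrix()`:
`domain-vector` (default) treats the whole domain as one $3N$-dimensional
vector per frame; `atom-pair-mean` computes the DiCC of every (atom-in-A,
atom-in-B) pair of 3-D series and averages. The first is the cheapest
well-defined reading of "the atomic positions of a domain" and is what the
reference matrices shipped with the package are compared against; the
second follows the per-atom convention of part of the trajectory-dCor
literature and is noticeably more conservative, because independent
per-atom noise dilutes each 3-D pair. The construction used is recorded in
the output metadata.

## Alignment, and when not to align

Real MD trajectories contain global rigid-body motion that would dominate
any position-based statistic, so the standard protocol — and the default of
the `run_dicc()` pipeline stage — is to superpose every frame onto the
first frame's protein backbone (Kabsch SVD superposition with determinant
correction; unweighted, as no mass weighting is implied by "backbone
atoms") before computing DiCC.

Alignment has a cost that is easy to underestimate: the fit absorbs six
rigid degrees of freedom *shared by all domains*, so part of each domain's
motion reappears, with opposite sign, in every other domain. For a system
of only two mobile domains this fit-induced coupling is nearly total — two
statistically independent domains show apparent DiCC ≈ 1 after alignment,
because the fitted frame turns every displacement of one domain into a
counter-displacement of the other. With six domains plus connecting
structure (the real-protein situation) the artifact is diluted and the
aligned statistic is the accepted practice. The synthetic generator below
produces coordinates in a fixed laboratory frame with no global tumble, so
validation and parameter-recovery runs on synthetic data use the raw
trajectory (`align: false`); this choice is made explicit in the pipeline
configuration rather than silently inferred.

A second small-sample property worth knowing: the V-statistic's distance
matrices have an exactly zero diagonal and, for high-dimensional noise,
nearly constant off-diagonal entries. That shared pattern inflates DiCC
between *independent* high-dimensional series — in the limit of pure
uncorrelated per-atom jitter the statistic approaches 1 even though no
coupling exists. DiCC as used here is therefore informative about
domain-scale (center-of-mass) motion, not about uncorrelated internal
noise, and the generator's defaults keep center motion (1.0 Å per frame)
well above the internal jitter (0.3 Å). At the default 100 frames the null
(independent domains, center motion dominant) sits around 0.35 — the
documented finite-sample positive bias of the V-statistic — while strongly
coupled domains exceed 0.9, so ordering across coupling strengths is
recovered reliably; with temporal averaging or longer runs the null shrinks
toward 0.

## The synthetic generator

`synthetic_spec()` + `build_synthetic_system()` + `simulate_trajectory()`
emulate the statistical structure the analyses consume, not the physics
that produces it:

* each domain is a rigid cluster of pseudo-residues (backbone atoms
  N/CA/C/O on a helical lattice), displaced per frame by a correlated
  Gaussian: displacements across domains have correlation matrix
  `coupling` and per-axis scale `com_sigma`;
* independent Gaussian `jitter_sigma` per atom per coordinate models
  internal flexibility;
* an optional single-residue ligand (atoms C25 and O3, echoing the
  cholesterol atoms used for translocation tracking) moves as directed
  drift plus a diffusive random walk — the contrast between lateral
  bilayer-ward motion and axial tunnel-ward translocation reduces, at this
  level of description, to the drift direction;
* draws are consumed in a documented order (domain displacements, then
  jitter, then ligand diffusion) from a single seeded stream, so outputs
  are bit-reproducible and stable under feature toggles.

Defaults are chosen to resemble a 100-snapshot, 1 ns/frame production run
of a large solvated protein: 100 frames, `com_sigma` 1.0 Å (giving
per-domain backbone RMSDs in the 2–3 Å range), `jitter_sigma` 0.3 Å, ligand
drift 0.1 Å/frame so a full run covers ~10 Å, diffusion 0.2 Å per step.
Frames are drawn independently by default — the statistic operates on
positions, not dynamics, so white motion suffices for recovery tests — and
an AR(1) memory parameter (`ar_phi`) exists for more realistic-looking
series.

What the generator deliberately does not emulate: force fields, solvent and
membrane, autocorrelated collective modes, anisotropic domain rotation
(domains translate rigidly but do not tumble), side chains. Passing tests
on synthetic data therefore demonstrate the *estimators* are correct and
recover prescribed coupling; they do not demonstrate anything about the
conformational ensembles of real proteins.

## Geometry: superposition and RMSD

`kabsch_superpose()` returns the optimal proper rotation + translation and
the minimized RMSD; degenerate (collinear) point sets are rejected rather
than silently resolved. `rmsd_series()` aligns globally on a fit selection
(default: all protein backbone) and then computes each domain's RMSD *under
that single global fit*, without per-domain refitting — refitting each
domain would hide exactly the inter-domain motion the package exists to
measure. The reference structure defaults to the first frame and is
configurable (an energy-minimized or average structure can be passed as a
coordinate matrix); with a first-frame reference the series starts at 0 by
construction. `net_displacement()` reports the straight-line distance
between a selection's unweighted centroid in the first and last frames —
for a drift of 0.1 Å/frame over 100 frames that is 99 steps, hence 9.9 Å.

## Interactions

`contact_shell()` lists residues whose minimum atom distance to a query
selection is at or below a cutoff (inclusive boundary; defaults 5.0 Å for
display shells, 3.0 Å for close contacts). `hbond_network()` classifies a
donor/acceptor heavy-atom pair (N/O/S only, enforced) as hydrogen-bonded in
a frame iff their separation is ≤ 3.5 Å, and reports per-pair occupancy
over the trajectory. The criterion is deliberately distance-only — matching
the 3.5 Å convention used in structural depictions of hydrogen-bond
networks — with an optional D–H···A angle term (≥ 120°, hydrogens located
by ≤ 1.25 Å proximity to the donor) available but off by default. Note one
naming caveat surfaced in the NPC1 literature this package accompanies:
pairs of asparagine side chains are sometimes described as "salt bridges";
chemically they are neutral polar contacts, and `diccr` treats them as
generic donor/acceptor pairs with no special handling.

## Domain definitions

Domains are unions of inclusive 1-based residue ranges. The bundled NPC1
partition (`npc1_domains()`, also shipped as
`inst/extdata/npc1_domains.yaml`) uses NTD 30–250, MLD 374–620, CTD
861–1083, TM helices 260–373 ∪ 621–797 ∪ 1084–1278, linker 251–259 and
cytosolic loops 290–337. Published boundary statements for NPC1 differ by a
few residues between depictions (NTD also appears as 25–264, MLD as
370–621, CTD as 854–1083); the package adopts the partition used for the
correlation tables and surfaces the discrepancy here rather than resolving
it. The cytosolic-loop range lies inside the first TM range: overlapping
domains are explicitly permitted, and selections are idempotent and
duplicate-free.

## Reference matrices

`inst/extdata/` ships the published six-domain DiCC matrices for
cholesterol-bound wild-type NPC1 and the P691S mutant (100 ns simulations,
values printed to three decimals). They serve as worked-example input for
`delta_dicc()`/`run_compare()`: the largest off-diagonal change is
CTD–CytLoops at 0.209, and NTD–TMD changes by 0.105. One cell of the mutant
matrix is printed inconsistently between its two symmetric positions in the
original presentation (MLD–TMD: 0.810 vs 0.801); the shipped file uses
0.810 in both triangles, the value consistent with the published difference
matrix. Recomputing the full off-diagonal ranking also shows TMD–CytLoops
(0.179) and NTD–CytLoops (0.119) rank above NTD–TMD — the ranked report
written by `run_compare()` is the recomputation, not a transcription.

Because the originating 100 ns, ~300k-atom membrane trajectories are not
desk-scale objects (and the series construction behind the published
matrices is not fully specified), those DiCC values are treated as fixed
reference *inputs*, not as quantities this package re-derives from
trajectories.

## Problem sizes used in the shipped tests

The test suite and the reproduction script run entirely on synthetic data:
two-domain systems of 20 pseudo-residues per domain (160 backbone atoms) at
100 frames for null and coupling-recovery studies (50 replicates × 3
coupling levels), 2000 frames for convergence of the empirical coupling,
500-atom random frames for brute-force comparison of the contact and
hydrogen-bond scans, and 10⁴-atom single frames for the Gaussian RMSD
expectation check. These sizes were chosen so each statistical check has
comfortable resolution while the whole suite stays interactive.

## Known limitations

* DiCC values depend on the series construction (`domain-vector` vs
  `atom-pair-mean`) and on whether $R$ or $R^2$ is reported; comparisons
  across software must match those conventions cell by cell.
* The V-statistic estimator is positively biased at small $n$ and inflated
  for high-dimensional uncorrelated noise (see above); no bias-corrected or
  unbiased (U-statistic) estimator is provided, and no permutation testing
  is attempted.
* Alignment-induced coupling makes aligned DiCC matrices of few-domain
  systems hard to interpret; prefer raw lab-frame coordinates when the
  input has no global tumble.
* The DCD reader/writer handles the CHARMM/NAMD convention without unit
  cells; periodic-boundary unwrapping is out of scope, and analyses assume
  unwrapped coordinates.
* Hydrogen-bond detection is geometric only; occupancies say nothing about
  energetics.

## References

Székely, G. J., Rizzo, M. L., & Bakirov, N. K. (2007). Measuring and
testing dependence by correlation of distances. *Annals of Statistics*,
35(6), 2769–2794.

Kabsch, W. (1976). A solution for the best rotation to relate two sets of
vectors. *Acta Crystallographica A*, 32, 922–923.
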