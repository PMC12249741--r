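---
title: "Comparative MD trajectory analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative MD trajectory analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcompare)
```

mdcompare compares the structural dynamics of a wild-type protein against
point variants from molecular-dynamics trajectories. This vignette is the
package's account of the science it implements: the models and their
assumptions, the parameters that matter, the synthetic-data generators that
back the test suite, and the design choices made where the methodology is
genuinely open.

## The analysis pipeline

A study compares one reference condition ("wild") against any number of
variants, each condition carrying one or more replicate trajectories. Per
replicate the package computes sampling-convergence diagnostics and the
classic superposition metrics; per condition it computes residue-residue
correlation structure, essential-dynamics subspaces, secondary-structure
occupancy, and a free-energy landscape with basin-resolved re-analysis. All
residue reporting uses author (PDB) numbering, since variant positions such
as Thr46 or Pro56 are quoted in author numbering in the literature.

## Superposition and the four global metrics

All fluctuation analyses first remove the six rigid-body degrees of freedom
by least-squares (Kabsch) superposition, with reflections excluded. RMSD
series are fitted frame-by-frame against the first frame (the convention for
per-replicate equilibration plots) or against the input structure — the
latter is what the free-energy landscape uses, so that the reaction
coordinate has a fixed physical origin. RMSF uses an iteratively refined
mean structure (tolerance 1e-6 Å; two iterations typically converge),
which removes reference-frame bias.

A consequence worth knowing: superposition absorbs variance. For isotropic
Gaussian displacements of per-coordinate standard deviation $\sigma$ on $n$
atoms, the expected RMSF is not $\sigma\sqrt{3}$ but
$\sigma\sqrt{3}\sqrt{1 - 2/n}$, because 6 of the $3n$ variance degrees of
freedom are removed. The test suite asserts this corrected closed form.
Likewise, a planted correlation block spanning a large fraction of the chain
is partially absorbed as collective motion: at domain scale (a block of ~18
residues in a 125-residue chain) the deflation is a few percent, which is
why planted-recovery tests run at that scale.

Rg is computed about the (by default mass-weighted) centroid and SASA by the
Shrake–Rupley construction: a deterministic Fibonacci sphere lattice
(default 960 points) on each atom inflated by the probe radius (1.4 Å
water), counting points not buried inside any neighbour. Radii come from a
pinned Bondi table; SASA uses protein heavy atoms by default (whether
crystal waters or hydrogens were included in published SASA figures is
rarely stated, so the defaults are pinned and documented rather than
guessed). Against an independent implementation (mdtraj) the total SASA of a
129-residue lysozyme chain agrees to ~0.1%.

## DSSP

Secondary structure is assigned by the classic 1983 dictionary: amide
hydrogens are rebuilt at 1.0 Å from N along the previous carbonyl's O→C
direction; hydrogen bonds are scored with the electrostatic model
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, with bonds below −0.5 kcal/mol; n-turns (n = 3, 4, 5), minimal
helices, bridges, ladders and bulge-linked sheets follow the original
rules, with bends at Cα kinks above 70° and chain breaks at peptide C–N
distances above 2.5 Å. Priority is H > E > B > G > I > T > S. No DSSP 4
extensions (no polyproline-II class) are implemented, matching the
historical definition. Agreement with an independent implementation is
98–100% of residue-frames across the fixture set (ideal helix, hairpin,
coil, and a real lysozyme chain); the residual disagreements are
G-versus-T boundary calls at helix termini.

Occupancies are residue-frame averages (the percentage of all
residue-frames in a class), and per-residue difference profiles are
percentage-point deltas (variant − wild). Overall deltas are additionally
rounded to integer percent, the granularity at which such shifts are
usually quoted; unrounded values are retained. The eight codes map to the
reported classes as H→α-helix, G→3₁₀-helix, I→π-helix, E→β-sheet,
B→β-bridge, T→turn, S→bend, "-"→coil. Because "β-sheet" versus "β-strand"
proportions are sometimes distinguished without definition, the package
emits both readings: E (sheet) versus B (bridge) occupancies, plus
per-frame counts of maximal E segments (`strand_segments()`); neither is
privileged.

## Dynamic cross-correlation

The DCCM is the normalised covariance of residue displacement vectors about
their time means,
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
(\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle)^{1/2}$,
computed after superposition onto the mean structure. Values are bounded by
±1 (asserted for every matrix); zero-variance residues get zeroed rows with
a warning rather than NaNs. Replicates are computed separately and averaged
entrywise by default (a concatenated mode is available through the pipeline;
published work rarely states which pooling was used, so both exist and
neither is asserted as anyone's choice).

Wild-versus-variant comparison uses the entrywise absolute difference with a
0.2 threshold, the conventional display cutoff. Since the rule by which
published "altered regions" (e.g. 45–62) are delimited from such maps is
never stated, region extraction is fully specified here as a documented
decision: a residue is affected when more than `row_fraction` (default 5%)
of its row exceeds the threshold; affected residues merge into maximal runs
bridging single-residue gaps; runs shorter than `min_len` (default 2) drop.
These defaults reproduce planted-block fixtures exactly.

## Essential dynamics

PCA diagonalises the 3N×3N covariance of the superposed Cα coordinates
(mass-unweighted, as Cα-level analyses conventionally are). At least six
trailing eigenvalues are near zero because superposition removed the
rigid-body subspace; rank deficiency when frames < 3N is expected and only
warned about. Eigenvector signs are fixed by making the largest-magnitude
component positive so porcupine exports are reproducible — the overall sign
of a mode remains a convention, and flipping it flips every arrow.

Subspace similarity uses RMSIP over the first k = 10 PCs,
$\sqrt{\frac1k \sum_{i,j\le k} (\eta_i\cdot\nu_j)^2}$: 1 for identical
subspaces, 0 for orthogonal ones, and for independent random
10-dimensional subspaces of a 375-dimensional space it concentrates near
$\sqrt{10/375} \approx 0.163$ — a useful null reference when reading RMSIP
heat maps.

Sampling convergence uses the cosine content of the leading PC projections
(Hess's half-period-cosine diagnostic), evaluated by trapezoidal quadrature
on the frame grid after mean-centring. Random-diffusion-like sampling gives
values near 1; the pipeline flags a replicate converged when the first five
PCs all fall below 0.7. The diagnostic is deliberately order-sensitive —
permuting frames changes it — while the PCA itself is order-free; both
properties are asserted in the tests.

## Free-energy landscapes

The landscape is the Boltzmann inversion of a 2-D histogram over
(RMSD, Rg), $G_i = -k_B T \ln(N_i / N_{max})$ with
$k_B = 0.0019872041$ kcal/mol/K and T = 300 K by default, on a 50×50
equal-width grid spanning the data range. The most-populated bin sits at
exactly 0; empty bins carry NA energy and are rendered at a display
ceiling, never treated as minima.

Basin "clustering by FEL value" has no canonical algorithm, so the package
uses a deterministic, parameter-light rule: cells at or below a depth
cutoff (default 1.0 kcal/mol) form candidates, and their 8-connected
components are the basins, ranked by minimum raw energy. Two numerical
safeguards matter in practice. First, candidate detection runs on a lightly
smoothed (3×3 box) count grid: sparse histograms fragment under Poisson
shot noise, and smoothing suppresses spurious satellite minima without
altering the reported (raw) energies. Second, components holding fewer than
`min_frames` frames (default 0.2% of the trajectory) are dissolved — they
are isolated outliers, not metastable states. Basin counts are inherently
bin-dependent; `basin_count_sensitivity()` reports counts at 30/50/70 bins
so that sensitivity is visible rather than hidden.

Because the fixed absolute cutoff truncates each basin's low-density skirt,
the raw frame count of a basin underestimates the state's population, and
deeper basins are truncated relatively less. The meaningful recovered
occupancy is therefore a basin's frame count relative to all basin-assigned
frames; with equal spreads this ratio is unbiased, and for a planted
0.7/0.3 two-state system it recovers 0.7 within sampling error with a mild
upward bias on the deeper state (~0.05 in the test conditions).

Basin re-analysis extracts member frames as a sub-trajectory in original
order. The representative conformer is the medoid frame — the member with
least RMSD to the superposed basin mean — because averaged coordinates have
unphysical local geometry: DSSP and SASA in basin reports run on real
frames, with the mean structure exported for visualisation only.

## The synthetic-data generators

The generators exist so every stage has a ground-truth recovery test
without any trajectory download; they emulate statistics, not physics.

* `make_correlated_trajectory()` plants an exact residue-residue
  correlation matrix (unit diagonal plus signed constant blocks, verified
  positive-semidefinite at build time, with the offending block named when
  not) by sampling each Cartesian axis independently with covariance
  `amplitude^2 * target` about a fixed non-collinear Cα trace. The
  population DCCM equals the target exactly; sample estimates converge at
  ~1/√frames, which the suite checks at two sizes. Note that an
  anticorrelated rectangle between two groups is only a valid correlation
  structure together with its positively correlated diagonal companion
  blocks — a lone −0.9 rectangle is rejected as non-PSD, which is a
  mathematical fact rather than a generator limitation.
* `make_basin_trajectory()` drives a hidden Markov chain whose stationary
  distribution is the requested occupancy vector (mean dwell settable),
  emitting conformations from two analytic modes: a breathing mode (radial
  scaling sets Rg) and a fixed random displacement field orthogonalised
  against the rigid-body modes (sets the remaining RMSD budget), plus
  per-frame scatter of the target coordinates (default SD 0.08 Å) so each
  basin has a smooth footprint, and small isotropic noise. Infeasible
  centres — an Rg target whose scaling alone exceeds the RMSD target — are
  rejected with the geometry spelled out.
* `make_ideal_structure()` builds full N/CA/C/O backbones from ideal bond
  lengths/angles at requested dihedrals (NeRF-style chain construction):
  a canonical α-helix (−57°, −47°), an antiparallel hairpin whose strands
  (−139°, 135°) are joined by a type II′ turn, an irregular coil, or
  arbitrary per-residue dihedrals (used to plant a helix switch at chosen
  residues). Test sizes: correlated recovery at 125 residues × 10⁴ frames
  (the scale of a small β-sandwich domain); basin recovery over 20 seeds
  per layout at 10⁴ frames; study-level tests at 60 residues × 25 frames.

What passing these tests shows — and does not show. The generators produce
Gaussian, stationary, protein-shaped-but-not-protein data: recovery there
demonstrates the estimators are implemented correctly and are unbiased
under their own assumptions. It does not certify behaviour on real MD data
with anharmonic wells, slow conformational drift, or solvent artefacts; the
convergence diagnostics exist precisely because real sampling can fail in
ways synthetic data cannot.

## Numerical choices and degenerate inputs

Collinear coordinate sets make the optimal rotation non-unique and are an
error in `kabsch()`. Constant reaction coordinates cannot be binned and are
an error in `fel()`. A zero-variance PC projection has undefined cosine
content and is defined as 0 with a warning. DCD output is single-precision
by format, so round-trips are exact only to ~1e-5 Å; multi-model PDB
round-trips hold to the format's three decimals (≤1e-3 Å). Altloc atoms
collapse to the highest-occupancy copy; insertion codes are rejected
outright rather than renumbered. XTC is not read — no reader exists in this
package's dependency set — and the error says so.

## Known limitations

* DSSP boundary calls (G vs T at helix ends) differ from other
  implementations on ~1–2% of residue-frames.
* Basin counts depend on binning; report the sensitivity table alongside
  any count.
* The region-extraction rule for DCCM differences is this package's
  documented convention, not a reconstruction of any published rule.
* Replicate pooling (average vs concatenate) changes numbers; both modes
  exist, and reports state which was used.
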