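---
title: "Methods: antibody flexibility analysis with mabflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody flexibility analysis with mabflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabflex)
```

## The problem

An IgG1 antibody is three globular domains — two antigen-binding Fabs and
one Fc — tethered by a flexible hinge. Molecular-dynamics ensembles of such
molecules do not converge in RMSD terms: the hinge leaves at least four slow
degrees of freedom (a latitude θ and a longitude ϕ per Fab), so the
informative summaries are orientational. `mabflex` implements the analysis
layer for this problem: per-frame Fab orientation angles in a frame anchored
to the Fc, Y/T-shape classification, reweighting of accelerated-MD (aMD)
ensembles onto a (θ1, θ2) free-energy surface, minimum-energy frame
selection, and the secondary descriptors (CH2 opening, glycan geometry,
contacts, hydrogen bonds, torsions, GROMOS clustering, essential dynamics)
computed over that minimum-energy set.

## The Fc-anchored frame

For every trajectory frame the reference frame is rebuilt, because it is
jointed to the moving Fc:

* **origin** — centroid of the hinge Cα atoms. The hinge is the physical
  pivot of the Fab arms, and its centroid is the most frame-stable point
  available without fitting.
* **z** — dominant principal axis of the Fc atom cloud (largest-eigenvalue
  eigenvector of its coordinate covariance). The sign is fixed so z points
  from the Fc centroid toward the hinge origin. We deliberately do **not**
  orient z toward the instantaneous Fab centroid: when both Fabs dip just
  past the equatorial plane (θ slightly above 90°, exactly the T-shaped
  region of interest) a Fab-centroid rule flips the axis and corrupts θ,
  whereas the Fc-to-hinge direction is stable for all θ up to 180° and
  still points toward the side of the molecule the Fabs occupy.
* **x** — the vector joining the CH2-domain centroids (A to B),
  orthogonalized against z and normalized. If that vector is numerically
  parallel to z (within 1e-6 relative), the geometry is degenerate and the
  code raises an error rather than guessing.
* **y = z × x**, completing a right-handed orthonormal triad.

Each Fab direction is `v = Fab Cα centroid − origin`; then
θ = acos(v·z/|v|) and ϕ = atan2(v·y, v·x), reported in degrees
(θ ∈ [0, 180], ϕ ∈ (−180, 180]). Using the domain centroid rather than a
fitted Fab long axis matches the latitude/longitude picture of *where the
Fab is*, not how it is internally oriented. Both choices where the source
description was open (centroid vs specific residues; wrapped vs cumulative
Δϕ) are exposed: `compute_delta_phi()` reports wrapped shifts in
(−180, 180] by default — consistent with reading "shifts of at least 100°"
off a wrapped distribution — with `cumulative = TRUE` available.

A frame is **T-shaped** when both θ ≥ 85°, **Y-shaped** when both < 85°,
and **asymmetric** otherwise. The 85° default reflects that the one fully
crystallized human IgG1, a T-shaped structure, has both θ above 90°, with
margin for thermal spread; it is a tunable argument.

## aMD reweighting

Dual-boost aMD adds a boost ΔV ≥ 0 to the potential wherever it lies below
a threshold, flattening basins. Boost parameters follow the standard
prescription from short conventional-MD averages: `EthreshD = DIHED +
4·(solute residues)`, `alphaD = (4/5)·(solute residues)`, `EthreshP =
EPTOT + 0.16·(atoms)`, `alphaP = 0.16·(atoms)`, all kcal/mol
(`compute_amd_params()`).

Because the boosted ensemble samples p·exp(−βΔV), unbiased statistics are
recovered by weighting each frame with exp(+βΔV). Exact exponential
weights amplify noise catastrophically, so `reweight_fes()` uses the
truncated Maclaurin expansion Σₖ (βΔV)ᵏ/k! to order `k_max = 10`. At
βΔV ≤ 3 the truncation bias on the PMF is below 1e-3 kcal/mol (the series
is within 0.03% of the exponential); a diagnostic warns when the largest
βΔV pushes the truncated series more than 1% away from exp(βΔV).

Weighted (θ1, θ2) histograms use 2.5° bins over [0, 180] by default — fine
enough to resolve the 85° shape threshold while keeping of order a hundred
frames per occupied bin at n ≈ 10⁴–10⁵. The PMF is −kT·ln p, shifted so the
occupied-bin minimum is exactly 0; empty bins carry +Inf and are excluded
from normalization and the minimum search. kT uses T = 300 K
(0.5961 kcal/mol) unless a temperature is supplied with the boost record.
`select_min_energy_frames()` returns every frame whose bin has
PMF < 0.5 kcal/mol; the cutoff is the conventional "minimum-energy region"
threshold and the set is never empty for a positive cutoff. Each grid also
carries the Kish effective sample count per bin ((Σw)²/Σw²), the honest
measure of local statistical support under non-uniform weights.

## Clustering and essential dynamics

`rmsd_matrix()` computes all-pair minimal RMSD after Kabsch superposition
(via bio3d's least-squares fitting) over Cα atoms for protein clustering or
glycosidic oxygens for glycan clustering. `gromos_cluster()` then applies
the neighbour-counting algorithm: the frame with the most neighbours within
the cutoff becomes a cluster medoid ("central member"), it and its
neighbours are removed, and the count repeats up to `max_clusters`
(defaults mirror the study protocol: 0.75 nm/15 for conventional MD,
0.65 nm/10 for aMD, 0.1 nm/10 for glycans). Remaining frames stay
unassigned (id −1). Ties in the neighbour count break toward the lowest
frame index, making the procedure fully deterministic — a choice the
original algorithm leaves open.

`essential_dynamics()` superposes frames on the mean structure (fit to
frame 1, recompute the mean, fit once more), forms the 3N Cα coordinate
covariance with 1/N normalization and diagonalizes it. No mass weighting is
applied (plain Cα coordinates); superposition can be disabled.
`filtered_delta_phi()` reconstructs the trajectory keeping only one mode's
motion (mean + projection × eigenvector), restricts it to the
minimum-energy frames and recomputes Δϕ — the test of whether a single
collective mode carries the Fab rotation. ED superposition about the
iterated mean (rather than frame 0) was chosen because the covariance is
defined about the mean; the option is localized in one place.

## Descriptors

* **CH2 opening** — distance between the Cα atoms of the two glycosylated
  Asn residues. The Cα (not side-chain) choice avoids atoms perturbed by
  the glycosidic bond.
* **Glycan minimum distance** — per-frame minimum over all heavy-atom pairs
  between the two chains (fucose included among "heavy atoms").
* **Glycan centre-of-mass displacement** — frames are superposed on the Fc
  Cα atoms onto the first analyzed frame; the descriptor is each chain's
  CoM distance from its reference-frame position. The reference is frame 0
  of the analyzed (minimum-energy) subset; this choice is recorded in the
  output metadata since "displacement of the chain relative to itself" is
  ambiguous about the anchor.
* **Contacts** — per light-chain C-terminal residue, per frame, the number
  of heavy-atom pairs within 0.4 nm of the hinge group (pair counts, not
  binary occupancies).
* **Hydrogen bonds** — geometric criterion: donor–acceptor ≤ 0.35 nm and
  D–H···A angle ≥ 120° (the Baker–Hubbard-style convention of the common
  trajectory tools); donors are inferred from H atoms covalently bound to
  N/O/S in the first frame. Both thresholds are arguments. Frequencies are
  per (donor residue, acceptor residue) pair over the analyzed frames.
* **Glycosidic torsions** — φ/ψ per linkage from user-named atom quadruples,
  with the fraction of frames inside a supplied reference range. Torsions
  use the IUPAC sign convention (positive clockwise viewed along the
  central bond), matching bio3d.

Units are nm and degrees throughout; file coordinates (PDB/DCD, Å by
convention) are scaled on input.

## The synthetic generator

No trajectories are distributed with the source study, so validation runs
on `generate_toy_mab()`: a pseudo-atomic antibody (hinge whose centroid is
exactly the origin, an Fc column whose principal axis is exactly z, CH2
blobs and glycosylated-Asn markers at a prescribed separation, two
collinear-atom Fab arms placed at prescribed (θ, ϕ), two glycan chains
rooted at the Asn positions, light-chain C-terminal residues breathing near
the hinge, and optionally an explicit donor–H/acceptor triplet hydrogen
bonded in an exact fraction of frames). Ground truth (angles, shape labels,
CH2 distances, H-bond occupancy) is emitted beside every ensemble, and
every frame can be wrapped in a random global rotation + translation to
exercise equivariance. Because arms are placed analytically, the geometry
round-trip is exact to machine precision, which is why the angle-recovery
tests can demand 1e-6°.

`generate_boosted_samples()` draws (θ1, θ2) from p₀·exp(−βΔV) by rejection
sampling, where p₀ is a truncated-normal mixture and ΔV a bounded Gaussian
bump (defaults keep βΔV ≤ 3, inside the validated Maclaurin radius). The
unbiased per-bin probabilities have a closed form
(`analytic_bin_pmf()`, products of normal CDF differences), giving an
exact reference PMF. Rejection sampling was preferred over MCMC for
exactness at toy scale; the sampler aborts below 0.1% efficiency.

The four study-condition presets (`toy_study_presets()`) pin the mixture
weights and CH2 laws to the reported behaviour of the fucosylated and
afucosylated κ and λ systems: 30% both-T for the fucosylated κ form, ~50%
both-Y for its afucosylated form, Y-preferring λ forms, CH2 medians
3.1/4.8/3.7/4.1 nm, fucosylated glycans parked inside the Fc cleft.
Where only a qualitative statement was available (the λ both-T levels, the
CH2 spreads), a single realistic value was fixed (both-T ≈ 12%,
sd 0.5–0.6 nm) and not revisited.

What the toys deliberately do **not** emulate: atomistic packing,
force-field energetics, solvent, correlated domain motions, or realistic
glycan conformers. Passing tests therefore demonstrate the correctness of
the *analysis operators* — frames, angles, weights, clusters, modes — not
the realism of any simulation.

## Numerical choices and problem sizes

* Degenerate inputs error loudly: empty selections, CH2 vector parallel to
  z, Fab centroid on the origin, boost/angle length mismatches, cutoffs
  ≤ 0, missing hydrogens for H-bond analysis.
* Angle wrap-around uses the half-open convention (−180, 180]; the
  reference frame of a Δϕ series is exactly 0.
* Replica merging keeps per-frame provenance and excludes a configurable
  number of leading equilibration frames per replica; with three replicas
  of 10,000 frames and a 3,000-frame exclusion the analysis ensemble is
  exactly 21,000 frames.
* Test and script problem sizes were chosen so the statistics are sharp at
  desk scale: 10⁴ frames for shape-fraction recovery (3σ binomial bands),
  5×10⁴ samples for PMF recovery (0.2 kcal/mol on bins with ≥100 effective
  samples), ≤50-frame systems for the exhaustive clustering and descriptor
  oracles.

## Known limitations

* XTC trajectories are not read; inputs are PDB (multi-model) and DCD, the
  formats the underlying bio3d reader supports.
* The GROMOS medoid is the neighbour-richest frame, not the minimizer of
  intra-cluster mean RMSD; the two differ for stretched clusters.
* RMSD matrices after independent pairwise superposition can violate the
  triangle inequality; this is inherent to the definition and documented
  rather than corrected.
* H-bond donor inference requires explicit hydrogens and element symbols in
  the topology.
* The Maclaurin-reweighted PMF is biased where βΔV exceeds the validated
  radius; the diagnostic flags this but cannot repair it.
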