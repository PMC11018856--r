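---
title: "Analysing protein-crystal MD ensembles with xtalmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing protein-crystal MD ensembles with xtalmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalmd)
```

## The problem

Molecular-dynamics simulations of protein *crystals* sit between two
worlds: they must reproduce the crystallographic observables (lattice
geometry, B-factors, ordered water) well enough to be compared with
diffraction data, while also revealing the equilibrium conformational
motions that crystallography averages away. The model system this
package is built around is a small single-domain protein (a PDZ domain)
in a C121 (C2) crystal: a C-centred monoclinic cell with four
symmetry-related chains, simulated as a 3 × 3 × 3 supercell so that each
unit cell is surrounded by independent neighbours — 108 chains, each an
independent sample of the same molecule in the same environment.

xtalmd implements the analysis layer for such simulations: lattice
mathematics and disorder metrics, structural-accuracy and equilibration
diagnostics, water-site tracking, dihedral/distance featurization with
linear projections, Markov state models, and free-energy/entropy
analysis of a loop-opening coordinate. It deliberately does *not* run
MD; trajectories come from outside (multi-model PDB input is supported)
or from the package's own synthetic generator.

## Lattice model

A `unit_cell(a, b, c, alpha, beta, gamma)` fixes the Cartesian frame by
the monoclinic standard — **a** along x, **b** along y, **c** in the x–z
plane — because crystallography only defines the cell up to an
orthogonal transformation and every downstream quantity (the ac-plane
disorder projection in particular) needs one concrete frame. The C121
operator set is hard-coded and test-verified for group closure;
a trivial P1 registry entry exists for single-chain work. The supported
cell for the PDZ-domain study is a = 65.30 Å, b = 39.45 Å, c = 39.01 Å,
β = 117.54°.

`build_supercell()` places symmetry images cell-major/operator-minor and
records every chain's lattice site (cell index, operator, ideal centre
of mass). That bookkeeping is fixed at construction time: chains in a
stable crystal vibrate about their sites by an ångström or two and never
migrate between sites, so no nearest-site reassignment is attempted.

`inverse_lattice_transform()` undoes each site's transform for the
mass-weighted heavy-atom centre of mass of each chain and frame. The
reference point is recovered *exactly* by back-transforming the stored
ideal site centres rather than being estimated from the first frame:
estimating it from a noisy frame couples the reference error into every
displacement and visibly biases the disorder amplitude on small
supercells. If per-frame box matrices are attached to the ensemble they
are used for the Cartesian-to-fractional step (anisotropic pressure
coupling reshapes the box in NPT crystal simulations); the displacement
is always expressed in the reference cell's Cartesian frame.

The *disorder amplitude* is the mean displacement magnitude over chains
and frames. For independent per-axis Gaussian rigid-body noise σ_rb the
expectation is the 3-D Maxwell mean 2√(2/π)·σ_rb ≈ 1.596 σ_rb, which is
the basis of the generator round-trip test. With spatially *correlated*
internal noise the chain centre of mass genuinely wanders beyond the
rigid-body term (a correlated field does not average out 1/√N over
atoms), so the rigid-body recovery test is run with independent internal
noise; on realistic parameters the correlated contribution adds a few
per cent, which is physics, not estimator error.

## Structural and equilibration metrics

All alignment-dependent metrics share one Kabsch superposition (proper
rotations only; near-collinear selections are rejected). RMSD time
series are reported as mean ± between-chain SD per frame with a
trailing-window mean (default trailing fraction 0.2, generalizing a
"last 1 μs" reporting window to arbitrary trajectory lengths); per-residue
MSD is Cα-based and averaged over chains and frames. The
ensemble-average structure is computed by the standard iterative
superpose-and-average loop to a 10⁻⁶ Å mean shift.

The native-contact fraction Q uses the common hard-cutoff definition —
heavy-atom pairs under 4.5 Å between residues at least 4 apart,
preserved when the instantaneous distance is within 1.2× the reference —
with all three parameters exposed, since published Q variants differ in
exactly these constants.

B-factors are B = (8π²/3)·RMSF² per Cα. `mode = "lattice"` superposes
each *whole supercell frame* once onto the reference lattice, so chain
rigid-body motion contributes; `mode = "chain"` superposes each chain
onto its own iterative mean, isolating internal motion. Whole-supercell
(rather than per-unit-cell) alignment is the deliberate choice for the
lattice mode: it treats the supercell as the crystallographic object
whose disorder is being measured. Two small-sample caveats are inherent
to the definitions and matter for tests: any least-squares fit removes
6 of the 3N degrees of freedom (≈ (1 − 6/3N) shrinkage, <2% for the
atom counts used), and the global fit removes the mean of the per-chain
rigid displacements (a 1/n_chains effect, negligible at 108 chains but
25% at 4 — the B-decomposition round trip therefore runs on the full
supercell).

`equilibration_check()` encodes the two necessary equilibrium conditions
as deterministic verdicts: (i) per replica, the least-squares slope over
the trailing window must lie within 2 block-bootstrap standard errors of
zero; (ii) all pairwise differences of trailing-window means must lie
within 2 pooled standard errors. The 2-SE thresholds are this package's
quantification of conditions that are usually stated qualitatively; the
moving-block bootstrap (block length ≈ √w) absorbs the autocorrelation
that would otherwise make the SEs optimistic.

## Covariance distance decay

After per-chain superposition, the scalar covariance
C_ij = ⟨Δr_i·Δr_j⟩ of Cα displacements is pooled over chains and frames,
binned in 2 Å distance shells, and fitted with A·exp(−d/ℓ). The scalar
(trace) contraction is used because the tensor contraction behind
published covariance-decay plots is rarely stated; a correlation-matrix
normalization is available from the returned covariance matrix.

The fit deserves its own paragraph. Least-squares superposition acts, to
first order in the displacements, as the orthogonal projection P onto
the complement of the six rigid-body modes, so the *observable*
covariance is P K Pᵀ, not the underlying kernel K. Fitting A·exp(−d/ℓ)
directly to the binned post-superposition covariances therefore
underestimates ℓ systematically (in controlled experiments a true
ℓ = 11 Å comes back as 5–8 Å). The default estimator instead evaluates
the model kernel through the projection built from the mean coordinates
— profile least squares over ℓ with A solved linearly, bins weighted by
their pair counts — which recovers the injected decay length to within a
few per cent. The naive direct fit is always computed and reported next
to it. Degenerate inputs (no positive bin mean: independent noise) are
flagged, and a fit whose amplitude is within twice the residual spread
is marked `degenerate` rather than trusted.

## Water sites

Ordered-water tracking follows the local-alignment idea: each
crystallographic water site is anchored to the protein heavy atoms
within 4.0 Å in the reference (at least 3 anchors, else the site is
flagged and excluded); per frame the anchors are superposed onto their
reference positions and the inverse transform carries the site into the
frame; the site is occupied when any water oxygen lies within 1.4 Å
(minimum-image if box vectors are supplied). A site is *preserved* when
its occupancy is ≥ 0.5. All four constants are configuration, not
doctrine — published water-tracking criteria differ, and the exact
thresholds of the reference method live in its own paper — so they are
exposed with these defaults. Preservation is summarised overall, per
replica, and per experimental-B-factor bin (well-ordered, low-B sites
are expected to survive simulation more often).

## Featurization and projections

`compute_dihedrals()` produces IUPAC-convention φ/ψ/χ1/χ2 from the
standard atom quadruples, with undefined angles (termini, short side
chains, collinear atoms) explicitly `NA`. `featurize_sincos()` encodes
fixed Ramachandran and Janin residue sets as (sin, cos) pairs —
residue-major, angle-major, sin before cos, the order serialized in the
feature labels so projections are reproducible — giving the documented
(93 + 60) × 2 × 2 = 612-dimensional vector for a 95-residue chain.
`featurize_ca_distances()` produces all n(n−1)/2 Cα pair distances with
an exclusion list for disordered tails.

PCA is plain mean-centred `prcomp`. LDA standardizes every feature by
its pooled within-group variance first (features with zero within-group
variance fall back to the global variance and are flagged) and ranks
features by absolute discriminant coefficient. Two practical notes,
both visible in the tests: discriminant coefficients are only stable
when samples comfortably exceed features (the synthetic force-field
separation check uses 1000 samples/group for 48 features; the real
study's ratio was far larger still), and when two rotamer wells are
symmetric about zero their cosine features are identical
(cos(±60°) = ½), so the discriminating signal lives entirely in the sine
features.

Rotamer tables bin χ1/χ2 into g+ = [0°, 120°), t = [120°, 180°] ∪
(−180°, −120°), g− = [−120°, 0°) — bin boundaries chosen here, since the
underlying plots never define them — ignoring backbone dependence, and
are compared by total variation distance. External reference tables
(e.g. a survey of high-resolution structures) are accepted as plain
tibbles with the same columns.

## Markov state models

Microstates come from seeded k-means on projected coordinates (external
2-D embeddings such as UMAP are consumed as inputs, never computed);
assignment is nearest-centre with ties to the lowest index.
Transition counting is sliding-window at lag τ, never across trajectory
boundaries; chains of a supercell are treated as independent
trajectories. Estimation is non-reversible maximum likelihood (row
normalization) by default — reversibility is an assumption, not a given,
for a relaxing crystal — with a `(C + Cᵀ)/2` reversible option that
provably satisfies detailed balance. States with no outgoing counts are
trimmed and reported; a count graph with multiple closed communicating
sets is an error naming the components, with one deliberate exception: a
purely diagonal count matrix (no observed transitions at all) estimates
the identity chain and returns infinite implied timescales with a
warning, because that is the informative answer for a too-short
trajectory rather than a modelling error.

Implied timescales t_i(τ) = −τ/ln λ_i(τ) are scanned over lags with a
relative-change flatness diagnostic for lag selection. Coarse-graining
is crisp spectral lumping: k-means on the rows of the leading n_macro
right eigenvectors, a documented simplification of PCCA+ membership
optimization that reproduces the macrostate assignment on metastable
systems (which is what populations and slowest-timescale summaries
need); the macrostate transition matrix is re-counted on the lumped
trajectories at the same lag when they are available. Model selection
uses a trajectory-wise cross-validated sum of the leading m held-out
transition-matrix eigenvalues (m = 2 by default, matching the binary
relaxation processes probed here); the score is bounded by m, approaches
m for metastable systems and 1 for i.i.d. noise.

## Loop thermodynamics

The loop coordinate is a residue-pair Cα distance (no alignment —
internal coordinates are superposition-free). Distributions use 50
uniform bins on [2, 18] Å (bin width 0.32 Å) with standard errors from
bootstrap resampling of *whole chains*, because frames within a chain
are autocorrelated while chains are approximately independent samples;
the SE scaling test verifies the expected 1/√n_chains behaviour. The
free energy is G = −ln p in kBT (empty bins undefined, not zero;
δG = δp/p), optionally in kcal/mol at T = 289 K, the crystal-simulation
temperature anchor. Shannon entropy is the literal histogram sum
−Σ p ln p in nats; its ceiling at 50 bins is ln 50 ≈ 3.91, so entropy
values are only comparable at a fixed binning (the bin count is carried
on the result). Note that published entropy values for such coordinates
sometimes exceed this ceiling, which signals a different estimator
scale; the histogram-sum definition implemented here is the one the
formula states.

Default state intervals — closed < 6.5 Å, intermediate [6.5, 10) Å,
open ≥ 10 Å — are a transparent fallback for states that are properly
derived from embedding-space clustering; pre-assigned labels are
accepted as the faithful mode. Populations equal integrated histogram
masses exactly when state boundaries coincide with bin edges; with the
default 0.32 Å grid the 6.5/10 Å boundaries do not, so that identity is
only exact for edge-aligned rules.

## Deviation profiles and functional comparison

The thermal deviation profile samples unordered structure pairs
uniformly with replacement (self-pairs excluded), superposes each pair
on all shared Cα, and averages |Δr| per residue; full enumeration on
small ensembles is the test oracle, and 2000 pairs reproduce it to
Monte-Carlo accuracy. The ligand-induced profile superposes each holo
structure onto its apo partner on explicitly *mapped* residues —
the mapping is a supplied table, never an implicit sequence alignment,
because silent alignment errors are worse than a little bookkeeping —
and averages per reference residue over the pairs covering it, reporting
coverage and never coercing missing residues to zero. The two profiles
are compared by Pearson correlation over shared residues.

## The synthetic generator

`synth_crystal_trajectory()` is first-class, tested code, not a test
fixture: it generates the data every recovery claim is measured on.
Per frame and chain it adds (i) an independent rigid-body translation
N(0, σ_rb² I); (ii) internal displacements from a Gaussian field with
covariance σ_int²·exp(−d_ij/ℓ) realized through a Cholesky factor of the
template kernel (templates are kept ≤ 500 atoms so the factorization is
trivial); (iii) optionally, a hidden two-state Markov loop process that
places a marker residue so that a chosen residue-pair distance follows
N(μ_state, σ_d²); and (iv) optional water molecules tethered to the same
≥ 3-atom anchor sets the tracker uses, present per frame with
probability q, riding the rigid motion plus the mean displacement of
their anchors. Water sites are placed at least 3.5 Å apart so each is a
distinct density peak. All draws hang off one seed; identical specs are
bit-reproducible.

Defaults are the study conditions: the C121 cell above, a 3 × 3 × 3
supercell, σ_rb = 1 Å per axis (disorder amplitude ≈ 1.6 Å), σ_int =
0.5 Å per axis (B_chain ≈ 20 Ų), ℓ = 11 Å, loop switching probabilities
p01 = 0.02 / p10 = 0.08 per frame (stationary 0.8/0.2) between means
5.4 and 12 Å (inside the observed 4–15 Å range) with σ_d = 1 Å, frames
10 ns apart. One deliberate inconsistency is worth knowing about: a
measured lattice amplitude of ~1.6 Å and a measured B_lattice − B_chain
of ~4 Ų cannot both arise from one Gaussian σ_rb (the former implies
σ_rb ≈ 1 Å, the latter ≈ 0.4 Å); in real crystals the amplitude is
dominated by non-Gaussian symmetry-melting offsets between chain
subsets. The generator is Gaussian by design, follows the amplitude, and
reports the B-difference as its own internally consistent quantity.

What the generator does **not** emulate — and therefore what passing
round trips do and do not show — matters: there is no excluded volume or
force field, no solvent, no anisotropic box breathing, no coupling
between chains, and the loop process moves one residue along a fixed
axis. Recovery of σ_rb, ℓ, q, π and t₂ demonstrates that the estimators
are unbiased and correctly scaled on data with exactly the assumed
structure; it does not certify force-field accuracy or convergence of
any real simulation, which is precisely why the equilibration
diagnostics exist as a separate, assumption-free check.

## Numerical choices and degenerate inputs

Tolerances: fractional/Cartesian round trips are exact to 10⁻¹⁰;
the iterative mean stops at a 10⁻⁶ Å shift (100-iteration cap, then an
error with the last shift); eigenvalue degeneracy at a PCCA cut is
refused at 10⁻¹⁰; stationary distributions are renormalized leading left
eigenvectors with non-negativity enforced by modulus. Ties in k-means
assignment go to the lowest centre index; macrostates are relabelled by
first appearance so runs are comparable. Collinear dihedral quadruples
yield NA, never silent zeros; all-zero distributions, empty contact
sets, empty displacement tables and single-frame B-factor requests are
errors, not NaN propagation.

Problem sizes in the shipped tests and acceptance script were chosen so
each round trip has comfortable statistical margin at its stated
tolerance — 10⁴ chain-frames for the 2% amplitude check, 4 × 400
chain-frames of a 60-residue template for the 10% decay-length check,
the full 108-chain supercell for the 5% B-decomposition check (see the
1/n_chains effect above), 10⁶ frames for the 5% timescale check, 10³
frames for binomial water-occupancy recovery — and the whole suite runs
in about a minute.

## Limitations

Only C121 and P1 are registered (the registry is extensible but an
arbitrary space-group library is out of scope); anisotropic B-tensors,
structure-factor and diffuse-scattering computation are not attempted;
UMAP embeddings are inputs, not outputs; Bayesian MSM uncertainty and
hidden Markov models are not provided; and the interval-based loop
states are a stand-in wherever a proper embedding-space clustering is
available.
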