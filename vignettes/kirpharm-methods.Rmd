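---
title: "Methods: dynamic pharmacophores, WHAM free energies and dose-response analysis for Kir6 inhibitor discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic pharmacophores, WHAM free energies and dose-response analysis for Kir6 inhibitor discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirpharm)
```

`kirpharm` implements the computational stages of a structure-based pipeline
for finding blockers of Kir6.x (KATP) potassium channels: trajectory-based
interaction analysis of a probe ligand (rosiglitazone-like thiazolidinedione)
bound near the PIP2/gating interface, dynamic pharmacophore modelling over an
MD snapshot ensemble, common-hits-approach (CHA) virtual screening,
umbrella-sampling free-energy profiles, and Hill-equation analysis of
patch-clamp fractional-block data. This vignette records the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Trajectories and geometry

Trajectories are multi-model PDB files (MODEL/ENDMDL blocks, Angstrom,
1-based residue numbers) plus a YAML-style selection config declaring the
ligand and PIP2 atoms, the ligand bond list and atom typing, the fragment
decomposition, and the frame spacing `dt` in ns. Multi-model PDB was chosen
as the smallest standard format every structure toolkit reads; parsing goes
through `bio3d`, with a pre-scan that reports a frame whose atom count
deviates by model index. Residue numbering follows the channel's own
labels (e.g. PHE76, VAL172 on chains A/D); configs must declare numbering
explicitly rather than renumber.

Ligand RMSD superposes each frame on a reference by a least-squares rigid
(Kabsch/SVD) fit over a *fit selection* and measures an *analyze selection*,
both in Angstrom. Which atoms define the fit is genuinely open (a protein
fit measures pose drift in the site; a ligand fit measures conformational
drift), so both selections are explicit arguments rather than a hidden
convention. Fits need at least three atoms; the estimator is exactly
invariant under rigid transforms of a frame when the selections coincide
(property-tested against `bio3d::rmsd`).

Buried interface area is `(SASA_ligand + SASA_receptor − SASA_complex)/2`
in nm². SASA is Shrake–Rupley with a deterministic Fibonacci sphere lattice,
960 points per atom and a 1.4 Å water probe by default, with Bondi-style
van der Waals radii from a bundled element table; an isolated atom
reproduces `4πR²` to well under 1% and the estimate moves by less than 2%
when the point count doubles. The point set is deterministic so results are
bit-reproducible; a point on an exactly touching neighbour sphere counts as
buried only when strictly inside, which makes the two-sphere overlap limit
behave as the geometric limit (each coincident sphere keeps a hemisphere).

## Interaction perception

Per-frame ligand features use the five-kind vocabulary H (hydrophobic), AR
(aromatic), HBD/HBA (H-bond donor/acceptor) and PI (positive ionizable).
Feature placement is fully determined by the config's atom typing — aromatic
ring membership, apolar carbons, donor/acceptor heavy atoms, protonatable
nitrogens — never by on-the-fly protonation or aromaticity prediction:
determinism and testability outweigh convenience here. AR features sit at
ring centroids (rings found as cycles of the declared aromatic atoms in the
bond graph; requesting ring perception without a bond list is an error) with
the SVD plane normal; H features at centroids of bond-connected apolar
clusters; HBD/HBA/PI on their heavy atoms.

The geometric detection rules are conventional interaction-geometry
defaults, configurable per call, and documented as this package's
conventions rather than reference values:

| rule | default |
|---|---|
| H: apolar C to apolar C | ≤ 4.5 Å |
| AR–AR: centroid distance / normal angle | ≤ 5.0 Å / ≤ 30° |
| HB: heavy-atom distance / D–H...A angle | ≤ 3.5 Å / ≥ 130° (angle skipped without explicit H) |
| PI: charged N to anionic O | ≤ 5.6 Å |
| feature tolerance radius r_tol (all kinds) | 1.5 Å |

The receptor scope for interaction maps is protein + PIP2; membrane lipids
(POPC) and waters are excluded, matching how such maps are conventionally
restricted to the functionally interpretable partners. Ligand–lipid hydrogen
bonds do occur in membrane simulations, so the scope is an explicit
parameter (`scope = "all"` includes lipid partners) rather than hard-wired.

## Interaction maps, persistence and residence

The interaction map is a fragment × (residue, kind) matrix of
percentage-of-frames values. A frame contributes at most once per (residue,
kind, fragment) cell regardless of how many atom pairs qualify, because the
map reports *presence* frequencies; the exact-recount property (the matrix
equals a naive per-frame recount) and frame-count-weighted merging of two
record sets are both tested. For a rosiglitazone-like ligand the canonical
five-fragment decomposition is the pyridine (RingA), benzene (RingB),
thiazolidinedione (RingC) and the two linkers (LinkerD, LinkerE).

Binding-site occupancy marks a frame bound when the minimum heavy-atom
distance between ligand and site residues is at or below the cutoff
(centre-of-mass distance is available as an option; the criterion behind
published occupation times is typically unstated, and minimum heavy-atom
distance is the more conservative, geometry-robust choice). The default
cutoff is 4.0 Å — display conventions vary between 3.5 and 6 Å, so configs
are expected to be explicit. Residence is the longest contiguous bound run
on the trajectory clock with the fence-post convention that n contiguous
frames at spacing dt span (n−1)·dt; a run over frames at 300–1500 ns is
reported as 1.2 μs.

## Dynamic pharmacophore models and CHA screening

Each frame's model keeps exactly the ligand features participating in at
least one detected interaction in that frame (an option keeps all perceived
features instead; interaction-filtered is the default because the models are
meant to encode how the ligand is actually held). Two frame models are
identical when they share the multiset of (feature kind, involved ligand
atoms); identical models merge into a representative whose feature centers
are the member mean, weighted by frame count. Frames with no interactions
yield an empty-model sentinel excluded from the frequency denominator, and
the denominator is reported alongside the frequencies.

Matching a model against a conformer searches all injective, kind-consistent
feature assignments (exhaustive for up to 6 model features — observed models
carry 2–4; ties break deterministically by lexicographic pairing), rigidly
superposes the paired centers, and declares a match when every pair distance
is within r_tol. The score of a matched assignment is
`s = 1 − mean(d_i/r_tol_i)`. No published formula exists for the
proprietary CHA score, so this package defines the molecule score as
`S = Σ s_m` over matched models: it is a reimplementation convention, not a
claim of bit-compatibility, but it reproduces the published hit-list
structure (a molecule matching 3 of 5 models scores just under 3, one
matching 2 just under 2, and `S ≤ n_active` always). Screening takes the
best score per model over a molecule's conformers (capped at 200 conformers
per molecule, the conventional library-generation limit), filters at
`min_active` matched models (default 2 of 5), and ranks by `S`. Racemic
compounds are screened by pooling both enantiomers' conformers under one
molecule id.

## Umbrella sampling and WHAM

Window input is one two-column series (time, ξ in nm) per window plus a
metadata table of centers and force constants, compatible with common
pull-coordinate outputs; the loader drops the first 10% of each series as
equilibration (a 10 ns window with 1 ns equilibration). Defaults: T = 310 K
with k_B = 0.0083145 kJ·mol⁻¹·K⁻¹ (k_BT ≈ 2.577 kJ/mol), bin width 0.02 nm,
convergence tolerance 10⁻⁶ kJ/mol on the window free energies, iteration cap
10⁵, with an honest `converged` flag.

The WHAM self-consistency equations (see README) are iterated directly on
the histogram grid; bins never visited stay `NA` rather than being
extrapolated. Adjacent windows (ordered by center) that share no histogram
support abort with an error naming the gap, and a histogram-overlap
diagnostic (`window_overlap`, integral of the minimum of two normalized
histograms) warns below 0.05 so intermediate windows can be added. The
profile is anchored at the largest-ξ populated bin — the ligand-in-bulk
reference, so the solvent plateau sits at zero — with `"min"` and numeric
anchors available; absolute well depths depend on this convention and on the
reaction-coordinate definition, so only profile *shapes* (curvatures,
barriers) are treated as recoverable quantities.

Errors are estimated by resampling each window's samples with replacement
(100 resamples by convention) and re-running WHAM on the point estimate's
grid; an explicit seed is required so bands are reproducible. The simple
bootstrap is appropriate for the uncorrelated synthetic samples used in
testing; real pull-coordinate series are autocorrelated, where a block
bootstrap would be needed — a known limitation, not yet implemented. One
consequence of the bulk anchor worth knowing: when the anchor bin itself is
sparsely populated (as in a synthetic harmonic fixture whose largest-ξ bin
holds a handful of samples), the anchor's own noise enters every bin's band
and does not shrink with sample size; the 1/√N scaling check therefore
anchors at the well-populated minimum.

## Dose-response analysis

Fractional block is `1 − I_drug/I_control` from currents at −80 mV (inward)
and +50 mV (outward). The Hill fit fixes the bottom at 0 and the top at 1
(data are normalized to control and not corrected for rundown), estimating
only IC50 and h by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`; IC50 ∈ (0, 10⁴] μM, h ∈ (0, 5], initialized at the
geometric-mean dose and h = 1). Whether published fits weighted replicate
means is typically unstated; the default here fits per-dose means with
inverse-SE² weights (falling back to unweighted when SEs are degenerate,
e.g. noiseless data), with unweighted and all-replicates modes available.
Standard errors come from the fit covariance; noiseless data recover planted
(IC50, h) to 4 significant figures and the fit is scale-equivariant in
concentration. Rectification compares paired outward/inward block with a
two-tailed paired t-test and the index `mean(block_out)/mean(block_in)`;
"rectifying" requires index > 1 at the configured significance (default
α = 0.001, the stringent reporting threshold).

## Synthetic-data generators

All generators are bit-reproducible under (spec, seed) and exist to give
every stage inputs with known ground truth; they make no claim of physical
realism (no force fields, no lipid dynamics, no autocorrelation).

*Ensemble generator.* Five model regimes emulate the observed per-frame
model classes: all regimes share the two hydrophobic ring features, the
dominant regime adds the thiazolidinedione N–H donor, and the minority
regimes vary the polar features (two of them differing only in the involved
ligand atoms). Default probabilities (0.9552, 0.0120, 0.0120, 0.0120,
0.0088) give an expected dominant count of 4,776 of 5,000 frames, mirroring
the published ensemble structure; feature centers carry Gaussian jitter of
0.3 Å, a magnitude that keeps a regime's frames well inside the 1.5 Å
matching tolerance, as per-frame feature scatter in a stable pose should be.
What this does **not** emulate: gradual conformational drift, correlated
frame-to-frame transitions, or frames whose feature sets are perception
borderline — so passing recovery tests show the merging/screening machinery
is correct, not that feature perception on real trajectories is.

*Umbrella windows.* Samples are drawn exactly from the biased Boltzmann
density `p_i(ξ) ∝ exp(−β[U(ξ) + ½k_i(ξ−ξ_i)²])` by inverse-CDF sampling on
a 10⁴-point grid over the declared range, for harmonic, double-well
(`U = a(ξ²−b²)²`) and tabulated potentials. Closed forms (biased variance
`k_BT/(κ+k)`, flat-potential SD `√(k_BT/k)` ≈ 0.0508 nm at k = 1000
kJ·mol⁻¹·nm⁻², T = 310 K) are property-tested. Samples are i.i.d., unlike
real pull-coordinate series.

*Dose-response tables.* Hill-model block plus Gaussian noise (default
σ = 0.03 on the block scale, a typical patch-to-patch scatter for
normalized currents), truncated to the guard band [−0.05, 1.05].

*Screening libraries.* Actives pick a set of representative models (default
2, matching the hit filter) and carry one conformer per chosen model with
features jittered within r_tol/2 under a random rigid transform, so
retrieval is guaranteed by construction. Decoys carry the same feature-kind
multiset with positions fully re-randomized inside the model's spatial
envelope, each at least 2·r_tol from its template position and permuted, so
their internal geometry is random rather than perturbed; chance matches
against a 2-feature model remain possible (a single inter-feature distance
is weakly discriminating — an intrinsic property of small pharmacophores,
not an artifact), but matching ≥ 2 models by chance is rare.

## Problem sizes and test budgets

The test suite exercises: 5,000-frame ensembles for representative-model
recovery; 200 replicates per drug × 4 published (IC50, h) parameter sets at
σ = 0.03 for Hill recovery (within 15% on IC50 and 0.15 on h in ≥ 95% of
replicates); 5-window harmonic and 19-window double-well WHAM fixtures at
5,000 samples/window (curvature within 10%, barrier within 0.5 kJ/mol,
translation invariance to 10⁻⁶, bootstrap bands scaling ≈ 1/√N); 500
random matching instances against an independent Horn-quaternion
exhaustive-permutation oracle; and seeded active/decoy retrieval (all
actives, < 5% decoys). These sizes were chosen as the smallest at which the
statistical assertions have comfortable margins.

## Known limitations

- Perception rules are heavy-atom conventions; without explicit hydrogens
  the H-bond angle test is skipped, which over-detects marginal H-bonds.
- Receptor aromatic rings and apolar/donor/acceptor classes are recognized
  from standard residue and atom names; exotic residues fall back to
  element-based rules.
- WHAM is 1-D only (no 2-D WHAM, no MBAR), and absolute PMF depths depend
  on the anchor convention.
- The CHA score is this package's convention; published proprietary scores
  are comparable in structure, not in value.
- Simple (not block) bootstrap; real correlated series will understate
  error bands.
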