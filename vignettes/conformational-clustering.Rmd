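---
title: "Methods: invariant descriptors and unsupervised conformational analysis of surface-hopping ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invariant descriptors and unsupervised conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namdclust)
```

# Scope and data model

`namdclust` analyses ensembles of nonadiabatic (surface-hopping) molecular
dynamics trajectories.  The on-disk unit is a root directory containing
`TRAJ<k>` subdirectories, each with a concatenated-XYZ geometry series
(`dyn.xyz`, comment lines carrying `time = <t> fs`) and a per-frame property
table (`properties.csv` with canonical columns `State`, `Total_Energy`,
`S1`, `S2`, ..., `DE21`, `Hops_S21`, `Hops_S12`, `Pop1`, `Pop2`), plus a
single-frame reference geometry `geom.xyz` at the root.  Ingestion
inner-joins geometries and properties on the `(trajectory, time)` key with a
1e-6 fs time tolerance; frames present on only one side are dropped with a
message, and a fully empty join is an error.  Units are fixed by convention:
coordinates in Å, time in fs, energy gaps in eV; state and total energies
pass through unchanged (NAMD codes typically print hartree-scale totals next
to eV gaps, and nothing downstream depends on their absolute scale).

The property CSV layout is this package's documented interface rather than
any upstream program's native format: it keeps the pipeline testable with
data generated in code, and adapting a particular dynamics code's output is
a matter of column renaming.

# Invariant descriptors

All descriptors map a geometry to a fixed-length vector that is invariant
under global rotation and translation; this is what makes frames from
independently oriented trajectories comparable.

**Pairwise distances (R2).**  The strict lower triangle of the Euclidean
distance matrix, flattened row-major with stable names `R_i_j` (0-based,
i > j): `n(n−1)/2` features, 66 for a 12-atom molecule.  Variants: `inv_r2`
(`1/R`, Coulomb-matrix-like emphasis on short contacts), `delta_r2`
(`R(t) − R(ref)`), and `re` (`R(ref)/R(t)`), the last two requiring a
reference geometry (typically the ground-state minimum).

**Z-matrix.**  Internal coordinates from a connectivity table in which atom
`i` references a bond partner, angle partner and dihedral partner of lower
index.  The default connectivity is the sequential input-order chain
(`i ← i−1, i−2, i−3`): the choice is arbitrary for an automated pipeline, but
it is deterministic, matches common Cartesian-to-internal converters, and
any user-supplied connectivity is honoured.  Bonds are in Å; angles
([0, 180]) and dihedrals ((−180, 180], right-handed atan2 convention with
`φ = atan2((n₁×n₂)·b̂₂, n₁·n₂)`) in degrees.  `zmatrix_to_cartesian()`
rebuilds coordinates by natural-extension reference-frame placement, and the
round trip reproduces the internal coordinates to better than 1e-8, which is
how the sign convention is pinned down in the tests.

**Delta Z-matrix.**  Differences against a reference sharing the same
connectivity.  Angular differences are wrapped to the smallest signed value
in (−180, 180]; without the wrap, a dihedral crossing the ±180° seam would
produce a spurious ~360° jump and any bounded transform of it would be
discontinuous.  The optional bounded transforms operate on scaled deltas:
bond deltas in Å as-is, angular deltas converted to radians first, so that a
full ±180° swing maps to ±π instead of saturating `tanh` at ±1 already for
a few degrees.  `tanh` maps to (−1, 1); `sig` is the logistic function
`1/(1 + e^{−x})` mapping to (0, 1) with 0.5 at zero change.

**Cremer–Pople ring puckering.**  The ring is translated to its geometric
centre and the unique mean plane is defined through
`R′ = Σ r_j sin(2πj/N)`, `R″ = Σ r_j cos(2πj/N)`; out-of-plane displacements
`z_j = r_j · n̂` then decompose by discrete Fourier sums into amplitude/phase
pairs `(q_m, φ_m)` for `m = 2..⌊(N−1)/2⌋`, plus the single signed coordinate
`q_{N/2}` for even rings — the `N − 3` independent puckering coordinates,
with total amplitude `Q = √(Σ z_j²)`.  For six-membered rings the package
reports the familiar `(Q, θ, φ)` with `cos θ = q₃/Q` and `φ = φ₂`, so chairs
sit at the poles and boats/twist-boats on the equator.  Atom index 1 of the
supplied ring ordering fixes the phase origin `j = 0`.  A planar ring gives
`Q = 0` exactly; an alternating `z_j = (−1)^j δ` ring is a pure-q₃ chair
with `Q = √6·δ`.

**SOAP power spectrum.**  Each atomic environment is the Gaussian-smeared
density of its neighbours of species Z within `r_cut`,
`ρ_Z(r) = Σ_i exp(−|r − r_i|²/(2σ²))`, expanded as
`c^Z_{nlm} = ⟨g_n Y_lm | ρ_Z⟩` in an orthonormal radial basis times real
spherical harmonics, and combined into the rotation-invariant partial power
spectrum `p(Z₁,Z₂,n,n′,l) = π√(8/(2l+1)) Σ_m c^{Z₁}_{nlm} c^{Z₂}_{n′lm}`.
Implementation choices:

- radial basis: the cutoff-normalised polynomial set
  `φ_n(r) = ((r_cut − r)/r_cut)^{n+2}`, orthonormalised through the closed-form
  overlap matrix (`g = S^{−1/2} φ`) — a standard choice for molecular SOAP
  whose cutoff normalisation keeps the overlap matrix well conditioned up to
  `n_max = 8`;
- the angular integral over each neighbour Gaussian is analytic (modified
  spherical Bessel expansion), leaving one radial Gauss–Legendre quadrature
  per `(n, l, neighbour)`; the Bessel factor is evaluated in
  exponentially scaled form so the combined weight is `exp(−a(r − r_i)²)`
  and never overflows;
- defaults `r_cut = 6 Å`, `n_max = 8`, `l_max = 6`, `σ = 0.5 Å` follow
  common descriptor-library practice; `n_quad = 120` makes the quadrature
  error negligible against those parameters;
- aggregation is `averaged` over atomic centres by default, because
  frame-level clustering needs one vector per geometry; `per-atom` output is
  retained as an option.

The implementation is validated against an independent brute-force
product-quadrature of the projection integral and against its invariances
(rotation to 1e-10, same-element permutation exactly).  Note that the
spectrum is *not* invariant to changing `r_cut` itself even when no new
neighbours enter, because the radial basis is anchored to the cutoff; what
holds is that atoms beyond `r_cut` contribute nothing at fixed parameters.

# Preprocessing

Z-score scaling uses the population standard deviation (ddof 0) —
consistent with the per-cluster `std` statistics — and maps constant columns
to 0 with a warning; min–max scaling maps onto [0, 1] (or a requested range)
with constant columns at the midpoint.  Fitted parameters are first-class
objects that can be re-applied to new rows or inverted.  SOAP tables are
deliberately protected: their columns form one coherent spectral series, and
feature-wise rescaling destroys the relative magnitudes that carry the
structural information, so scaling a table tagged `descriptor = "soap"`
requires an explicit `override = TRUE`.

Stride resampling keeps frames whose time stamp is an integer multiple of
the stride (1e-6 fs tolerance), the standard way to thin a 0.1 fs series to
0.5 fs and reduce temporal correlation before embedding; a stride below the
native step returns the table unchanged with a warning rather than failing.
Random subsampling is uniform without replacement behind an explicit integer
seed, preserving row order among kept rows.

# Embedding

**PCA** delegates to `stats::prcomp` (column-centred, unscaled).  Axis signs
are fixed by orienting each component so its largest-magnitude loading is
positive, which makes outputs bit-stable across runs; explained-variance
ratios are reported against the total data variance, so they are
non-increasing and sum to at most 1.

**ISOMAP** builds the k-nearest-neighbour graph (default `n_neighbors = 30`,
Euclidean edge weights), symmetrised by union — the weaker of the two
common conventions, keeping the graph connected more often; this is a
documented implementation choice, not an inference about any reference
implementation.  All-pairs geodesics come from Dijkstra's algorithm
(`igraph::distances`), and classical MDS of the geodesic matrix
(`stats::cmdscale`) produces the embedding; negative MDS eigenvalues are
clamped at zero and their total magnitude is reported as
`meta$residual`.  A disconnected neighbourhood graph is an error naming the
component sizes, since geodesics across components are undefined.

**t-SNE** is an exact (dense) implementation written for this package:
per-point Gaussian bandwidths calibrated to the requested perplexity by
bisection, symmetrised affinities, Student-t output kernel, gradient descent
with momentum (0.5 then 0.8), adaptive per-parameter gains, early
exaggeration (factor 12 for 100 iterations) and 500 iterations by default.
The method is treated as a contract — seeded determinism plus recovery of
planted well-separated structure — rather than a numerical reference;
internal optimiser constants follow the original algorithm's common
defaults.  The O(n²) cost is appropriate for the subsampled table sizes
(≈ 1000 rows) this pipeline targets.

# Clustering and model selection

K-means (k-means++ seeding, Lloyd iterations, 10 restarts keeping lowest
inertia, `tol = 1e-4` on the relative centroid shift, 300 iteration cap) and
the full-covariance Gaussian-mixture EM (k-means initialisation,
`reg_covar = 1e-6` on covariance diagonals, `tol = 1e-3` on mean
log-likelihood) are implemented in-package so that their per-iteration
diagnostics — the inertia trace and the log-likelihood trace — are part of
the returned model and can be asserted monotone, which is the cheapest
strong check that the optimisers are actually correct.  Hierarchical
clustering delegates to `stats::hclust` (Ward `ward.D2` default; average,
complete and single linkage available) with `cutree` at the requested k.
Spectral clustering uses the RBF affinity with `γ = 1/n_features`, the
symmetric normalised Laplacian, the bottom-k eigenvectors row-normalised,
and k-means in the spectral embedding.

Cluster quality is measured by the mean silhouette `(b − a)/max(a, b)` and
the Calinski–Harabasz index `(BSS/WSS)·(n − k)/(k − 1)`; a zero
within-cluster dispersion is guarded with `ε = 1e-12` so perfectly tight
clusters give a large finite value instead of infinity.  Automatic selection
of k (`n_clusters = "best"`) runs the chosen algorithm over the candidate
range, ranks the candidates separately by each metric (higher better) and
returns the k with the smallest summed rank, ties going to the smallest k.
The summed-rank combiner is a declared design choice: it is scale-free (the
two metrics live on incomparable scales), simple to reason about, and
reduces to either metric alone when they agree.  Cluster label identity is
arbitrary; all validation uses the permutation-invariant adjusted Rand
index.

# Post-analysis

RMSD uses Kabsch superposition by default: both geometries are centred and
the optimal *proper* rotation (SVD with determinant correction, so
reflections are disallowed) is applied before
`RMSD = √(mean_i |r_i − r′_i|²)`, unweighted over all atoms.  Superposition
and mass weighting are conventions, not givens, so the unaligned mode is
exposed too (`align = FALSE`); aligned RMSD is never larger than unaligned.
A frame is a hopping geometry iff either direction flag is set; the
forward/backward subsets are also returned because the two hop directions
are usually analysed separately.  Per-cluster statistics report mean, median
and population std per property, with counts, so count-weighted cluster
means reproduce the global mean exactly.

# The synthetic generator: what it emulates and what it does not

`simulate_ensemble()` emulates the *layout and statistical signatures* of a
small surface-hopping ensemble of a fulvene-like molecule (a five-membered
carbon ring with an exocyclic methylene, C6H6, 12 atoms): a harmonic stretch
of the exocyclic C–C bond (default 0.25 Å amplitude, 10 fs period, random
phase per trajectory), an optional methylene torsion oscillation, latent
conformer classes encoded as static torsion offsets (defaults 0/60/120° in
proportions 0.4/0.4/0.2, the rotated class deliberately rarest), hop events
flagged where the noiseless stretch is within δ (default 0.002 Å) of its
per-cycle maximum and alternating in direction with the current state, an
energy gap linear in the stretch (3.8 eV intercept, −6 eV/Å slope, 0.1 eV
Gaussian noise, optional per-class shifts) and isotropic 0.01 Å coordinate
jitter.  Classes are planted with exact largest-remainder proportional
counts, randomly permuted over trajectories, so the realised class structure
matches the configuration even for a dozen trajectories.  Trajectories are
kinematic (closed-form), not integrated dynamics: that gives exact ground
truth and zero numerical drift, at the price of emulating none of the real
features of NAMD data — no anharmonicity, no mode coupling, no momentum
conservation, no physically meaningful hopping probabilities, and
within-class variation far more structured than thermal sampling.  Passing
the pipeline's tests on this generator therefore demonstrates algorithmic
correctness under controlled conditions, not performance on real ensembles.

Default sizes (10 trajectories × 201 steps at 0.1 fs; 12 × 101 and a
300-row subsample in the end-to-end analyses) are desk-scale choices that
keep every analysis in seconds while leaving the per-trajectory structure —
several stretch periods, multiple hop windows — intact.

# Numerical and degenerate-input conventions

- Time matching everywhere uses an absolute 1e-6 fs tolerance.
- Exported CSVs print floats with 6 decimals (write→read round trips are
  the identity to 1e-6); XYZ files print 8 decimals.
- Collinear backbones (dihedral), coincident atoms (angle), collinear rings
  (puckering) and disconnected ISOMAP graphs are errors, not NaNs.
- Constant feature columns scale to 0 (z-score) or the range midpoint
  (min–max) with a warning.
- K-means empty clusters are re-seeded from the farthest point; GMM
  covariances carry a 1e-6 diagonal floor.
- All stochastic steps (subsampling, k-means/GMM/spectral restarts, t-SNE
  initialisation, the generator) take explicit integer seeds and are exactly
  reproducible; fixed config plus fixed seed gives byte-identical CSV
  outputs.

# Known limitations

- The Z-matrix default connectivity is a chain in input order; for branched
  molecules a chemically meaningful connectivity should be supplied.
- Angular "bending" coordinates spanning six atoms (large out-of-plane
  motions) are not implemented; users can append custom columns to any
  feature table.
- SOAP here targets molecules: no periodic boundary conditions, and the
  O(centres × neighbours × quadrature) cost is intended for ≤ a few dozen
  atoms per frame.
- t-SNE is exact O(n²); subsample before embedding tables much beyond a few
  thousand rows.
- The native output dialects of specific dynamics packages are out of
  scope; data reach the pipeline through the documented XYZ + CSV layout.
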