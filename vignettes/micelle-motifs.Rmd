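---
title: "Reconstructing molecular motifs and their dynamics in surfactant micelles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing molecular motifs and their dynamics in surfactant micelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(micellemotifs)
```

Surfactant micelles are dynamic objects: the amphiphiles that build them
continuously reshuffle between structurally distinct regions of the
aggregate, and in bicomponent micelles the two species may intermix or
segregate depending on their interactions and head-group geometry. This
package reconstructs that structural and dynamical organisation directly
from equilibrium molecular-dynamics trajectories, with no prior labelling
of what the "regions" are. The pipeline is entirely unsupervised: a
high-dimensional, symmetry-invariant descriptor of each surfactant's local
environment is clustered by density, and the cluster label time series is
turned into populations, exchange probabilities and species compositions.

This vignette documents the models and algorithms, the parameters that
matter (with units and defaults), the numerical choices, and the
limitations — in particular, what the built-in synthetic trajectories do
and do not share with production-scale simulations.

## The minimalistic coarse-grained micelle model

`sim_config()`, `mcg_pair_table()`, `build_bicomponent_system()` and
`run_simulation()` implement an implicit-solvent Langevin simulator of
five-bead linear amphiphiles: one head bead and four tail beads joined by
harmonic bonds,

$$U_\text{bond}(r) = \tfrac12 k_b (r - r_0)^2, \qquad
r_0 = 0.47\ \text{nm},\ k_b = 1250\ \text{kJ mol}^{-1}\text{nm}^{-2},$$

with all nonbonded interactions described by a Lennard-Jones potential
truncated and shifted to zero at $r_c = 1.2$ nm. Directly bonded (1–2)
pairs are excluded from the LJ sum; 1–3 pairs and beyond interact, which
gives the chain its bending stiffness without explicit angle terms. The
bond constants are typical for this resolution; only the harmonic form is
fixed by the model, and both are exposed in `sim_config()`.

Two surfactant species `R` and `B` share identical tails
($\sigma_\text{tail} = 0.47$ nm, $\epsilon_\text{tail,tail} = 5$ kJ/mol,
intra- and inter-species) — in an implicit-solvent model this strong
tail–tail cohesion *is* the hydrophobic effect. The head–head interaction
matrix is the experimental dial:

| regime | $\epsilon_{RR}$ | $\epsilon_{BB}$ | $\epsilon_{RB}$ | behaviour |
|---|---|---|---|---|
| `mixing` | 0.5 | 0.5 | 0.5 | species fully intermixed |
| `segregating` | 4 | 4 | 0.5 | two single-species domains |
| `intermediate` | 4 | 0.5 | 0.5 | partial segregation |

(all in kJ/mol; head sizes $\sigma_{RR} = \sigma_{BB} = 0.7$ nm for the
equal-size systems, and $\sigma_{RR}/\sigma_{BB} = 0.7/0.47 = 1.49$ for
the size-asymmetric ones). Head–tail pairs take the Lorentz mean
$\sigma$ and, by default, the tail well depth
$\epsilon_\text{head,tail} = 5$ kJ/mol. We verified by direct simulation
that this strong head–tail attraction does *not* invert the micelle — the
corona stays intact, with ~90% of heads outside their own chain-end bead —
it merely packs the head shell tightly onto the core; weakening it to 0.5
kJ/mol instead produces a more loosely wrapped, elongated aggregate whose
descriptor statistics are visibly poorer (the five leading principal
components then capture only ~70% instead of ~81% of the SOAP variance).
The full pair table is user-overridable, so any published interaction
matrix can be dropped in.

Dynamics are NVT Langevin in a cubic 20 nm periodic box at $T = 300$ K,
integrated with the BAOAB splitting at $\Delta t = 40$ fs with
mass-independent friction $\gamma = 1/\tau_t$, $\tau_t = 0.1$ ps. BAOAB
reduces exactly to velocity Verlet as $\gamma \to 0$ (the NVE limit used
by the energy-conservation tests). All bead masses are 72 amu; mass only
sets the time mapping, not equilibrium structure. Thermal noise is drawn
from R's RNG, so a seed makes trajectories bitwise reproducible. Pair
interactions go through a Verlet neighbour list (0.3 nm skin) rebuilt
whenever any bead has moved more than half the skin; the list changes
nothing about the forces, only their cost.

Two numerical caveats worth knowing:

* the *kinetic* temperature reported in the log underestimates the target
  by ~2–3% at $\Delta t = 40$ fs because the stiff bond and tail modes
  bias the full-step velocities (the usual $O(\Delta t^2 \omega^2)$
  discretisation effect); the free-particle thermostat is exact to
  sampling error;
* bead pairs closer than $10^{-6}$ nm (possible only in pathological
  inputs) have their repulsion clamped, with a warning and a count.

`build_bicomponent_system()` offers two initial conditions. The
`random_dispersed` mode scatters whole molecules for self-assembly
studies. The `preassembled_micelle` mode places all heads on a spherical
shell (Fibonacci-lattice directions, tails pointing inward, small
positional jitter, short steepest-descent relaxation) — a fixture that
skips the tens of microseconds of self-assembly that desk-scale runs
cannot afford. Its `arrangement = "janus"` variant additionally
pre-segregates the two species onto opposite hemispheres: the analogous
fixture for segregating interaction regimes, whose equilibrium *is*
compartmentalised but whose on-surface demixing from a random arrangement
is far slower than the assembly itself. Under mixing interactions the
janus arrangement decays quickly, so it biases nothing it should not.

## SOAP descriptors of head environments

For every sampled frame, one descriptor is computed per surfactant,
centred on its head-group centre of mass (`extract_head_centers()`; for
the built-in model the head group is the single bead 0). The neighbour
density around a centre is a sum of Gaussians of width $\sigma_\text{atom}$
on all *other* head centres within $r_\text{cut}$ (minimum image); the
centre does not count itself, so an isolated surfactant has an exactly
zero descriptor. The density is expanded as

$$c_{nlm} = \int \rho(\mathbf r)\, g_n(r)\, Y_{lm}(\hat{\mathbf r})\,
d^3r,$$

on $n_\text{max}$ spherical Gaussian-type radial functions
(decay rates set so basis $k$ falls to $10^{-3}$ at $r_\text{cut}\,k/n_\text{max}$,
Löwdin-orthonormalised) times real spherical harmonics up to
$l_\text{max}$, and compressed into the rotationally invariant partial
power spectrum

$$p_{nn'l} = \pi \sqrt{\tfrac{8}{2l+1}} \sum_m c_{nlm}\, c_{n'lm},$$

keeping the non-redundant $n \le n'$ triangle with a $\sqrt 2$ factor on
off-diagonal pairs (norm-preserving). With $n_\text{max} = 8$,
$l_\text{max} = 8$ and a single species channel the vector has
$9 \times 8 \cdot 9 / 2 = 324$ components. Defaults:
$r_\text{cut} = 30$ Å (micelle-scale neighbourhood),
$\sigma_\text{atom} = 3.5$ Å (of the order of half a head diameter —
smooth enough to be insensitive to thermal jitter, sharp enough to
resolve first-shell structure). Lengths are nm internally; `soap_params()`
accepts Å with an explicit `units` tag because cutoffs are conventionally
quoted in Å.

Two design choices deserve a note:

* **Single species channel by default.** The descriptor is deliberately
  blind to the species label — all heads feed one density channel — so
  clusters are found from *structure alone* and species composition is a
  posteriori information. This is also what the 324-component dimension
  implies. A `per_species` policy (channel per species, crossed blocks)
  is available for completeness.
* **Radial integrals by quadrature tables.** The expansion uses the
  modified-spherical-Bessel addition theorem for a displaced Gaussian;
  the radial integrals $I_{nl}(R)$ are precomputed on a 1201-point grid
  in the neighbour distance $R$ (200-node Gauss–Legendre quadrature,
  exponentially-scaled Bessel functions for stability) and linearly
  interpolated. The table is cached per parameter set. Against a
  brute-force 3-D spherical quadrature of the same integrals the
  coefficients agree to ~$10^{-6}$, comfortably inside the $10^{-4}$
  tolerance the test suite asserts.

`build_soap_dataset()` walks a trajectory (optionally windowed and
strided) and stacks the per-frame spectra frame-major, carrying
(frame, time, centre, species) metadata per row.

## Dimensionality reduction

`fit_pca()` centres the data and eigendecomposes its covariance (computed
as the cross-product of the centred matrix — identical spectrum to a thin
SVD at a fraction of the memory for $10^5 \times 324$ inputs). No
whitening or per-feature scaling is applied to SOAP features. Axis signs
are fixed deterministically (largest-magnitude loading positive) so refits
reproduce. Five components are retained by default; a
`variance_target` picks the smallest sufficient count instead. The
retained-variance bookkeeping is exact, with zero-variance directions of
rank-deficient data reported as ratio 0. When several micelle systems are
compared, the model is fitted on their pooled datasets, so all systems
share one embedding — the cumulative-variance figures quoted for the
analysis refer to that pooled fit.

`twonn_dimension()` estimates the intrinsic dimension of the embedded
manifold from the ratios $\mu = r_2/r_1$ of second- to first-neighbour
distances: under mild assumptions $P(\mu > x) = x^{-d}$, and $d$ is the
slope of the origin-constrained fit of $-\log(1 - F(\mu))$ on $\log\mu$
over the empirical distribution, after discarding the largest 10% of
ratios (the heavy tail is the estimator's known weak spot). Exact
duplicate rows are dropped with a warning.

## PAMM-style density clustering

`pamm_cluster()` works in the retained PCA space (never the raw 324-D
space):

1. **Grid.** `farthest_point_sampling()` picks `ngrid` points by greedy
   max–min selection from a seeded random start — deterministic given the
   seed, and guaranteed to cover low-density regions a random subset
   would miss.
2. **Adaptive anisotropic KDE** (`kde_on_grid()`). Every grid point gets
   a bandwidth matrix from the locally weighted covariance of the data
   around it. The dimensionless `fs` is the *fraction of samples* that
   localises that estimate: the Gaussian locality window around grid
   point $i$ has the width of the distance to the
   $\lceil f_s n \rceil$-th nearest data point. We also evaluated reading
   `fs` as a fraction of the global data spread; in the 5-D embedding
   that collapses the kernels to nearest-neighbour volume (≈ 1 sample
   per kernel), i.e. a noise-level density estimate, which settles the
   ambiguity in favour of the fractional-samples reading. Each local
   covariance is scaled by the Silverman factor
   $(4/(d+2))^{2/(d+4)} n_\text{eff}^{-2/(d+4)}$ of the effective
   localisation count. Each *data* point kernel uses the bandwidth of its
   Voronoi grid centre. Densities are normalised so the Voronoi-weighted
   sum over grid points is exactly 1; near-singular local covariances are
   regularised by relative diagonal loading (counted and messaged).
3. **Quick-shift mode assignment** (`assign_modes()`). Each grid point
   links to the nearest higher-density point among its $k$ nearest grid
   neighbours ($k = \max(16, \text{ngrid}/50)$); link-free points are
   density peaks, their basins the preliminary clusters.
4. **Outlier-basin merging.** Basins holding less than `merge_threshold`
   (default 1%) of the probability mass are merged into the neighbouring
   basin behind their highest saddle (the largest `min(f_i, f_j)` over
   neighbour-graph edges joining the two basins), iterating from the
   weakest basin; the dominant mode is never absorbed. An optional
   significance filter (`z_merge > 0`) additionally merges basins whose
   peak does not rise at least $z$ combined standard errors above that
   saddle, with the KDE log-density error estimated as
   $1/\sqrt{n_\text{eff}}$ from effective kernel sample counts; it is off
   by default because at desk-scale sampling the error model's constants,
   not the data, end up deciding the cluster count.
5. **Classification** (`classify_points()`). Every data point inherits
   the cluster of its nearest grid point; ties break to the lowest grid
   index.

For the optional significance filter, one correction matters with
trajectory data: descriptor rows from frames closer than the
decorrelation time are not independent samples.
`statistical_inefficiency()` estimates the factor
$g = 1 + 2\sum_t \rho(t)$ from the per-surfactant time autocorrelation of
the retained components (variance-weighted across components), and
`pamm_cluster()` divides the effective sample count by it automatically
when the dataset carries frame/centre metadata. For production-style
sampling — frames tens of nanoseconds apart — $g \approx 1$; for the
densely sampled short fixtures in the tests $g$ is 2–20.

When several micelle systems are compared, the PCA embedding is fitted on
their pooled datasets but the clustering runs per micelle on that
micelle's rows: each aggregate gets its own density topology, populations
and diagram, all expressed in one common coordinate system.

## Interconversion diagrams

`label_series()` arranges the per-(frame, surfactant) labels into a
frames × surfactants matrix (surfactants tracked by persistent molecule
id). From it:

* `populations()` — percentage of all (frame, surfactant) cells per
  cluster, i.e. the cluster distribution averaged along the trajectory;
* `transition_counts()` / `conditional_transition_matrix()` — counts of
  label pairs on consecutive frames and their row-normalised conditional
  probabilities $P_{ij} = c_{ij} / \sum_j c_{ij}$ at the lag d*t* set by
  the sampling stride (10 ns in the production protocol). Rows with no
  outgoing events are reported as `NA`, never imputed; the diagonal is
  the residence probability;
* `cluster_composition()` — percentage of each cluster's member cells by
  species;
* `build_interconversion_diagram()` — the bundle of all of the above,
  plus a stationary-flux-imbalance diagnostic
  $|\pi_i P_{ij} - \pi_j P_{ji}|$ (reported, not asserted — a finite
  trajectory need not satisfy detailed balance), serialisable to JSON and
  DOT via `write_interconversion_diagram()`.

Populations and compositions are invariant under frame reordering;
transition matrices of course are not. No multi-lag Markov model is
fitted: the analysis reports exactly the one-lag conditional
probabilities.

## Structural observables

`radial_distribution()` histograms distances from a per-frame reference
point (for micelles: the centre of mass of all tail beads, the core) to a
selection (head beads), normalised by shell volume and mean box density so
an ideal gas gives $g(r) = 1$. `contact_count()` reports the mean number
of A–B head pairs within a cutoff (default 0.8 nm, roughly first-shell
contact for 0.47–0.7 nm beads) per A–B couple per frame.
`gyration_radius()` is the mass-weighted RMS distance from the centre of
mass and refuses visibly wrapped aggregates; `unwrap_aggregate()` rebuilds
molecules across the periodic boundary by bond-graph traversal and shifts
whole molecules by minimum image (valid while the aggregate is smaller
than half the box).

## The synthetic generator as a study stand-in

The built-in simulator *is* the data generator for the test suite and the
acceptance analysis, at the study conditions: 100 R + 100 B five-bead
amphiphiles, 20 nm box, 300 K, the interaction regimes above. What the
desk-scale fixtures cannot reproduce is the production timescale: the
reference protocol runs tens of microseconds and analyses the last 5 μs
at a 10 ns stride (500 frames, 100 000 descriptor rows), while the
fixtures here start from the preassembled-micelle fixture, equilibrate
for 1 ns and sample 60–120 frames at a 0.1 ns stride (minutes of CPU).
Consequences to keep in mind:

* consecutive fixture frames are correlated (statistical inefficiency
  2–8), so every density-significance decision leans on the
  autocorrelation correction described above;
* slow collective relaxations (global shape changes, complete on-surface
  demixing) are not sampled — which is exactly why the segregating
  fixtures start from the janus arrangement rather than waiting for
  demixing;
* transition probabilities are quoted at the fixture lag (0.1 ns), not at
  the 10 ns production lag, so residence probabilities are not directly
  comparable to production values even where populations are.

Passing tests therefore demonstrate that the machinery — simulator
physics, descriptor invariances, embedding bookkeeping, clustering
significance logic, diagram arithmetic — behaves correctly at the study
conditions, not that a 10-nanosecond trajectory is statistically
equivalent to a 5-microsecond one.

## Numerical choices and degenerate inputs

* LJ forces and the finite-difference gradient agree to $10^{-9}$
  relative on random configurations; Newton's third law holds to machine
  precision (forces are accumulated pairwise).
* The SOAP radial table interpolation error is far below the $10^{-4}$
  quadrature-oracle tolerance; spectra are smooth (O($\delta$)) in
  neighbour displacements away from the cutoff.
* Empty SOAP neighbourhoods, all-identical TwoNN inputs, single-frame
  transition series, zero-outgoing-event rows, empty RDF selections and
  over-full placement boxes all raise explicit errors or produce exact
  zeros as documented, never silent garbage.
* Quick-shift ties and classification ties break to the lowest index;
  cluster ids are ordered by decreasing population for stable reporting.
* All stochastic stages (placement, thermal noise, FPS start) consume
  R's RNG under explicit seeds; the full pipeline is bitwise reproducible
  for a fixed configuration and seed.

## Limitations

* The simulator covers exactly the minimal model: no explicit solvent, no
  electrostatics, no angles/dihedrals, no barostat. External trajectories
  at other resolutions are ingested via multi-frame GRO or XYZ files plus
  a head map; compressed binary trajectory formats are out of scope.
* PAMM cluster counts on short, correlated trajectories are sensitive to
  the density-error model; the statistical-inefficiency correction makes
  the defaults honest but cannot manufacture sampling that is not there.
* The descriptor describes head-centre arrangements only; tail
  conformations enter solely through their effect on head packing.
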