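---
title: "Rigid-body docking by uniform rotational sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body docking by uniform rotational sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotdock)
```

rotdock generates rigid-body docking poses for two protein partners — the
larger one called the receptor, the smaller the ligand — by sampling the
rotations of *both* molecules uniformly, rather than fixing one molecule and
scanning translations of the other. This vignette explains the model behind
each stage, the parameters that matter, the numerical choices we made where
the design was genuinely open, and what the synthetic test system does and
does not demonstrate.

## The sampling model

### Direction sets on the sphere

A docking orientation is built from a pair of unit vectors: one direction on
a sphere around the receptor, one around the ligand. How many directions are
needed depends on the desired surface resolution $\rho$: we want the centers
of the sampled partner placements to be roughly $\rho$ apart on the surface
where the partner's center can sit. That surface is the *expanded* molecular
surface — the solvent-accessible surface computed with a 14 Å probe, which
is roughly the radius of gyration of a medium-sized protein and smooths away
all local detail. An equilateral triangular mesh of edge $\rho$ tiling an
area $A$ has about

$$N = \frac{2A}{\sqrt{3}\,\rho^2}$$

vertices (each vertex owns a hexagon of area $\sqrt{3}\rho^2/2$), so
`points_for_resolution()` converts the expanded area directly into a point
count with this closed form, floored at 4 (fewer than four directions cannot
bracket a three-dimensional body). This replaces explicit mesh generation
while preserving exactly the quantity the mesh was used for — its vertex
density.

Distributing $N$ points uniformly on a sphere has no exact general solution.
`distribute_points()` uses two regimes:

* **$N \le 150$** — the points minimize the Coulomb energy
  $\sum_{i<j} 1/|p_i-p_j|$ (the Thomson problem) with a multi-start
  projected-gradient BFGS. Starts are the generalized-spiral configuration
  plus seeded random configurations, so the result is deterministic for a
  fixed seed and never worse than the spiral. For the small symmetric counts
  the optimizer reaches the known global optima (antipodal pair, equilateral
  triangle, tetrahedron, octahedron, icosahedron) to high precision; the
  test suite asserts this against closed forms.
* **$N > 150$** — a deterministic golden-ratio generalized spiral with the
  offset latitude lattice $h_k = -1 + (2k-1)/N$. The offset matters: the
  classical spiral pins its first and last points at the poles, where the
  nearest-neighbour spacing collapses to $\approx 2/\sqrt{N}$ and uniformity
  degrades. With the offset lattice the minimum pairwise angle stays above
  0.7 of the hexagonal-packing estimate $\sqrt{8\pi/(\sqrt{3}N)}$ for all
  counts we test (up to 2000).

The threshold of 150 keeps both branches deterministic and fast; the
optimizer becomes expensive well before it stops being beneficial.

### From directions to orientations

Three equivalent enumeration schemes turn the direction sets $P_{rec}$,
$P_{lig}$ and a twist grid $\psi$ into poses:

* **RRT** — the ligand is twisted about its $z$ axis by $\psi$, its north
  pole is then rotated onto a ligand point $p_{lig}$, and the ligand center
  is translated along each receptor direction $p_{rec}$.
* **TRR** — the ligand is translated along $p_{rec}$, rotated so that
  $p_{lig}$ faces the receptor on the inter-center axis, then twisted about
  that axis.
* **RRR** — both molecules are rotated: the receptor so that $p_{rec}$
  points along $+z$, the ligand so that $p_{lig}$ points along $-z$ (each
  molecule facing the other), followed by the ligand twist about $z$. This
  is the default: it describes docking purely with rotations and is the
  cheapest to evaluate (see the contact-distance caching below).

The number of twist angles is $\mathrm{round}(\sqrt{|P_{lig}|})$, uniformly
spaced on $[0, 2\pi)$. The square-root rule matches the angular resolution
of the twist to that of the point set, which is what makes the combined
rotation set uniform: with 492 ligand vertices, for example, only 22 twist
increments are required, versus the 72 five-degree increments a fixed-step
scheme would use. The test suite checks the resulting uniformity globally:
the relative rotation angle between two random poses must follow the Haar
density $(1-\cos\theta)/\pi$, with a Kolmogorov–Smirnov statistic below
0.05.

Conventions that fix the enumeration bit-for-bit: the minimal-arc rotation
is used everywhere; its antipodal tie-break is a rotation by $\pi$ about the
$x$ axis for the north pole (and about the deterministic in-plane basis
vector otherwise); $\psi = 0$ is included and $2\pi$ excluded; poses are
enumerated receptor point outermost, twist innermost. Poses are stored as a
plain table (one row per pose, rotations as canonical scalar-first
quaternions with $w \ge 0$) rather than a lazy stream; at the problem sizes
this package targets (up to a few hundred thousand poses) the table is
small, and the fixed enumeration order preserves the ability to checkpoint
by `(i_rec, i_lig, i_twist)`.

### Restraint-restricted sampling

When interface residues are known (mutagenesis, conservation, prior
structures), `restrict_directions()` keeps, for each restraint residue, the
direction best aligned with the center-to-residue vector plus its 6 angular
nearest neighbours (hexagonal coordination; configurable). One deliberate
subtlety: the twist count of subsequent sampling is computed from the
*parent* point-set size, not the restricted subset. Restriction narrows
where the molecules face each other; it should not coarsen the twist
resolution, and keeping the parent count makes the pose count shrink by
exactly $\left(\frac{k_{rec}}{N_{rec}}\right)\left(\frac{k_{lig}}{N_{lig}}\right)$.

## The optimal separation

For each orientation the center-to-center distance $r$ that brings the
surfaces into contact is computed from two *grid-projected surfaces*. A
17 × 15 equilateral triangular lattice with step $\lambda = 3.5$ Å is placed
in the plane through the molecule's geometric center perpendicular to the
interaction direction. For each lattice point, the *surface backbone atoms*
(N, CA, C, O with non-zero solvent accessibility) inside the cylinder of
radius $\lambda/2$ around the lattice line are collected, and the cell
records the farthest signed axial projection; empty cylinders are null
cells. Cells behind the center are legitimately negative — concave faces
need them. Summing the receptor and ligand matrices cell by cell and taking
the maximum over cells where *both* heights exist gives the separation at
which the projected surfaces touch; a fixed margin $\epsilon = 4.7$ Å is
added for the side-chain volume that backbone atoms do not account for.
Orientations with no doubly-occupied cell cannot be scored and are flagged
invalid and counted, not given a fallback distance.

Three design choices deserve justification:

* **Axial heights, not Euclidean distances.** Only the signed projection
  along the interaction axis makes "sum of the two matrices = required
  separation" geometrically exact; Euclidean distance to the surface would
  mix lateral offsets into the sum.
* **Both grids share one in-plane basis.** Cell $(i,j)$ of the receptor
  matrix and cell $(i,j)$ of the ligand matrix must sample the *same*
  lateral offset, otherwise the element-wise sum pairs cells on different
  axis-parallel lines. The ligand grid therefore reuses the receptor's
  in-plane basis while projecting along $-u$.
* **The basis is anchored in the receptor's body frame.** The in-plane
  basis is the deterministic orthobasis of the receptor-native direction
  $R_{rec}^{\mathsf T}u$, carried to the world frame by $R_{rec}$. A basis
  derived from $u$ alone would make $r$ depend on the world orientation of
  the whole problem (the deterministic orthobasis is not
  rotation-equivariant), breaking the invariance of $r$ under rigid motions
  of the complex. With the body-frame anchor the invariance is exact and is
  asserted in the tests.

Because the grids only need directions and bases, they are computed in each
molecule's *native* frame using the pre-images of $u$ and the basis under
the pose rotations — the atomic coordinates are never transformed during
sampling. For RRR the ligand's native frame depends only on
`(i_lig, i_twist)`, so its grids are shared across all receptor directions;
grids are cached by their native-frame geometry (not by pose indices, which
externally supplied pose tables may not carry). An independent validation
path (`separation_worldframe()`) transforms the coordinates explicitly and
recomputes both grids in the world frame; the two agree to machine
precision on random poses, and a brute-force slide oracle confirms that at
$r - \epsilon$ the backbone surfaces touch within one lattice step.

## Residue-based desolvation

Scoring millions of poses with an atom-based buried-surface desolvation
requires recomputing accessible areas per pose, which dominates runtime.
The fast alternative precomputes, once per unbound molecule, each residue's
intrinsic contribution

$$E_i = \sum_{a \in i} \sigma_a \, \mathrm{ASA}_a$$

from element-keyed atomic solvation parameters $\sigma$ and unbound
per-atom areas. A pose is then scored as $\sum_{(i,j)} (E_i + E_j)$ over all
intermolecular residue pairs with any heavy-atom pair within 8 Å — only
distances are computed per pose. A residue in $k$ pairs contributes $k$
times: this over-counting is deliberate, because a residue central to the
interface forms more pairs *and* buries more area, so the pair-sum tracks
the atom-based energy better than counting each interface residue once. The
package carries both variants and an atom-based $\Delta$ASA oracle
(`atom_desolvation()`); on a 200-decoy synthetic set the pair-sum correlates
with the oracle at $r \approx 0.88$ versus $\approx 0.74$ for the
count-once variant (numbers from `scripts/acceptance.R`). The bundled
$\sigma$ table (C +0.012, N −0.060, O −0.030, S +0.021 energy Å$^{-2}$,
default 0) is a documented placeholder with conventional signs — all
identities and orderings the tests assert are parameter-table-agnostic, and
the table is replaceable through the scoring functions and the CLI.

The 8 Å criterion uses heavy atoms only (hydrogens are absent from typical
crystal structures and are dropped at parse time). The contact search is
pruned with residue centroids and enclosing radii but returns exactly the
brute-force pair set, which the tests verify pose by pose. Filtering keeps
the $k = \max(1, \mathrm{round}(pM))$ lowest-energy poses with ties broken
by enumeration order.

## Surface areas

Accessible areas come from an in-package Shrake–Rupley implementation with
a fixed deterministic golden-spiral test-point sphere (default 960 points
per atom; no RNG anywhere in the geometry). The water probe is 1.4 Å; the
expanded surface uses the same algorithm with the 14 Å probe. Neighbours
are processed nearest-first in blocks with early exit once every test point
is buried, which makes deeply buried atoms cheap. Van der Waals radii are a
bundled element table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, default
1.70 Å); only relative surface geometry matters downstream, so the exact
radii are configurable rather than load-bearing. Against a brute-force
random-point oracle the implementation agrees within 2% of total area on
small clusters; the isolated-atom closed form $4\pi(r_v+p)^2$ is reproduced
within the point-count discretization.

## Evaluation

A pose is *near-native* when the ligand Cα RMSD to a reference complex,
after least-squares superposition of the receptor Cα traces (Kabsch, proper
rotations only, matched by chain and residue number, unmatched residues
dropped with a logged count), is at most 10 Å. `success_rate()` reports the
percentage of cases with a near-native within the top $N$ ranks, and
`nn_concentration()` the near-native fraction of a pose set, which is the
quantity that drives downstream scoring success. For contexts where docking
sets from an FFT-based method are merged with ours,
`combine_ranked_sets()` implements weighted score merging (default weight
0.5 on our scores) with stable tie-breaks. `fft_grid_size_class()`
classifies case sizes by the FFT box dimension
$s = \lceil 2(R_{rec}+R_{lig})/\delta \rceil$ at $\delta = 0.7$ Å (small
below 150, large above 250) — the regime where FFT methods degrade and
rotational sampling retains its resolution is the large-$s$ class.

## The synthetic test system

`make_synthetic_pair()` builds rigid pseudo-proteins in real PDB syntax:
bead sites cover a spherical surface (plus a sparse interior and center) at
a chosen spacing, and each bead becomes a pseudo-residue with four backbone
atoms and one side-chain pseudo-atom within 1 Å of the site. Residue types
are a seeded apolar/hydroxyl/amide mix (ALA/SER/ASN-like, 50/25/25): the
heterogeneity is essential, because with identical residues every $E_i$ is
nearly equal and the over-counting versus count-once comparison degenerates
into noise — the paper-level behaviour of the desolvation filter only
emerges when residues differ in their intrinsic contributions, as real ones
do. The knob-and-socket shape seats a hemispherical ligand knob into a
matching receptor socket along $+z$ with a 2.6 Å surface gap, giving a
bound complex with known pose whose minimum interface distance
(≈3.3–3.7 Å) is touching but clash-free. `make_decoy_set()` produces the
exact bound pose, near-native perturbations and random contact
orientations, each with its ground-truth RMSD recorded.

What passing tests on these fixtures shows: the geometric contracts
(uniformity, separations, invariances), the exactness of the fast scorer
against enumeration, and the end-to-end ability of RRR sampling at
$\rho = 14$ Å (about 40–50 directions per body) to produce near-native
poses for every seeded fixture. What it does not show: performance on real
proteins — the fixtures are convex-ish, have no flexible side chains, no
electrostatics-driven interfaces, and their unbound structures are
identical to the bound ones, so success rates here say nothing about
unbound-unbound docking difficulty.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately small
scale: fixtures of ~150–250 residues, direction sets of 25–256 points,
$10^3$–$10^4$ poses, 200-decoy scoring sets, 240–960 Shrake–Rupley points.
These sizes keep the full suite in minutes on one CPU while leaving every
assertion at its stated tolerance. All randomness (optimizer restarts,
fixture jitter, decoy draws, pair subsampling) flows from explicit integer
seeds through one seeded-RNG helper; the geometry itself — spiral points,
lattice, projections — is RNG-free, so identical inputs give bit-identical
outputs.

## Known limitations

* Rigid bodies only: no side-chain or backbone flexibility, no ensembles
  (the pose table and plug-in scorer hook are the intended extension
  points).
* The $\sigma$ table is a conventional-sign placeholder, not a fitted
  parameter set; absolute desolvation energies are only meaningful for
  ranking.
* The 17 × 15 × $\lambda$ grid spans ~56 × 42 Å laterally; bodies much
  larger than the footprint would need `grid_params()` adjusted.
* The separation construction assumes the maximum of the summed heights is
  attained where both surfaces genuinely oppose each other; for extremely
  concave interfaces the cylinder test can overestimate contact (grazing
  atoms at the cylinder edge), bounded by the slide-oracle agreement of one
  lattice step.
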