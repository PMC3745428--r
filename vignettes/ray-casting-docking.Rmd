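---
title: "Ray-casting shape-complementarity docking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-casting shape-complementarity docking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raydock)
```

raydock implements rigid-body protein-ligand docking in the DARC (Docking
Approach using Ray Casting) family: a surface pocket is described as a set
of rays cast from a buried origin, and a docked pose is scored purely by how
well the ligand's silhouette, as seen from that origin, matches the pocket's
topography. This vignette explains the model, its tunable parameters, the
numerical choices made where the design was genuinely open, and what the
synthetic test fixtures do and do not demonstrate.

## The pocket as a set of rays

Pocket mapping starts from a protein structure and a target site (a residue
or an explicit center):

1. **Grid labelling.** A cubic grid (default spacing 0.5 Å, half-width
   `extent = 15` Å) is laid over the site. A grid point is labelled
   *protein* (P) when it lies within the van der Waals radius of any atom
   (the boundary is inclusive — a deterministic, testable tie rule), else
   *solvent* (S).
2. **Pocket marking.** An S point becomes a *pocket* point when, along at
   least one of seven scan directions (the three axes and the four body
   diagonals), a P point occurs within `max_span` grid steps (default 12) on
   each side with only solvent/pocket points between. This is the classic
   protein–solvent–protein criterion of grid-based pocket finders; the
   direction set and span are not fixed by the method family, so both are
   exposed as configuration.
3. **Shell and forbidden perimeter.** The *shell* is the set of pocket
   points in direct face-neighbour contact with the protein — the pocket's
   inner lining. *Forbidden* points are solvent points face-adjacent to the
   protein within `ring_width` grid spacings (default 2, Euclidean) of a
   shell point: the surface just outside the pocket mouth, where a bound
   ligand should not protrude. Only the largest connected shell component is
   kept by default, so disjoint stray cavities do not pollute the ray map.
   Connectivity here is the 26-neighbourhood: a shell is a one-grid-point
   thick curved surface, and adjacent shell points routinely share only
   edges or corners; with strict face connectivity a single contiguous
   hemispherical shell fragments into dozens of components (on the pit
   fixture below it would keep only the flat pit bottom).
4. **Ray origin.** The origin is placed `offset` Å (default 30) from the
   pocket center of mass along the direction towards the protein center of
   mass — i.e. buried inside the protein so that every ray looks outward
   through the pocket. Centers of mass are unweighted coordinate means
   (mass-weighting would move them by far less than the 30 Å offset scale).

Each shell and forbidden point then becomes a ray stored in spherical
coordinates about the origin: polar angle `theta` from +z, azimuth `phi`
from +x (degrees in files, `phi = 0` at the poles), and `rho`, the distance
at which the ray meets the pocket surface. Collinear points (angles equal
within 1e-6 degrees) collapse to the nearer point, since a ray's first
intersection is what matters. Raysets round-trip through a plain-text
rayfile (`DARC_RAYFILE v1`) with fixed 6-decimal fields; writing, reading
and re-writing is byte-stable.

## Scoring a pose

A pose is a rotation about the conformer centroid (ZYX Euler angles)
followed by a translation. For each ray the first intersection with the
posed ligand (smallest positive root of the ray-sphere quadratic per atom;
tangency counts) is compared with the stored `rho`:

| condition | meaning | contribution |
|---|---|---|
| pocket ray, hit at `d >= rho` | unpacking (gap between ligand and wall) | `c1 * (d - rho)` |
| pocket ray, hit at `d < rho`  | steric clash | `c2 * (rho - d)` |
| pocket ray, no hit | pocket left unfilled | `c3` |
| forbidden ray, hit | ligand extends past the pocket | `c4` |
| forbidden ray, no hit | — | 0, not counted |

with defaults `c1 = 1.0`, `c2 = 1.4`, `c3 = 21.6`, `c4 = 9.5`. The pose
score is the sum of contributions divided by the number of *contributing*
rays: every pocket ray plus the forbidden rays that hit. Lower is better; a
perfectly complementary ligand scores 0, and a ligand that misses every ray
scores exactly `c3`. The published description fixes the four conditions and
constants but not the exact functional form of the distance terms; the
linear form above is the simplest one consistent with every stated
condition, and all four weights are configurable so alternatives can be
explored. Two related open points were resolved the same way: a forbidden
ray is penalised by any intersection (no depth scaling), and the exact-match
tie `d = rho` contributes zero through either branch, so no tie rule is
needed.

### Ray elimination

Scoring can skip rays that cannot possibly hit the ligand. Every atom at
distance `d > r` from the origin subtends a spherical cap of half-angle
`asin(r / d)`; the scorer computes the exact bounding box of each cap in
(`theta`, `phi`) — the longitude extent of a cap away from the poles is
`asin(sin(alpha) / sin(theta_center))` — and unions the boxes over atoms.
Rays outside the union box are treated as guaranteed misses without testing
any atom. When an atom contains the origin, or a cap touches a pole, the
bounds report `covers_all` and nothing is eliminated. Correctness rather
than tightness is the contract: because the bounds are conservative, scores
with and without elimination are *identical*, and the test suite asserts
exact (bitwise) equality on random ligands and poses.

### Batch scoring

`score_swarm()` evaluates many poses of one conformer in two stages
mirroring the decomposition used for massively parallel scoring: stage one
fills the full ray-by-pose contribution table (deliberately without
elimination, keeping every entry on the same branch-free code path), stage
two reduces each column to a normalized total. The batch path shares its
transform and intersection kernels with the single-pose path, so its totals
are bitwise equal to sequential scoring.

## Pose optimization

Docking per rigid conformer uses particle swarm optimization over the
6-dimensional pose space. Defaults: 200 particles, 200 iterations —
evaluating 40,000 poses per run; at the typical mapping scale of 7,000 rays
and a 30-atom ligand that is 210,000 candidate ray-atom intersection tests
per pose and 8.4e9 per run, which is why the inner loops live in C++.

The update is the standard constriction form
`v <- chi * (v + c_p r1 (pbest - x) + c_g r2 (gbest - x))` with
`chi = 0.7298`, `c_p = c_g = 2.05` — the method family cites particle swarm
optimization without printing its hyperparameters, so the widely used
constriction defaults were adopted and exposed in `pso_config()`. Velocities
are clamped to half of each dimension's range; rotation dimensions wrap
modulo 2 pi; translations clip to the search box (the pocket-ray surface
bounding box padded 2 Å — the search region is likewise unstated upstream)
with the clipped velocity component zeroed. Personal/global bests update
only on strict improvement, so the global-best trajectory is non-increasing
by construction. Initial rotations are drawn uniformly per Euler angle,
which is not uniform over SO(3); at this problem scale the bias is
irrelevant to the optimizer and is accepted for the simplicity of a
6-vector state.

Iteration accounting follows the published convention that a 200 x 200 run
evaluates 40,000 poses: the evaluation of the initial swarm is iteration 1,
and each iteration is evaluate, update bests, move. `n_iterations = 0`
degenerates to a single evaluation of the initial swarm. Every run is
deterministic given the seed; `dock_compound()` offsets the seed by the
conformer ordinal (a single-conformer compound reproduces `dock_conformer()`
bit for bit) and `screen_library()` by 1000 per compound. Screening ranks
compounds by their best conformer's score, breaking ties by input order, and
flags the top `hit_fraction` (default 10%) as hits.

## Synthetic fixtures and what they show

The package tests itself against analytic constructions rather than
protein data:

- **Planted fixture** (`make_planted_fixture()`): 500 pocket and 50
  forbidden rays from an origin at (0,0,0); a single-sphere ligand of radius
  r = 2 Å centered D = 6 Å up the z axis; pocket rays Fibonacci-sampled in a
  15° cone (necessarily inside `asin(r/D) = 19.47°` so every cone ray hits)
  with `rho` set to the analytic first-hit distance
  `t(u) = (u.c) - sqrt((u.c)^2 - D^2 + r^2)`; forbidden rays sampled outside
  the cone so they miss. The `rho` values are computed from directions
  reconstructed through the same helper the scorer uses, with the same
  arithmetic ordering as the C++ kernel, so the planted pose scores
  *exactly* 0.0 in floating point. A single sphere is used deliberately:
  it is the only ligand for which exact zero is achievable along every ray;
  multi-sphere ligands are exercised against the brute-force oracle instead.
- **Toy receptor** (`make_toy_receptor()`): a slab of overlapping
  pseudo-atoms (lattice 0.5 Å, radius 0.9 Å) with a hemispherical pit carved
  from the top face by removing every atom whose sphere would intrude into
  the pit ball. That carve rule makes the pit's analytic solvent boundary
  the hemisphere itself, so the extracted shell can be checked against an
  exact oracle (`spacing * sqrt(3)` tolerance). The pseudo-atom size
  matters: larger atoms bulge above the slab face and the pocket-marking
  picks up funnel points above the pit rim well off the hemisphere; with the
  chosen defaults the envelope is smooth at grid resolution and the measured
  shell deviation stays well inside the tolerance.
- **Decoy libraries** (`make_random_library()`): random multi-sphere rigid
  "compounds" (radii uniform in [1.4, 2.0] Å, 1-3 conformers each) standing
  in for a screening library.
- **Brute-force oracle** (`brute_force_score()`): a deliberately naive pure-R
  triple loop, kept independent of the C++ kernels, against which both fast
  scorers are required to agree to 1e-9 relative on random poses.

These fixtures validate the geometry, the scoring algebra, the elimination
logic and the optimizer's behaviour. They do *not* emulate real data:
pseudo-atom receptors have no chemistry, single-sphere ligands have no
internal structure, and decoys are not drug-like. Passing tests therefore
demonstrate algorithmic correctness and reproducibility, not screening
enrichment on real targets — shape-only scoring is a pose generator, not a
binding-affinity predictor, and in production use it is followed by all-atom
refinement and re-ranking, which are out of scope here.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately modest sizes
chosen as representative: oracle and elimination checks on 100 random poses;
pose recovery over 20 independent seeds at the full 200 x 200 sampling
level; convergence medians over 10 seeds comparing 10 vs 200 iterations (at
200 particles) and 10 vs 200 particles (at 200 iterations); pocket-marking
equivalence against a line-scan oracle on random 21^3 grids; and the pit
receptor at 0.5 Å spacing. Because longer runs of the same seed extend the
same deterministic trajectory, the iteration comparison is non-increasing
per seed by construction; the particle comparison is statistical.

Degenerate inputs are defined, not accidental: a zero-atom (or far-removed)
ligand scores exactly `c3` because all pocket rays miss and forbidden
misses do not count; an empty atom list yields empty angular bounds (no ray
passes); coincident pocket and protein centers of mass are a geometry
error; a grid with no pocket points is a "no pocket found" error. Rayfile
numbers are fixed 6-decimal text — within-tolerance equality after a round
trip, byte-identical on re-write.

## Known limitations

- Scoring is shape-only: no electrostatics, chemistry or solvation terms.
- The receptor is rigid, and each conformer is docked rigidly; conformer
  generation itself is upstream of this package.
- The CLI `synth` fixture writes its ligand as carbon atoms in PDB, which
  stores no radii, so the round-tripped fixture uses the carbon table
  radius (1.7 Å) as its default sphere radius.
- The original implementation's native rayfile format is not parsed; this
  package defines its own documented text format.
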