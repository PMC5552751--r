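---
title: "Ligand egress, path variables and well-tempered metadynamics: the methods behind egresslab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand egress, path variables and well-tempered metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

egresslab implements, at desk scale, a workflow used to study how a small
ligand leaves a buried binding site: find a curvilinear egress pathway with a
biased search, describe progress along it with path collective variables,
resolve the free energy along the path with well-tempered metadynamics, and
characterize the accompanying conformational change by embedding and
clustering snapshots. All of it runs on built-in Langevin toy systems, so
every statistical claim made by the test suite is checkable against analytic
or brute-force oracles.

## The toy engine

Units are Angstrom, picosecond, kcal/mol, Kelvin and amu, with
`kB = 0.0019872041` kcal/mol/K. Dynamics is Langevin in the BAOAB
discretization; with zero friction it reduces to velocity Verlet, which is
what the energy-conservation test exercises. The ligand is a rigid body (a
compact five-atom "camphor-like" cluster): its center of mass translates
under the net force and its orientation evolves by Euler's equations in the
principal frame, each with its own thermostat channel. Rigidity avoids any
intramolecular force-field design and matches how a small rigid substrate
behaves on these time scales.

Two fixture families exist:

* `make_double_well(barrier, spacing)` — a single particle in
  `U(x) = b((x/a)^2 - 1)^2`. This is the metadynamics benchmark: barrier
  exactly `b` at `x = 0`, minima at `±a`, Boltzmann density known by
  quadrature.
* `make_cage_ligand(n_cage, cage_radius, n_tunnels, seed)` — a spherical
  shell of harmonically restrained atoms (a Fibonacci lattice) with
  `n_tunnels` angular gaps cut out, a fixed central anchor atom playing the
  role of a metal center, and the rigid ligand at an off-center active site.
  A one-sided harmonic wall on the ligand-COM distance from the center (the
  analog of a metal-to-ligand distance restraint) keeps escaped ligands from
  drifting to infinity.

Nonbonded interactions are Lennard-Jones 12-6 plus Coulomb with a
configurable dielectric, evaluated over ligand-environment pairs only: cage
atoms are site-restrained, so cage-cage interactions would add cost without
changing behavior, and the rigid ligand needs no internal terms. There are
no cutoffs at these sizes. Pair distances are clamped at 0.1 A so
overlapping input gives a large finite energy and a warning rather than NaN.

### Choices that required judgment

* **Cage restraint stiffness.** The harmonic site restraint defaults to
  10 kcal/mol/A^2 in run configurations — a deliberately generic value, and
  documented as a package default since no reference value exists for it.
  For the egress studies below we stiffen the wall to 50 kcal/mol/A^2:
  with k = 10 a pulled ligand can shoulder wall atoms aside almost anywhere
  (thermal site displacement 0.25 A, but ~1 A under a modest steady push),
  which would make the shell porous everywhere instead of only at the
  engineered gaps.
* **Cage density for path studies.** 150 atoms on a radius-10 A sphere with
  a 30-degree tunnel half-width. At this density the lattice spacing is
  ~3.1 A against a combined LJ sigma of 3.4 A (a solid wall), natural
  lattice holes subtend ~10 degrees, and the engineered gap (~30 degrees,
  10 A chord) is unambiguously the widest opening. Sparser shells (e.g. 60
  atoms) remain useful for construction and clustering tests but have
  natural holes comparable to a tunnel, which confounds "did the search find
  the engineered exit".
* **Active-site placement.** The ligand starts at 0.3 x radius from the
  center, tilted a fixed 50 degrees from the first tunnel axis (about a
  seeded random perpendicular). A buried site sits adjacent to the exit
  channels that emanate from it; placing the start at a uniformly random
  angle would instead model a site with no route access, and a local search
  cannot (and should not be expected to) see a mouth hidden behind the far
  side of a hollow shell.

## The egress search

The search minimizes an effective ligand-environment interaction functional
over rigid-body poses,

    Lambda = sum_{i in ligand, j in environment} h_ij exp(-r_ij^2 / 2 w^2) + gamma,
    h_ij = s_i v_j + s_j v_i,

with `s` the per-atom partial volume, `v` the solvation coefficient, and
`gamma` optionally the LJ + Coulomb interaction energy. The loop is: sample
`candidate_count` poses uniformly in a sphere of radius `rho` about the
current pose (orientations perturbed up to 15 degrees), evaluate Lambda,
refine the best candidate by derivative-free coordinate descent on the six
rigid-body coordinates **constrained to the sampling sphere**, then pull the
ligand toward the minimizer with a constant-magnitude COM force (plus a weak
orienting torque) for `m` MD steps, and record the resulting full-system
snapshot as the next path node. The search ends when the ligand COM passes
`1.3 x cage_radius` (an egress criterion mirroring the role of a
metal-to-ligand distance bound) or at the node budget.

The sphere constraint on the refinement matters: unconstrained descent can
walk many Angstroms per iteration and "tunnel" the target straight through
the wall region in pose space even when the dynamics could never follow,
which breaks the correspondence between the reaction coordinate and a
physically realizable route.

Parameter defaults and the values used in the cage studies:

| parameter | default | cage study | why |
|---|---|---|---|
| `w` (A) | 3.5 | 6 | 3.5 A is the solvation-shell scale appropriate to a dense matrix; for a hollow shell the screening length must reach the wall, otherwise the interior field is flat with a spurious barrier at the wall and the funnel toward the mouth disappears. Mapping Lambda along the tunnel axis shows a monotone decrease for w = 6 and a trap for w = 3.5. |
| `include_gamma` | TRUE | TRUE | the LJ term makes in-wall poses prohibitive, so Lambda cannot prefer through-wall shortcuts |
| `rho` (A) | 2 | 2 | local neighborhood; smaller than the wall thickness |
| `candidate_count` | 16 | 16 | enough for a stable argmin direction |
| bias force (kcal/mol/A) | 20 | 5 | must stay below the wall's LJ force scale (~tens of kcal/mol/A) so the pull cannot punch through 3-atom lattice holes; the tunnel offers no opposing force, so a gentle pull suffices |
| `m` (steps) | 100 | 200 | ~0.4 ps per segment: long enough for the cage to respond, short enough that nodes stay ~1 A apart |

Per-atom defaults are `s = 1`, `v = 0` (the desolvation term is opt-in);
the cage fixture sets `v = 1` on shell and anchor atoms so the functional
has its intended meaning there. All of these are plain config values.

`reparameterize_path()` resamples a path at equal arc length in
displacement-set coordinate space (nodes first superposed on the frame of
node 1), preserving the endpoints exactly; near-equidistant nodes are a
precondition for well-behaved path variables.

## Path collective variables

For a path of N nodes and metric `||.||^2` = mean-square displacement of the
displacement-set atoms after superposition on the alignment set (the two
sets are disjoint: cage atoms align, ligand atoms displace),

    s(R) = sum_k k exp(-lambda ||S(R)-S(k)||^2) / sum_k exp(-lambda ||S(R)-S(k)||^2)
    z(R) = -(1/lambda) ln sum_k exp(-lambda ||S(R)-S(k)||^2)

computed with log-sum-exp stabilization (lambda x MSD can exceed 700, so the
naive form overflows). `sigma = (s-1)/(N-1)` rescales progress to [0, 1].
When every MSD ties, the formula itself yields s = (N+1)/2 — no special
tie-break is needed.

Gradients are taken with the references aligned onto the current frame and
the rotation held fixed. Because the alignment set is disjoint from the
displacement set, the rotation does not depend on displacement-atom
coordinates at all, so the displacement-atom gradients used for biasing are
exact — the finite-difference check in the tests agrees to ~1e-9, not
just the 1e-4 documented bound. (Gradients with respect to alignment atoms
would carry a rotation-derivative term; they are not needed for biasing the
ligand and are not computed.)

`choose_lambda()` implements the standard heuristic `lambda = 2.3 / <MSD>`
between consecutive nodes, so the weight of the next node at one node
spacing is ~0.1. Published pathway tables that report both `<MSD>` and
lambda match this rule for two of three pathways (14.41 -> 0.16,
13.03 -> 0.18) but not the third (16.31 vs 0.36); since no rule is stated
anywhere, lambda stays user-settable and the discrepancy is simply noted.

## Well-tempered metadynamics

The bias is a sum of Gaussians deposited along the CV trajectory. The
deposition rate is stated in the literature as an energy rate,
1.92 kcal/mol per ps; we interpret that as initial height x frequency and
default to `h0 = 0.48` kcal/mol every 0.25 ps, which reproduces the product.
Heights decay by the well-tempered rule `h = h0 exp(-V/kB dT)` with
`dT = 3300 K` at `T = 300 K` (bias factor 12). Gaussian widths are adaptive
in the time domain: the standard deviation of the CV over the trailing
0.25 ps, floored (0.05 A on the 1D benchmark, 0.01 sigma-units on paths) so
a momentarily frozen CV cannot deposit spike kernels.

The free energy is estimated as `F = -((T+dT)/dT) V`, shifted so
`min F = 0`, and observables are reweighted with the time-dependent constant

    c(t) = (1/beta) ln [ Int dxi exp(-beta F(xi)) / Int dxi exp(-beta (F(xi)+V(xi,t))) ]

by trapezoid quadrature with log-sum-exp stabilization; frame weights are
`exp(beta (V(s(t), t) - c(t)))`. Two identities anchor the tests: `V = 0`
gives c = 0 and uniform weights, and a uniform bias `V0` gives `c = V0`
exactly regardless of F.

Convergence is monitored the standard way: the height trace, the residual
height fraction (mean height over the final 5% of kernels divided by `h0` —
the "final 5%" window is our operational definition of residual height,
since none is standardized), and block standard errors computed from the
spread of the estimator at evenly spaced times over the second half of the
run. On the 4 kcal/mol double well with the parameters above, 5e6 steps of
2 fs (10 ns) bring the residual fraction to ~0.1% and the mean block SE on
the sampled region to well under 0.2 kcal/mol; the barrier is recovered
within 0.5 kcal/mol across seeds. These problem sizes (5e6 steps for the 1D
benchmark, ~1e4 steps for the cage path runs) are the package's chosen
study sizes: large enough for the convergence criteria, small enough to be
re-run routinely.

On cages, metadynamics biases sigma only, while z is confined by a one-sided
harmonic wall — biasing progress along the path while restraining deviation
from it. The published constraint for the reference systems is z < 6 A^2. A
harmonic wall is soft: at stiffness 100 kcal/mol/A^4 thermal excursions
overshoot the set-point by ~0.1 A^2, so a wall placed exactly at 6 lets
occasional frames cross. Where the hard bound itself matters we place the
set-point at 5.5 A^2 with kappa = 200 kcal/mol/A^4, which keeps every
recorded frame strictly below 6 while leaving the accessible tube
essentially unchanged (z on a well-built path lives near 0-3 A^2). The wall
force enters the atoms through the chain rule with the analytic z gradient,
exactly like the bias force on sigma.

## Conformational-state analysis

Snapshots are compared by Kabsch-superposed RMSD on a chosen atom subset,
embedded in 2-D by classical (Torgerson) multidimensional scaling — chosen
over non-metric variants because it is deterministic and exactly checkable
(it reproduces 2-D-realizable distance matrices to machine precision) — and
clustered with DBSCAN. The embedding is min-max normalized to the unit
square, the convention in which basin centers are conventionally reported.
DBSCAN is implemented directly (queue expansion, noise = -1, border points
joining the first cluster that reaches them, so results are deterministic
for a fixed frame order); the test suite checks it against an independent
construction via connected components of the core-point graph. `eps` and
`minPts` default to a k-distance-elbow suggestion and are always
overridable. Occupancies are plain label fractions; representatives are
medoids (minimum summed RMSD within the cluster, ties to the lowest frame
index); external structures are assigned to the basin of their nearest
non-noise frame.

The planted-mixture test builds a "closed" family (cage at its lattice
sites) and an "open" family (one gate ring displaced 3 A outward) with
0.3 A coordinate noise, mixes them 70/30, and requires the pipeline to
recover the mixture within +/-0.05 with correctly separated medoids — a
desk-scale rehearsal of an open/closed state decomposition.

## What the toys do and do not show

The generator emulates the *structure* of the problem: a buried start, a
matrix that blocks everywhere but a few routes, restrained host atoms, a
rigid ligand, and observables (path CVs, free-energy profiles, state
decompositions) with known ground truth. It does not emulate solvent,
electrostatic screening, conformational gating by side chains, or the
microsecond time scales of real ligand egress; passing tests therefore
validate the machinery — integrators, estimators, gradients, search logic,
clustering — not any biological claim about a particular enzyme. Barrier
heights and occupancies from the toys are properties of the toys.

## Known limitations

* Alignment-atom gradients of s/z are not implemented (not needed for
  ligand biasing); biasing alignment atoms would require them.
* The rotational Langevin step is a simple explicit Euler-frame scheme;
  energy-conservation guarantees are tested for the translational
  integrator only.
* The memetic search is best-of-candidates plus constrained local descent; a
  population/crossover variant would explore more aggressively but would
  lose the brute-force-oracle testability that motivated this design.
* `reparameterize_path()` interpolates linearly in coordinate space, which
  slightly shortens rigid bodies between widely spaced nodes; resample from
  reasonably dense paths.
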