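---
title: "Minimalist coarse-grained models for protein transition paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimalist coarse-grained models for protein transition paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcgpath)
```

## The model and its assumptions

`mcgpath` represents a protein chain as one bead per residue at the Cα
position. This is the coarsest representation that still encodes secondary
structure: the pseudo bond angle θ (three consecutive Cα) and pseudo-dihedral
φ (four consecutive Cα) jointly distinguish helices (θ ≈ 90°, φ ≈ +50°) from
strands (θ > 110°, |φ| > 80°). The force field is *partially biased*: rest
values of all bonded terms and of the local contact wells are read off a
chosen reference structure, which thereby becomes a built-in energy minimum,
while the non-local interactions remain generic. The bias is the modelling
assumption that makes two-state transition sampling tractable: when the goal
is to connect two *given* structures, each state's force field must make
that state stable anyway, and simulating under the opposite state's bias
(start in A under FF_B, and vice versa) turns a rare activated event into a
relaxation that ordinary Langevin dynamics can reach.

The energy decomposes as bonded (bond restraints, angles, dihedrals) plus
non-bonded Morse pairs, split at a reference-distance cutoff r_cut = 8.5 Å
into local (structure-specific depth/range, strong in the H-bond range,
decaying to a floor near the cutoff) and non-local pairs (a single shallow
hydrophobic well, ε = 0.05 kcal/mol at r₀ = 9.5 Å). Pairs with |i−j| ≤ 3 are
excluded from the non-bonded sums, since those degrees of freedom are already
governed by the bond, angle and dihedral terms. A reference distance exactly
at the cutoff classifies as non-local (the local criterion is strict `<`).

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| B, k₀ | 3000, 10 | kcal/mol | angle-stiffness scale and floor of the damped-sinc law B·sinc²(βθ₀)+k₀ |
| β | 1.667 | rad⁻¹ | places the sinc zero at θ₀ ≈ 108°, i.e. stiff helices (θ₀ ~ 90°), soft strands (θ₀ > 110°) |
| A (helix / strand) | 25 / 5 | kcal/mol | dihedral amplitude, split at \|φ₀\| = 80° |
| r_cut | 8.5 | Å | includes H-bonds, salt bridges, disulfides in the local set |
| ε(r₀), α(r₀) | 3.8·e^(−(r₀/6.1)^8)+0.05, 2.2·e^(−(r₀/6.1)^8)+0.70 | kcal/mol, Å⁻¹ | short reference contacts are strong and short-ranged, long ones decay to the generic floor |
| non-local r₀, ε, α | 9.5, 0.05, 0.70 | Å, kcal/mol, Å⁻¹ | average hydrophobic attraction, amino-acid independent |

The angle stiffness divides by sin²θ₀ (the harmonic-cosine form needs it to
recover the equipartition stiffness k′ = k_B T / ⟨δθ²⟩ of an atomistic
reference). Rest angles are clamped to [5°, 175°] before this division —
near-collinear reference geometry would otherwise produce unbounded
stiffness. The dihedral rule compares |φ₀| to 80°, so left- and right-handed
reference geometry is treated alike; the sign convention for φ itself is the
right-handed IUPAC one, range (−π, π] (verified against `bio3d::torsion.xyz`
in the test suite).

### Numerical choices in the energy/force kernel

Non-local pairs are evaluated with a 25 Å truncation, shifted so the energy
is continuously zero at the cutoff; the shift is ~2·10⁻⁶ kcal/mol, cosmetic
but it keeps the microcanonical energy budget exact. The pair lists are
precompiled from the reference structure, so evaluation is a direct loop
over the fixed lists (at the chain lengths this package targets, up to a few
hundred beads, a direct loop is faster than maintaining a Verlet neighbour
list, which is why none is used). Overlapping beads (r < 0.1 Å) abort with
the offending pair named, since a Morse well has no repulsive core at r → 0.

## Langevin dynamics

`run_ld()` integrates the Langevin equation with the BAOAB splitting, chosen
for its near-exact configurational sampling at practical timesteps; at
γ = 0 it reduces to velocity Verlet, which is what the microcanonical
drift checks in the test suite exercise (energy drift is O(dt²): halving dt
reduces the drift about fourfold). Bonds are holonomic constraints by
default, enforced by SHAKE position iterations (tolerance 10⁻⁸ Å, 500
iteration cap) with RATTLE velocity projections after the stochastic and
kick stages; a stiff-harmonic mode (k = 100 kcal mol⁻¹ Å⁻²) is available for
cases where an exactly conserved energy is wanted. The instantaneous kinetic
temperature uses 3N − (N−1) degrees of freedom in constraint mode.

Bead masses default to a uniform 110 amu (the average residue mass);
equilibrium *configurational* observables are mass-independent under a
thermostat, so this choice only affects time scales. Units are Å / ps / amu
/ kcal/mol with k_B = 1.9872041·10⁻³ kcal mol⁻¹ K⁻¹. The default timestep is
0.01 ps and the default dump interval 10 ps. Velocities are initialized from
the Maxwell–Boltzmann distribution with the centre-of-mass momentum removed;
the integrator's noise stream is seeded from the same configuration seed, so
a run is bit-reproducible given its `sim_config()`.

Thermostat correctness is verified three ways in the suite: the time-mean
kinetic temperature of a 1 ns, 30-bead helix run at 300 K / γ = 8 ps⁻¹
agrees with the target within three standard errors; chained decorrelated
velocity snapshots pass a Kolmogorov–Smirnov test against the
Maxwell–Boltzmann distribution; and the stiffness of an isolated pseudo-angle
is recovered from its cos θ fluctuations via equipartition
(k_θ = k_B T / var(cos θ)) within 15%.

## The σ progress coordinate

σ(r) = ½(RMSD_A − RMSD_B)/RMSD_AB + ½, each RMSD computed after an
*independent* Kabsch superposition onto its reference (SVD with determinant
correction, proper rotations only). Independent fits make σ a pure shape
coordinate: any rigid motion of the query cancels exactly, and the endpoint
identities σ(A) = 0, σ(B) = 1 are algebraic. σ is deliberately not clipped
to [0, 1] — a conformation farther from A than B is from A produces σ > 1,
and that is information, not an error. Because σ projects the 2-D
(RMSD_A, RMSD_B) plane onto the A–B axis, the per-frame scatter table is
kept alongside it; structures with equal σ can be very different, and the
off-diagonal region of the scatter plot is where misfolded intermediates
show up.

Energy profiles are raw per-bin means and standard deviations of the
potential energy over regular σ intervals spanning the observed range (right-
closed last bin, empty bins reported as empty, never interpolated). They are
*not* free-energy estimates. Profiles from the two biased force fields have
no common energy zero; `align_energy_scales()` makes the usual alignment
explicit by matching the two profiles in the bin containing a chosen σ*
(default 0.4, where dual-bias trajectories typically come closest in
conformation space), returning the additive shift rather than silently
applying it.

## Principal-path clustering

The trajectory reduction is a regularized k-means in the flattened 3N
coordinate space (all frames first Kabsch-aligned onto endpoint A, so
Euclidean distances are shape distances — the same convention σ uses). The
cost is the within-cluster sum of squares plus s times the summed squared
distances between adjacent representatives; the endpoint representatives are
pinned to the A and B conformations, and the K−2 interior ones are
initialized on the A→B linear interpolation, making the fit deterministic.
Each iteration alternates an assignment step with an exact interior update
(a tridiagonal linear solve), so the cost is non-increasing by construction;
convergence is declared at a relative cost change of 10⁻⁸ (cap 500
iterations). An empty interior cluster simply leaves that representative
tethered by the spring term (at s = 0 it is retained with a warning).

The regularization weight is chosen by Bayesian evidence maximization,
reading the cost as an energy: the posterior over interior representatives
is ∝ exp(−cost), i.e. a unit-precision Gaussian likelihood times a
pinned-chain Gaussian smoothness prior with precision s. The evidence is
computed by a Laplace approximation at the fitted optimum *including the
prior normalization* — the (d/2)·log(2s) and (D/2)·log(K−1) terms from the
normalized chain prior. Without them the "evidence" is monotone in s and
selection always hits the grid boundary; with them the selected s is finite
and interior for well-behaved data (verified on noisy polyline clouds in the
suite). If all frames are identical the comparison is meaningless and the
function warns instead. The default grid is 10 log-spaced values spanning
10⁻³–10³ times the mean squared frame-to-frame displacement. The default
K is 20 representatives; `nearest_frames()` maps each representative to its
closest actual frame (ties to the earlier frame), giving a simulation-frame
counterpart of the optimized path, which necessarily scores an equal or
higher cost than the representatives themselves.

## Synthetic study systems

The generators exist so the whole pipeline is testable without any external
structure, and their defaults are the conditions under which the package's
checks run:

* `make_helix()` — parametric helix, rise 1.5 Å, radius 2.3 Å, twist
  100°/residue: θ ≈ 90°, φ ≈ +50°, spacing ≈ 3.83 Å, squarely in the
  helical force-field regime.
* `make_strand()` — planar zig-zag with bonds ±25° off-axis: θ = 130°,
  φ = 180°, an extended chain with no non-bonded contacts inside 8.5 Å.
* `make_hinge_pair()` — the two-state system: two helical arms joined by a
  4-residue loop (loop angles 100°, loop dihedrals 180°), the second
  half rigidly rotated about the central loop bead so the opening angle
  between the arms (measured between the arm rods from the hinge) is χ_A in
  state A and χ_B in state B. Defaults n = 40, χ_A = 30°, χ_B = 120° give
  RMSD_AB ≈ 9.2 Å, far above the thermal RMSD fluctuations of the chain at
  the 130 K study temperature, so the two basins are cleanly separated in σ:
  a 10 ns run from the closed state under the open-biased force field
  crosses to σ > 0.8, while a run started in its own bias state keeps
  σ within 0.2 of its basin. An earlier design that changed a single hinge
  *dihedral* was rejected because the helix axis lies close to that rotation
  axis, yielding too small an RMSD_AB for a clean two-state signal.
* `make_arc_cloud()` — a noisy quarter circle in 2-D with its endpoints, the
  standard curved-manifold fixture for the path clustering.

What these toys deliberately do *not* emulate: real contact maps (the toy
states are held apart by bonded hinge terms, not by a rearranged contact
network), sequence heterogeneity, chain lengths beyond ~10² residues, and
solvent or ion effects. Passing tests on them demonstrates the correctness
of the machinery — energies, forces, sampling, σ algebra, clustering — not
that the force field reproduces any particular protein's transition
thermodynamics, which additionally requires realistic reference structures
and much longer runs.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to what the
physics needs and no more: 1 ns (10⁵ steps) for the 30-bead thermostat
average, 10⁴–2·10⁴ steps for microcanonical drift scaling on a 10-bead
helix, 4·10⁵ steps for the isolated-angle equipartition estimate, and
5 × 10 ns (10⁶ steps) at N = 40 for the hinge transition demonstration,
whose success criterion is a majority of seeds reaching σ > 0.8.

## Known limitations

* The Morse wells have finite dissociation energies but no excluded-volume
  core; strongly compressed conformations are only penalized, not forbidden,
  and bead overlap aborts the run rather than being repelled.
* Single chains only; no explicit ions, so systems whose transition is
  ligand-gated are represented only through the dual-bias protocol.
* The non-local well is amino-acid independent by design; hydrophobicity is
  uniform along the chain.
* Energy profiles are potential-energy averages, not potentials of mean
  force; entropic contributions along σ are invisible to them.
* The evidence model treats the data precision as fixed at 1 (in Å⁻²);
  selected s values are therefore meaningful relatively, not absolutely.
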