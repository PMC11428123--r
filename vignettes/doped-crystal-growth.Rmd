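---
title: "Doped molecular crystals: solid-solution thermodynamics and interaction-driven growth"
author: "xtalgrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doped molecular crystals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xtalgrow)
```

`xtalgrow` models two linked questions about molecular-crystal solid
solutions, with guanine doped by hypoxanthine (hpx) or xanthine (xan) as the
motivating system: whether a doped lattice is thermodynamically within reach
of the physical mixture of the pure solids, and how dopants and solvent
reshape the crystal habit. This vignette is the package's methods record:
the models, their assumptions, the tunable parameters, the numerical
conventions, and what the synthetic data generator does and does not
emulate.

## 1. Structural substrate

A `crystal_structure` couples a triclinic `unit_cell` (lengths in Å, angles
in degrees) with space-group operations and molecule placements. All
geometry passes through one fixed Cartesian convention — **a** along x,
**b** in the x–y plane — so fractional and Cartesian coordinates never mix
conventions. d-spacings come from the general triclinic reciprocal metric,
valid for any cell.

CIF input is deliberately minimal (cell, symmetry `x,y,z` strings,
fractional atom sites). Molecules are assembled from atom sites by covalent
bonding — two atoms bond when their distance is below the covalent-radii
sum times a tolerance of 1.15, a standard heuristic exposed as `bond_tol` —
and unwrapped across periodic boundaries by breadth-first traversal. A bond
path that reaches the same atom through two different lattice images means
a covalently periodic network, which is rejected: this is a molecular-
crystal package. Partial occupancies are rejected for the same reason:
disorder is represented explicitly, by enumerating ordered configurations,
never by fractional sites.

## 2. Substitution and configurational ensembles

Host→guest substitution operationalizes "maximum atom overlap" as a
least-squares rigid superposition (Kabsch, via SVD with the determinant
correction) over the scaffold atoms the two purine templates share: the
nine-atom bicyclic ring plus the exocyclic O6 where present, matched by
canonical label (`N1 … N9, O6`). Substituents without a counterpart —
guanine's exocyclic amine — simply leave with the host molecule. A scaffold
RMSD above `rmsd_max` (default 0.75 Å) raises an alignment-quality error
rather than silently placing a badly fitted guest; for the idealized
templates shipped with the package the purine-on-purine RMSD is numerically
zero, so the gate only matters for distorted user-supplied templates.

At fixed guest count, the configurational ensemble contains all occupancy
patterns distinct under the *lattice translations of the supercell* — the
symmetry that is actually periodic there. Point-group reduction would fold
the ensemble further; we keep translations only and note that duplicates
under point symmetry merely re-sample identical energies, which biases
nothing. Enumeration is exhaustive up to 20,000 raw combinations, and
seeded random sampling beyond that; the ensemble is then capped (default 64
members, 16 in the pipeline chains) by a seeded subsample, with the seed
recorded in the result. Since the shipped energy model is exactly linear in
guest count, ensemble members at one composition are degenerate in energy
and the cap costs nothing; with a clustering-sensitive model the cap
becomes a real approximation, which is why it is configurable.

The ensemble→point reduction defaults to the minimum energy over members,
with `mean` and `boltzmann` available: which reduction the reference
analyses used is not derivable, so it is a configuration choice, not a
constant.

## 3. Thermodynamics

Per-molecule lattice energy of a solid solution:

$$E_\mathrm{latt} = \frac{E_\mathrm{cell} - N_h E_h^\mathrm{ref} - N_g E_g^\mathrm{ref}}{N_\mathrm{cell}}$$

which reduces to the standard single-component definition at $N_g = 0$ and
is invariant under supercell replication (tested). Units are kJ/mol
throughout; kcal inputs convert (×4.184) at construction time, and the
mixing entropy $\Delta S_\mathrm{mix} = -R(x_h \ln x_h + x_g \ln x_g)$ is
carried in J mol⁻¹ K⁻¹ and converted only at free-energy assembly:

$$G(x) = E_\mathrm{latt}(x) + F_\mathrm{vib}(x) - T\,\Delta S_\mathrm{mix}(x),$$

with $T = 300\,$K by default and Helmholtz/Gibbs treated as interchangeable
($P\Delta V = 0$ for substitutional doping). The vibrational term is a
least-squares cubic through sampled values at five compositions
(0, 0.25, 0.5, 0.75, 1) — a cubic because four coefficients are the most
that five points support without interpolation artifacts.

Stability is classified against the linear physical mixture of the pure
solids. Two conventions deserve comment:

* **The guest's own polymorph.** The pure-guest endpoint of the mixture
  line is *not* the all-guest host-structure crystal but the guest's own,
  more stable polymorph. The pairwise model carries this as
  `phase_advantage` (kJ/mol per molecule, default 9 for the hpx-like guest,
  doubled for the xan-like guest). Without it, an energy model linear in
  composition would make every dilute solid solution trivially stable —
  the mixing entropy guarantees it — and the metastability question would
  be empty.
* **The accessibility threshold.** The band within which a metastable
  solid solution is considered kinetically formable is $2RT$ evaluated
  exactly (≈4.99 kJ/mol at 300 K), not a rounded 4 kJ/mol; both statements
  circulate and they disagree numerically, so the exact one is the default
  and the threshold is a parameter.

Note one honest consequence of ideal mixing: as $x_g \to 0$ the entropy
slope diverges, so sufficiently dilute solid solutions always dip *below*
the mixture line. The metastability statement therefore applies from the
first computed compositions upward (x ≳ 0.1 on the default grid), and the
tests assert exactly that.

## 4. Interactions

Neighbors are molecules whose minimum atom–atom distance over all periodic
images is within 3.8 Å — the dimer-partitioning convention; a centroid
criterion would not reproduce the coordination of a π-stacked planar
molecule. The image search widens automatically from the cell's
perpendicular heights plus molecular radii, so cutoffs larger than the cell
are handled, not rejected. Hydrogens are optional in fixtures and treated
like any atom when present.

Symmetry-unique classification: two contacts share a type when a
space-group rotation (plus, possibly, exchanging the two molecules of the
pair) superposes the centered pair coordinates within 0.1 Å RMSD — exact
for generated fixtures, tolerant of rounded coordinates in real files.
Multiplicities are counted on a reference central molecule and must sum to
its neighbor count (invariant, tested). Energies attach to *types*:
`dg_cryst = dg_vacuum − dg_desolv` with the **half-bond convention** (each
contact contributes half the dimer energy to each partner) and the sign
convention that positive `dg_cryst` favors crystallization. The underlying
solvation-partitioning literature uses the opposite sign internally; state
this prominently whenever comparing numbers.

Interaction labels are assigned from geometry alone: the pure short-axis
contact is the `pi-stack`; the in-plane chain along **b** is the
`3H-bond`; the shortest remaining in-plane dimer link is the `2H-bond`
(splitting into ± twins in P1 supercells, which the labeler reunites by
vector and distance); stacked-level diagonals are `pi-other-k`; the rest
are `other-k`, distance-ordered.

## 5. The growth engine

Growth runs on the perfect-crystal site lattice (whole molecules, no
vacancies in bulk, no surface reconstruction). Each cycle draws one site
uniformly from the candidate set — empty sites with an occupied neighbor,
occupied sites with an empty neighbor — and proposes the only move the
site's state allows. Acceptance is Metropolis on
$U_i + \Delta\mu$, where $U_i$ sums `dg_cryst` over occupied neighbors,
**times the proposal-size correction** $|C(x)|/|C(x')|$ for the
state-dependent candidate set. The correction matters: without it the
attach/detach rate ratio is polluted by the changing proposal measure, and
the single-site equilibrium misses its analytic value
$e^{\beta U}/(1+e^{\beta U})$ by factors of order the coordination number.
With it the engine reproduces the logistic to four decimal places (tested
at five energies), at the price of one O(coordination) bookkeeping pass per
move. One knowingly tolerated asymmetry remains: filling the last vacancy
of an interior hole is irreversible (the reverse detachment would be
proposed from a state excluded by the surface rule); holes can heal but
never form, which only prunes pathological states.

Detachments that would disconnect the crystal are rejected, checked by a
breadth-first search among the detaching site's occupied neighbors with
early termination. Lattice boundaries are inert (out-of-lattice slots are
neither occupied nor attachable).

**Driving force.** The schedule is constant at `dmu_initial`, descends
linearly between `descent_start` and `equilibrium_iter` (linear because no
other shape is dictated; it is configurable), and is zero afterwards. The
reference protocol — one million cycles, 100 kcal/mol initial driving
force (the kcal reading of an ambiguous unit, taken explicitly as a
config unit), breakpoints at 500,000/600,000 — is the `"paper"` preset.
Zero scheduled driving force is referenced, by default, to the kink site:
`equilibrium_bias = "kink"` shifts the bias by −U_kink (half the bulk
per-molecule interaction energy), so "zero supersaturation" is true
coexistence — a crystal equilibrated there shows no net drift (tested by
stationarity around an anchored seed). The raw rule (`"zero"`) is kept for
completeness; under it any crystal with favorable kinks grows without
bound at nominal zero.

**The desk preset** is this package's scaled-down protocol choice:
100,000 cycles, a 5×5×5-cell seed, an initial driving force of 12 kJ/mol
above kink coexistence, descent over the 15–85% span of the run, and a
lattice sized to about one site per cycle (Å-isotropic dimensions). The
reasoning: at 100 kcal/mol every attachment is accepted and growth is
shape-blind; morphological selection happens only where the bias passes
through the window between facet nucleation thresholds, a few kJ/mol wide.
Spending most of the run inside that window is what makes a 10× shorter
simulation morphologically meaningful. Consequently the desk preset is not
a linear shrink of the reference schedule, and its driving force is in the
discriminating regime rather than the nucleation-swamping one.

**Morphology.** Extents are occupied-centroid spans along the **a**, **b**,
**c** directions plus one site diameter. The cross-section perpendicular to
**a** is the convex hull of the projected sites, its edges clustered by
direction (length-weighted, 18° tolerance, dominance at 8% of perimeter):
6 dominant edges → hexagonal, 4 → rectangular (aspect ≤ 2) or lath
(aspect > 2), else irregular. Facets are colored by the spacing method:
each surface site goes to the candidate family (|h|,|k|,|l| ≤ 2, reduced
by sign and common factor) whose supporting plane it lies closest beneath,
depth measured in units of that family's d-spacing, ties at edges resolved
toward the larger d-spacing. This global rule classifies a perfect cuboid
as pure {100} (tested) where local plane fitting tilts near edges.

## 6. What the synthetic data emulate — and what they do not

`synth_beta_guanine()` builds a *synthetic approximation* of the
β-guanine packing motif: monoclinic P2₁/c, Z = 4, a ≈ 3.55 Å stacking axis,
molecular sheets perpendicular to **a** with an idealized planar guanine
tilted 30° about the chain axis, chains along **b** at four z-levels. Its
contact graph reproduces the documented coordination — 12 neighbors within
3.8 Å in 8 symmetry-unique types, among them π-stack (×2), 3H-bond chain
(×2) and an in-plane H-bond dimer link — but its coordinates are idealized
constructions, *not* the published experimental structure, and the CIF
header says so. Anything that depends on true geometry beyond the contact
topology (real d-spacings, lattice-parameter trends with doping) is out of
reach of this fixture.

Interaction energies are qualitative by design: they encode orderings and
ratios (vacuum: 3H-bond 20 > 2H-bond 12 > π-stack 6 kJ/mol per half bond;
water: H-bond desolvation costly, π desolvation favorable, flipping the
ranking; toluene: the reverse, with the π-stack preferring to dissolve;
guests: the 3H chain cut to 0.7× and, for the xan-like guest, the 2H link
to 0.6×), never digitized values. The scales sit at a few to ~20 kJ/mol so
that RT at 300 K is a visible fraction of every interaction — growth
stochasticity is part of the model, not noise to be engineered away.
Passing tests on these fixtures demonstrate that the *mechanisms* (solvent
flips, guest disruption, threshold-driven habit change) behave correctly;
they do not validate absolute energies or absolute growth rates for any
real compound.

The pairwise energy model is extensive and exactly linear in guest count
(additive per-guest contact penalties, xan-like = 2 × hpx-like), so
injected penalties are recoverable from fitted lattice-energy slopes — a
designed-in identifiability check, tested to 5%.

## 7. Numerical conventions and degenerate inputs

* Molecule dedup after symmetry expansion: minimum-image centroid distance
  < 10⁻³ Å; atoms in CIF assembly: 0.05 Å.
* CIF coordinates are written to 8 decimals; write→read round-trips agree
  to better than 10⁻⁶ Å (tested).
* Symmetry-type matching tolerance: 0.1 Å RMSD; label-family reunification:
  0.05 Å in distance, 0.02 in fractional vector components.
* Kabsch requires ≥3 points; reflections are excluded by the determinant
  correction.
* Growth RNG is R's stream (seeded via `set.seed`), so trajectories are
  bit-reproducible per seed; replicate seeds are derived additively and
  stay below 2³¹.
* Degenerate inputs fail loudly: (000) Miller index, non-positive cells,
  empty interaction tables, crystals of ≤2 sites (metrics) or <10 surface
  sites (facets), all-zero energies at zero driving force (pure random
  walk → warning).

## 8. Problem sizes

The shipped analyses use a 2×2×1 supercell (16 sites) with ensembles of up
to 6 members for the thermodynamic chain, and desk-preset growth runs of
10⁵ cycles on lattices of ~10⁵ sites, five seeds per preset — sizes chosen
so the full test suite and the acceptance script each complete in about a
minute while keeping every qualitative contrast (solvent flips, guest
effects, sweep monotonicity) statistically stable across seeds.

## 9. Known limitations

* Electronic energies, phonons and continuum solvation are inputs, not
  computations; the synthetic providers stand in for them.
* Ideal mixing only; no regular-solution corrections, no charged-species
  substitution.
* One growth unit = one rigid molecule; no twinning (the experimentally
  observed chevron habit is out of scope), no dislocation or spiral
  growth, no explicit solution transport.
* The cross-section classifier works on convex hulls; strongly concave
  habits would be labeled irregular.
* On this fixture's geometry, the in-plane b and c growth directions are
  not symmetric even when the 3H and 2H energies are equal (their lattice
  steps differ), so equal-energy sweeps flatten the b/c contrast rather
  than exactly equalizing the extents.
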