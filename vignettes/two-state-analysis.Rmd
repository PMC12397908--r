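---
title: "Analysing two-state proteins: rigid domains, morphing pathways and binding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing two-state proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingeforge)
```

This vignette explains the models behind the package, the parameters
that matter, and the choices made where the methods leave room. The
package addresses a recurring situation in structural biology: the same
protein chain solved in two conformations — typically a free state and
a binding-partner-engaged state related by a hinge rotation of one
domain plus the relocation of a terminal segment — together with
solution binding data (fluorescence titrations, isothermal titration
calorimetry) that characterise the interaction driving the change.

## Rigid-domain detection from difference distance matrices

A conformation is described in internal coordinates by its C-alpha
distance matrix. Because the matrix is invariant under rigid motion,
the element-wise absolute difference between the matrices of two
conformations compares them without choosing any superposition frame —
the step that usually injects arbitrariness into domain analysis.
Residues belonging to one rigid body keep all mutual distances, so the
difference matrix contains near-zero diagonal blocks; entries between
residues of different bodies carry the hinge motion.

`segment_rigid_domains()` converts the difference matrix into an
explicit partition. The algorithm is greedy agglomeration on the graph
whose edges connect residue pairs with `|dD| <= threshold`:

1. contiguous sequence runs are grown as seed blocks (each new residue
   must be within threshold of *every* current member — a quasi-clique,
   not single-linkage, so chains of pairwise-similar residues cannot
   bridge two domains);
2. blocks whose members are all mutually compatible are merged, which
   admits sequence-discontinuous domains (common: a domain interrupted
   by an inserted domain);
3. every residue is re-examined against all blocks and moved to the
   compatible block with the smallest mean difference, strictly-better
   moves only. This pass matters at domain boundaries: a residue
   adjacent to the hinge pivot moves so little that it is compatible
   with both domains, and the first-come contiguous growth would
   otherwise absorb it into the preceding domain. The mean-difference
   rule assigns it to the body it actually travels with (against which
   its mean difference is ~0);
4. blocks smaller than `min_size` are relabelled 0 (flexible).

Defaults: `threshold = 2.0` Å — above the coordinate noise of typical
3–4 Å cryo-EM models, well below hinge-scale distance changes — and
`min_size = 15` residues, small enough to keep genuine subdomains and
large enough to suppress spurious fragments. Neither value has a
published reference standard; both are exposed as arguments and were
validated only against the synthetic ground truth described below. The
emitted partition is re-checked post hoc against its own invariant
(every within-block pair below threshold) and the function fails loudly
if the construction ever violated it.

## Superposition and the interdomain angle

`kabsch()` computes the least-squares proper rotation by SVD of the
weighted covariance matrix, with the standard sign flip of the smallest
singular vector when the unconstrained optimum is a reflection.
Collinear point sets (second singular value numerically zero) are
refused rather than silently returning one of the infinitely many
optima.

The interdomain rotation is reported with the field's three-point
recipe (`interdomain_angle()`): superpose conformation B onto
conformation A over an anchor domain, then measure the angle at a fixed
vertex C-alpha between the tip C-alpha of A and the tip C-alpha of the
superposed B. The vertex is taken from the anchored conformation A (the
"fixed" structure). The measure depends on the chosen anchor range,
vertex and tip; they are arguments, not constants, and the same
residues must be given when comparing numbers between studies. For a
vertex on a perfectly rigid anchor the measure is symmetric under
swapping the conformations; with real coordinates the residual anchor
deformation makes the two directions differ slightly, which is a
property of the measure itself.

Residue correspondence throughout is by author residue number — the two
conformations are the same chain, so sequence alignment would only add
failure modes. Mismatched residue sets use the intersection.

## The iterative dual-endpoint biased morph

Finding a plausible transition pathway between two conformations is
posed here as the iterative dual-endpoint protocol:

1. superpose the current endpoint structures and compute the vector
   between every pair of corresponding C-alpha atoms;
2. for each endpoint, place a per-residue harmonic bias center at the
   residue's own position advanced by `advance` (default 0.1) along its
   vector toward the other endpoint;
3. relax both endpoints under their force field plus the bias;
4. recompute the endpoint-to-endpoint RMSD; repeat until it falls below
   `tol` (default 1.2 Å) or `max_iter` (default 100) is reached.

Running the bias from both endpoints simultaneously and letting the
trajectories meet in the middle is the essential trick: it finds the
pathway requiring the least conformational rearrangement from either
side, instead of forcing one conformation through the other's strain
field. The cost of that bias is also its caveat — the result is *a*
low-rearrangement pathway, with no claim of being the minimum-energy
transition.

The relaxation backend is a C-alpha elastic network: harmonic springs
(`k_enm = 1`, reduced units) between all C-alpha pairs within `cutoff =
10` Å, at their rest lengths in each endpoint's own starting structure,
integrated by overdamped Langevin dynamics (`relax_step()`). At the
default `temperature = 0` this is steepest descent and the whole
protocol is deterministic; a temperature can be set for thermal
sampling, with one seeded stream per endpoint per iteration derived
from the master seed. The engine sits behind `build_enm()` /
`relax_step()` and can be replaced by any minimiser with the same
contract. The step size defaults to the stability bound of the
stiffest mode, `1 / (k_enm * max_coordination + k_bias)`; at
temperature 0 a sustained energy increase (more than 5 consecutive
uphill steps) aborts with advice to reduce the step, rather than
integrating garbage.

Parameter notes, all exposed as arguments:

* `k_bias = 5` (reduced energy/Å²): stiff enough to dominate the
  network locally so endpoints track their advancing centers, soft
  enough not to tear the chain. Bond lengths staying in [2.5, 5] Å
  along all trajectories is asserted in the test suite.
* `advance = 0.1`: each endpoint aims 10% of the remaining gap per
  iteration; with both endpoints moving, the gap contracts by roughly
  20% per iteration, so convergence from ~16 Å to 1.2 Å takes on the
  order of 13 iterations on the benchmark below.
* Stiff limit: with `advance = 0.5` and `k_bias` large the two
  endpoints jump to their common midpoint and the protocol converges in
  one iteration — direct Cartesian interpolation as a degenerate case.
  Note that `advance = 1` in the stiff limit is *not* convergent for a
  symmetric dual-endpoint update: both endpoints would swap
  conformations exactly, leaving the endpoint RMSD unchanged. The
  midpoint form is therefore the meaningful limiting statement for this
  protocol.
* Superposition frame: each iteration superposes B onto A's current
  frame before computing vectors; the frame choice does not affect the
  vectors' magnitudes (superposition removes the rigid part) but fixing
  one makes runs reproducible snapshot-for-snapshot.

`dual_reference_rmsd()` provides the standard trajectory diagnostic:
per-frame minimised RMSD to both endpoint references; for a morph
trajectory the distance to the start grows monotonically while the
distance to the target shrinks, which the test suite checks by rank
correlation.

## Surface areas and interfaces

`sasa()` implements Shrake–Rupley sampling: `n_points` quasi-uniform
points (golden-section spiral) on each atom's probe-expanded sphere,
counting the fraction outside all neighbouring expanded spheres.
Element-keyed van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å, plus common ions), probe 1.4 Å and 960 points are the
community-standard choices; unknown elements are an error unless a
fallback radius is explicitly supplied. Accuracy scales roughly with
`1/n_points`; an isolated sphere is exact, and a two-sphere
configuration agrees with the closed-form spherical cap to well under
2% at 960 points.

`buried_area()` combines three SASA evaluations as
`SASA(group1) + SASA(group2) − SASA(complex)`. Because the literature
is split between reporting this total and reporting half of it (the
convention of interface-analysis servers, counting the interface once
rather than once per partner), the report always carries both numbers;
comparisons against published values must say which convention they
use. Heteroatoms (cofactors, nucleotides) are included with the chain
group that owns them — in complexes where a cofactor lines the
interface, excluding it would misstate the buried area.

## Binding models

**Quadratic (ligand-depletion) titration.** When the fluorophore
concentration is comparable to the dissociation constant, the
hyperbolic isotherm is biased; the exact 1:1 solution is

$$f_\mathrm{bound} = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2L}$$

with the signal interpolating between `F_free` and `F_bound`. The
model collapses to the hyperbola as `L -> 0` (checked to 0.1% at
`L = Kd/1000`). Concentrations are treated as monomer concentrations
throughout; if a dimer is the binding unit, convert before fitting.

**One-set-of-sites ITC.** Cumulative heat after injection *i* follows
the single-class isotherm in the dilution-corrected total
concentrations, with each injection of volume `dV` into the overfilled
cell of volume `V0` diluting the existing contents by `(1 − dV/V0)`
(applied cumulatively) and the observed per-injection heat carrying the
displaced-volume term `(dV/V0)(Q_i + Q_{i-1})/2`. `V0` defaults to
200 μl, the nominal cell volume of the small-cell calorimeter class the
default injection schedule (18 × 2 μl, 70 μM cell, 700 μM syringe)
belongs to; both are arguments. The Wiseman `c`-value
(`n·M_t/Kd`) is reported, with a warning outside [1, 1000] where the
isotherm shape pins Kd poorly.

**Fitting.** Both fitters use Levenberg–Marquardt least squares
(`minpack.lm`) with positivity bounds on `Kd` (and `n`), multi-started
from five log-spaced `Kd` values to avoid local minima; the converged
start with the smallest residual sum of squares wins. Standard errors
come from the local covariance. Degenerate inputs fail informatively:
a constant titration signal and an all-zero isotherm are reported as
unidentifiable rather than fitted, and a `Kd` pinned at its bound is
flagged.

## The synthetic-data module

`make_hinge_protein()` is the package's ground truth. It emulates the
geometry the analyses assume: two rigid segments laid out as idealised
helix-like C-alpha curves (rise 1.5 Å, 100° turn per residue, radius
2.3 Å — consecutive spacing ~3.83 Å), joined at a hinge residue, with
the second conformation produced by an exact rigid rotation of segment
2 about an axis through the hinge C-alpha. The axis is chosen
perpendicular to the hinge-to-segment-centroid vector so the
constructed rotation equals the measured centroid angle, and the
in-plane rotation direction points away from segment 1; the arm leaves
the hinge perpendicular to the first segment, which keeps every hinge
angle in [0, 180) free of steric clashes (a generated conformation
with non-neighbour C-alpha contacts under 2 Å is regenerated with
seeded axis jitter, at most 10 times). An optional C-terminal tail is
additionally rotated to a distinct docking site, emulating a terminal
segment that swaps binding pockets between states.

Helical curves rather than straight lines matter twice: they produce
realistic banded distance matrices, and they avoid the collinear
degeneracy of the superposition problem.

What the generator does *not* emulate: side chains, sequence effects,
coordinate noise (conformations are exactly rigid, so difference
matrices are exactly zero within blocks), partial/gradual flexibility
between domains, and more than two rigid bodies plus one tail. Passing
the recovery tests therefore demonstrates the machinery is correct on
clean geometry, not that the default threshold is optimal for a noisy
experimental model — for real structures the threshold should be read
together with the map resolution.

`simulate_titration()` and `simulate_itc()` add i.i.d. Gaussian noise
to the exact models (defaults for demonstration fixtures: 1% of signal
range, 2% of the largest heat). Real instruments show drift and
heat-of-dilution backgrounds that are not modelled; subtract them
before fitting.

## Validation design and problem sizes

The test suite checks every operation against an independent oracle
where one exists: superposition against Horn's quaternion-eigenvalue
method, distance matrices and contact counts against brute-force double
loops, surface areas against closed forms (isolated sphere, two-sphere
caps, caged atom), ITC heats against the stoichiometric and saturation
limits and against differentiation of the cumulative heat, and the
whole simulate-and-fit loop against the generating parameters.

The standard benchmark sizes, chosen to exercise every code path while
keeping the full suite fast enough to run on every change: 120-residue
hinge pairs (60 + 48 + 12-residue tail) for the morph, 60 + 60 pairs
swept over hinge angles 20–160° for segmentation recovery, and the
titration/ITC layouts above for the fitters. Noiseless fits recover
their generating constants to fractions of a percent. For noisy
recovery the package emulates the usual laboratory protocol of three
replicate experiments with the estimate averaged over replicates; at 2%
Gaussian noise the median relative Kd error across seeds stays within a
few percent for both models, which is consistent with the information
content (Cramér–Rao bound) of these experiment designs — a single
noisy 18-injection isotherm at high `c` genuinely cannot localise Kd
much better than ~10%, and no fitter should claim otherwise.

## Limitations

* The elastic-network morph yields geometrically plausible, chain-intact
  pathways, not free-energy-ranked ones; no solvent, side chains or
  electrostatics.
* Difference-matrix segmentation assumes exactly two input
  conformations; multi-state consensus domains are out of scope.
* SASA uses a fixed element-keyed radius table; no implicit hydrogens
  beyond the heavy-atom radii, no per-residue parameter sets.
* The binding fitters handle one site class and single experiments; no
  competitive models, no global multi-experiment fits, no raw
  thermogram integration.
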