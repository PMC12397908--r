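# hingeforge

Tools for analysing proteins that switch between two conformations, and
for fitting the binding experiments that usually accompany such studies.
The package grew out of the analysis needs of hinge-motion enzymes — a
protein captured in two states (e.g. the free and the complex-bound
subunit of a homodimer), where one wants to know *which parts moved*,
*by how much*, *along which pathway*, and *how the accompanying binding
equilibria changed*.

It is aimed at structural biologists and biophysicists who have two
coordinate sets of the same chain (PDB or mmCIF) and/or titration data,
and want scripted, reproducible answers rather than point-and-click
tools.

## What it computes

**Rigid domains from difference distance matrices.** For C-alpha traces
of the two conformations, the intra-molecular distance matrices `D_A`
and `D_B` are compared element-wise; `|D_A − D_B|` is independent of any
superposition, and near-zero blocks mark residues that move as one rigid
body. `segment_rigid_domains()` turns the difference matrix into an
explicit partition (greedy agglomeration with a within-block threshold,
default 2 Å, minimum block size 15).

**Superposition geometry.** `kabsch()` (SVD with determinant
correction), minimised RMSDs, the three-point interdomain rotation angle
(`interdomain_angle()`: superpose on an anchor domain, measure the angle
at a fixed vertex Cα between the two positions of a tip Cα), and
selected atom-pair distances.

**Transition pathways by iterative dual-endpoint biased morphing.**
`biased_morph()` runs the iterative protocol: superpose the two current
endpoint structures, compute the vector between every pair of
corresponding Cα atoms, advance a harmonic bias center a fraction of the
way along each vector, relax both endpoints under an elastic-network
potential plus the bias, and repeat until the endpoint RMSD drops below
a tolerance (default 1.2 Å). Both trajectories and the RMSD series are
returned; `dual_reference_rmsd()` gives the standard two-reference
trajectory diagnostic.

**Interfaces.** Shrake–Rupley solvent-accessible surface areas
(`sasa()`), buried interface area between two chain groups in both
conventions (total buried and the halved "interface area"), and contact
lists.

**Binding models.** The quadratic (ligand-depletion) equation for
fluorescence titrations,

    f = [(P + L + Kd) − sqrt((P + L + Kd)² − 4·P·L)] / (2L)

and the one-set-of-sites ITC isotherm with the displaced-volume
correction, each as simulator (`simulate_titration()`, `simulate_itc()`)
and Levenberg–Marquardt fitter (`fit_quadratic()`, `fit_itc()`) with
multi-start initialisation.

A synthetic-data module (`make_hinge_protein()`) builds two-conformation
hinge proteins with known rigid-block labels, hinge angle and an
optionally relocating C-terminal tail, so every analysis stage can be
validated against ground truth.

## Worked example

```r
library(hingeforge)

# a 120-residue two-conformation protein: 60-residue anchor, 48-residue
# mobile segment rotated by 60 degrees, 12-residue relocating tail
hp <- make_hinge_protein(n1 = 60, n2 = 48, hinge_angle = 60,
                         tail_len = 12, seed = 1)

dd <- difference_matrix(ca_distance_matrix(hp$confA),
                        ca_distance_matrix(hp$confB))
segment_rigid_domains(dd)
#> domain_segmentation: 2 rigid block(s), 12 unassigned of 120 residues (threshold 2.00 A, min size 15)
#>   block 1 (60 residues): 1-60
#>   block 2 (48 residues): 61-108

interdomain_angle(hp$confA, hp$confB, anchor = 1:60,
                  vertex_res = 60, tip_res = 84)
#> [1] 59.9687  # degrees: the constructed hinge rotation, recovered

biased_morph(hp$confA, hp$confB, seed = 1)
#> morph_result: converged after 13 iteration(s); endpoint RMSD 1.134 A (initial 16.339 A)

# binding: simulate a noisy titration and fit it back
tc <- simulate_titration(Kd = 74, L_total = 1, P_series = 400 / 2^(0:11),
                         sigma = 7.5, seed = 2)
fit_quadratic(tc)
#> quadratic binding fit: Kd = 73.56 +/- 3.4 uM (F_free 1004, F_bound 248.1, rss 468.6)

fit_itc(simulate_itc(Kd = 0.42, n = 0.6, dH = -10, seed = 2))
#> one-set-of-sites ITC fit: Kd = 0.37 +/- 0.064 uM, n = 0.598 +/- 0.0053, dH = -9.97 kcal/mol (c = 113, rss 1.529)
```

The two rigid blocks are exactly the generator's segments, the
12-residue tail is left unassigned (below the minimum block size), the
morph meets the 1.2 Å stopping rule in 13 iterations, and the fitted
binding parameters recover the simulated ones within their standard
errors.

## Documentation

The methods vignette (`vignettes/two-state-analysis.Rmd`) describes the
models, the numerical choices and the limitations in detail.
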