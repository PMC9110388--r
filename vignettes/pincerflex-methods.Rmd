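---
title: "Models and methods behind pincerflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pincerflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pincerflex` studies large inter-domain motions of multi-domain "pincer"
proteins with a combination of crystal-structure geometry, elastic-network
normal modes, coarse-grained enhanced sampling, and multi-state SAXS
fitting.  This vignette explains the models, the tunable parameters and the
numerical choices, and states what the synthetic test bed does and does not
demonstrate.

## Collective variables

A four-domain pincer is summarised by two collective variables (CVs):

* **CV1** — the distance (Å) between the mass-weighted centers of mass
  (COM) of the first and the fourth domain ("opening").
* **CV2** — the torsion (degrees) of the four domain COMs, IUPAC
  convention, wrapped to (−180, 180] ("sideways" swing).

Centers of mass are computed over the heavy atoms present in the model
(hydrogens are absent from crystal structures anyway), mass-weighted by
default with a geometric option; for structures missing short terminal
segments the COM and Rg shift by a few tenths of an Å, which is why the
crystal-geometry checks carry a ±0.5 Å allowance.  Torsions of collinear
COM triples are reported as an explicit degenerate-geometry error rather
than a number.  Because deposited sign conventions vary, comparisons of
CV2 against published values are made on |CV2|.

Analytic CV gradients (chain-rule through the COMs, standard
four-point torsion derivative) drive both the biased sampling and the
classification of normal modes; they are verified against central finite
differences at 1e−6 accuracy in the test suite.

## The coarse-grained pincer and its imposed landscape

`build_pincer()` builds four quasi-rigid bead domains (default 20 beads of
25 Da and 3 Å radius in a 10 Å cloud) on a three-arm linker chain: the four
domain COMs are connected in sequence by stiff harmonic bonds of rest
length `arm` (default 46 Å).  On top of the bonded terms, the model carries
a CV-space potential

$$U(d,\varphi)\;=\;\sum_k -A_k\,
\exp\!\Big(-\tfrac{(d-d_k)^2}{2\sigma_{d,k}^2}
           -\tfrac{\Delta(\varphi-\varphi_k)^2}{2\sigma_{\varphi,k}^2}\Big)
\;+\;V_{\text{wall}}(d)\;+\;U_{\text{comp}}(d,\varphi),$$

with Δ the periodic angle difference and one-sided walls
$V = k(x-x_0)^p$ (defaults: bounds 41 and 75 Å, k = 0.36 kcal/mol/Å²,
p = 2).  The `abna-landscape` preset places wells at
(55 Å, −63°), (50, 27), (67, −63), (74, 45) with relative depths
0 / 1.2 / 2.5 / 8.2 kcal/mol below a common baseline (`base_depth`,
default 9 kcal/mol, so the shallow shoulder well keeps a positive
amplitude), and common widths σ_d = 2.5 Å, σ_φ = 18°.

**Entropy compensation.**  A three-arm chain has its own configurational
entropy in (d, φ): with near-rigid arm lengths the internal measure is flat
in (cos θ₁, cos θ₂, φ), which makes the marginal density of d at given φ
non-uniform by several tenths of a kcal/mol across the wall-bounded range.
The model therefore includes $U_{\text{comp}} = k_BT\,\log P_0(d\mid\varphi)$,
where P₀ is tabulated once at build time by quadrature over the chain
measure (481² grid per φ slice, 0.5 Å bins, light smoothing).  With this
term the marginal free energy of the dynamical system equals the configured
well landscape *exactly*, which is what makes the parameter-recovery tests
well-posed: a brute-force reweighting test confirms flatness of the
compensated measure to < 0.1 kcal/mol.  The compensation is part of the
model definition, reported alongside wells and walls.

**Geometry sizing.**  The arm length (46 Å) and domain cloud radius (10 Å)
were chosen once so that (i) inter-domain COM distances span the
wall-bounded 40–80 Å range with margin, and (ii) the preset's 3-state
mixture scatters with a Guinier Rg of ≈ 35.4 Å when the 2.5 Å hydration pad
is on — the experimental scale of a ~36 Å multi-domain enzyme.  Per-state
radii of gyration come out at ≈ 33 / 34 / 36 / 38 Å for the four wells.

## Sampling

Dynamics are BAOAB-split Langevin in internal units
(Å, Da, kcal/mol; time unit ≈ 48.9 fs), implemented in C++ with a fully
specified RNG (xoshiro256** with explicit Box–Muller), so fixed-seed runs
are bit-reproducible.  Defaults: dt = 0.5 (≈ 25 fs-equivalent), T = 300 K
(k_BT = 0.596 kcal/mol), friction 0.02 per time unit.  The light beads and
weak friction are deliberate: the slowest relaxation is the torsion φ,
whose lever arm is ~30 Å, and configurational sampling in Langevin dynamics
is correct at any friction.  A time step exceeding a tenth of the stiffest
bond period triggers a warning.

**Metadynamics.**  Gaussian hills are deposited along (d, φ) every
`stride` steps and accumulated — value and analytic gradient — on a
periodic grid, so the per-step cost does not grow with the hill count.
The reference all-atom protocol for this landscape used hills of height
0.289 kcal/mol and widths 0.2 Å / 0.07 rad every 20 ps, accumulating
~5.6·10⁴ hills over 1.12 µs.  Hills that narrow cannot fill a
48 Å × 2π landscape within the ~10⁵-hill budget of a desk-scale run (the
deposited bias volume falls two orders of magnitude short), so the package
defaults keep the height and rescale the footprint to the coarse-grained
diffusion scale: σ_d = 1.2 Å, σ_φ = 0.15 rad, stride 100 steps.  The wall
parameters are kept at the reference values.  Because the walls are soft
(0.36 kcal/mol/Å²) and deposition continues after the interior is filled,
the late-stage trajectory slowly leaks a few Å beyond the walls; this
wastes some sampling but does not bias interior free-energy differences.
Two further numerical guards: the bias exists only on its grid (outside,
the walls act alone), and the four-point torsion gradient — singular at
collinear COM triples — is clamped at 0.5 rad/Å so rare near-degenerate
passages cannot kick the system ballistically through the walls.

**FES reconstruction.**  In fixed-height metadynamics the negative
accumulated bias estimates the free energy up to a constant, oscillating
with an amplitude of roughly the hill height.  `fes_from_bias()` therefore
averages the estimator over 25 checkpoints spanning the final 60% of the
deposition history and shifts the minimum to zero; bins that received
essentially no bias are flagged unset (NA), never zero.  The averaging
window matters: windows that reach back into the filling (pre-diffusive)
stage bias all relative free energies towards zero, which is visible when
the window fraction is raised on short runs.

**Well ΔΔG estimators.**  `fes_well_ddg()` reports, per configured well,
the minimum of the surface within 1.5 well widths of the center
(`method = "min"`, the default — the value a microstate table assigns to
the well bottom).  The alternative basin integral
$-k_BT\log\sum e^{-F/k_BT}$ is smoother under bin noise but biased low for
shallow wells by the basin-entropy term $k_BT\log(A_1/A_k)$ (≈ 1.4 kcal/mol
for the 0.8 kcal/mol shoulder well), so it is not the default.

**Microstates.**  The sampled CV space is discretised into 20 bins per CV
over the FES extent; each visited bin is a microstate carrying the FES
value at its bin center, its member frames, and a representative frame
(nearest the bin center in bin-width-scaled units among frames with stored
coordinates).  Contiguity is 4-neighbour connectivity on the grid; relative
free energies are reported for the connected component containing the
global minimum.  Microstate *counts* depend on run length and bin edges
and are not treated as reproducible observables.

**Convergence.**  `convergence_report()` tracks CV range coverage per
trajectory quarter and the maximum |ΔF| between successive late FES
checkpoints, flagged against tolerances of 5 and 1.8 kcal/mol by default.
This checkpoint-difference diagnostic is a stand-in for block-average
convergence estimators; it is not claimed to reproduce any particular
toolkit's statistic.

## Elastic-network modes

`build_hessian()` is the standard anisotropic network model: nodes are one
site per residue (Cα for atomic structures, beads for the surrogate),
springs of uniform γ connect nodes within a cutoff, off-diagonal 3×3 blocks
are −γ r̂r̂ᵀ and diagonals minus the row sums.  Eigendecomposition is dense
(base `eigen`), sensible up to ~1000 nodes; the six rigid-body modes are
flagged by a relative threshold and excluded from nontrivial indexing.
Internal-coordinate (dihedral-space) modes are out of scope: the package's
claims are about Cartesian mode/displacement overlap only.  The default
cutoff (15 Å) suits Cα spacing; the bead surrogate's domains sit ~46 Å
apart, so network analyses of the surrogate use a cutoff large enough to
bridge neighbouring domains (36 Å in the tests) — with a disconnected
network every extra component adds rigid modes and the function warns.

`classify_motion()` projects a mode's Domain4 sub-vector onto the Domain4
sub-vectors of the two CV gradients and labels it "opening" or "sideways"
when one |projection| exceeds 1.5× the other, else "mixed"; the threshold
is a parameter.  Agreement between slow modes and an observed displacement
is quantified by cumulative overlap and judged against a null of random
unit vectors (95th percentile), not by mode indices, because mode ordering
is parameter-sensitive.

## SAXS

The Debye sum is evaluated exactly over pairwise distances with the q → 0
limit handled analytically; atomic models are reduced to one center per
residue (COM position, summed electron count) before summation, and a guard
rejects inputs above 5000 centers.  Coarse-grained beads can carry a
uniform homogeneous-sphere form-factor amplitude; the optional hydration
pad inflates that radius by 2–3 Å for comparisons with experimental-scale
radii of gyration and is off by default.  Computed curves are interpolated
linearly in q onto experimental grids and never extrapolated; fits require
at least 80% grid overlap.

`guinier_fit()` iterates the fit window to the fixed point
q_max·Rg ≤ 1.3 and reports the adjusted R² with a pass flag at the > 0.995
rule used to screen aggregation.  `porod_debye()` summarises the q⁴I vs q⁴
tail (final third of the grid) by a dimensionless plateau index — the
|slope| times the tail's q⁴ span over the mean q⁴I — near zero for an
ideal q⁻⁴ scatterer and larger for flexible particles; for the surrogate
the rigid reference must be a *compact* particle (a dense sphere), since
an open bead pincer has no Porod regime in the measured window.

`multistate_fit()` enumerates candidate subsets up to k_max (pool capped
at 20) and solves each for non-negative populations by NNLS
(`pracma::lsqnonneg`) on σ-whitened intensities; the weight vector is
normalised to the simplex with the overall scale c carrying the remainder,
which matches the χ definition with a single free scale.  χ is
non-increasing in k by construction, so `select_k()` picks the smallest k
whose successor improves χ by less than 5% (relative).

## The demonstration pipeline

`run_integrative_demo()` chains the stages with seeds derived from one
master seed: build the preset model → metadynamics (default 2·10⁶ steps,
frames every 1000) → FES + convergence + microstates → representative
conformer per well → synthetic 3-state experiment (populations
60.7/31.4/7.9%, σ(q) = 0.01·I(q)) generated *from the sampled
representatives* → multi-state fit, model selection, weight RMSE and
population-weighted Rg.  Generating the experiment from the sampled
representatives (rather than idealised templates) makes the validation
stage test exactly what the scoring stage produced.  All artifacts can be
persisted as plain text (hills table, profile, config, report).

## Problem sizes and what the tests show

The shipped checks run at desk scale: metadynamics recovery uses three
seeds of 10⁷ steps (a few minutes on one CPU) and recovers the
configured 1.2 and 2.5 kcal/mol well offsets within ±0.5 kcal/mol with the
8.2 kcal/mol shoulder ranked highest; weight recovery uses 200-point
profiles at 1% noise.  The surrogate emulates the *statistical structure*
of the real problem — a rugged 2-D free-energy landscape, conformers
distinguishable by scattering, honest noise models — but not its physics:
there is no solvent, no side-chain packing, no hydration-layer scattering,
domains are internally rigid, and the landscape is imposed rather than
emergent.  Passing tests therefore demonstrate that the estimators and
fits recover known ground truth under realistic noise, not that any
particular protein's landscape has these values; conclusions about a real
system require its own structures and measured scattering curves.

## Design notes

* The fitting surfaces (`multistate_fit`, `guinier_fit`) follow the
  classic R modelling idiom — a classed object with `print`, `summary`,
  `coef`, `fitted`, `residuals`, `predict`, `plot` methods — while the
  simulation stages are pipeline functions returning typed S3 containers.
* PDB parsing is delegated to `bio3d` behind `read_structure()`, with a
  pre-scan that reports malformed fixed-column records by line number;
  alternate locations resolve to the highest-occupancy conformer with
  first-listed tie-break.
* SASA is Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points, probe 1.4 Å, Bondi element radii or per-bead radii),
  so areas are exactly reproducible.
* The Kabsch superposition is implemented directly (the rotation matrix is
  needed for the Domain4 internal-rotation angle, defined as the angle of
  the Domain4-only rotation after global Domain1 alignment) and is
  cross-checked against a rotation-grid search oracle in the tests.
* Element data (masses, electron counts, van der Waals radii) cover the
  elements found in protein crystal structures; unknown elements error by
  name rather than defaulting silently.
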