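# pincerflex

Integrative conformational analysis of multi-domain "pincer" proteins in R.

Many carbohydrate-active enzymes are ultra-multimodular: a catalytic domain
and one or more carbohydrate-binding modules connected by flexible linkers.
Crystal structures of such proteins catch isolated conformational states,
while in solution the domains move tens of Angstroms relative to each
other.  `pincerflex` implements the computational core of the integrative
workflow used to characterise such motions for a four-domain GH43
arabinanase: crystal-state geometry, elastic-network normal modes,
enhanced-sampling simulation of a coarse-grained surrogate, free-energy
surface reconstruction, and multi-state fitting of small-angle X-ray
scattering (SAXS) data — plus a synthetic-data generator so the entire
pipeline is testable on a desk without external data.

## What it computes

* **Collective variables.** The pincer's conformation is summarised by
  CV1 = |COM(Domain1) − COM(Domain4)| (the opening distance, Å) and
  CV2 = the torsion of the four domain centers of mass (the sideways
  swing, degrees).  `cv_pair()`, `radius_of_gyration()`, `superpose()`
  (Kabsch), `sasa()` / `buried_interface_area()` (Shrake–Rupley) operate
  on PDB structures read with `read_structure()`.
* **Normal modes.** `build_hessian()` assembles the anisotropic-network
  Hessian (off-diagonal blocks −γ·r̂ᵢⱼr̂ᵢⱼᵀ within a cutoff);
  `normal_modes()`, `mode_overlap()` and `classify_motion()` label the
  slow motions as "opening", "sideways" or "mixed".
* **Coarse-grained metadynamics.** `build_pincer()` creates a four-domain
  bead model whose free-energy landscape over (CV1, CV2) is a configured
  sum of Gaussian wells; `metad_run()` performs BAOAB Langevin dynamics
  with Gaussian-hill bias deposition and one-sided restraining walls
  (`V = k(x−x₀)^p`); `fes_from_bias()` reconstructs the surface as the
  negative time-averaged bias; `bin_microstates()` discretises the sampled
  CV space into 20×20 microstates with relative free energies ΔΔG.
* **SAXS.** `debye_profile()` (Debye sum `I(q) = Σ fᵢfⱼ sin(qr)/(qr)`),
  `guinier_fit()` (ln I vs q² with the q·Rg ≤ 1.3 window rule),
  `pr_from_structure()`, `porod_debye()` flexibility index, `chi_fit()`,
  and `multistate_fit()` — subset enumeration plus non-negative least
  squares for population weights, ranked by
  `χ = sqrt(mean(((Iₑ − c·I_c)/σ)²))`.
* **Pipeline.** `run_integrative_demo()` chains
  generate → sample → score → validate with one master seed;
  `crystal_geometry_report()` compares conformational states
  (CVs, Rg, buried interface, Domain4 displacement and rotation after
  Domain1 alignment).

## Worked example

```r
library(pincerflex)

model <- build_pincer()            # the four-well pincer landscape
run   <- metad_run(model, n_steps = 5e6, seed = 1,
                   frame_stride = 1000, cv_stride = 100)
fes   <- fes_from_bias(run$bias)
round(setNames(fes_well_ddg(fes, model$wells), model$wells$name), 2)
#>  EM1  EM2  EM3  EM4
#> 0.00 1.28 2.53 7.85

# synthetic 3-state SAXS experiment and its multi-state fit
states <- lapply(c("EM2", "EM3", "EM4"), function(nm) {
  w <- model$wells[model$wells$name == nm, ]
  conformer_structure(model, w$d, w$phi)
})
experiment <- synthetic_saxs_experiment(
  mixture_spec(states, c(0.607, 0.314, 0.079), noise_a = 0.01),
  seed = 2, bead_radius = model$bead_radius)
profs <- lapply(states, debye_profile, q_grid = default_q_grid(),
                bead_radius = model$bead_radius)
multistate_fit(experiment, profs, k_max = 3)
#> Multi-state SAXS fit (non-negative weights, optimal scale):
#>   k = 1: states {1}, weights 100.0%, chi = 3.024
#>   k = 2: states {1,2}, weights 60.5%/39.5%, chi = 1.278
#>   k = 3: states {1,2,3}, weights 61.8%/30.9%/7.3%, chi = 1.066
#> Best: k = 3 (chi = 1.066)
```

The recovered well free energies (0 / 1.28 / 2.53 / 7.85 kcal/mol) match
the landscape the generator was configured with (0 / 1.2 / 2.5 / 8.2), and
the 3-state fit recovers the generating populations (60.7/31.4/7.9 %) to
within a percent with χ ≈ 1, i.e. at the level of the injected 1% noise.
`ensemble_rg()` then gives the population-weighted mean radius of gyration
of the fitted ensemble.

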