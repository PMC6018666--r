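# metafold

Integrative refinement of a protein-RNA complex from solution data, at
desk scale.

## The problem

Tandem-domain RNA-binding proteins such as hnRNP A1 recognize
single-stranded RNA through two RRM domains connected by a flexible
linker. A crystal structure fixes the domain folds and the RNA-binding
interfaces, but the solution arrangement of the two domains — and the
solution stoichiometry and binding thermodynamics — must come from
solution measurements: small-angle X-ray scattering (SAXS), amide
residual dipolar couplings (RDCs), paramagnetic relaxation enhancements
(PRE), chemical shift perturbations, static light scattering and
isothermal titration calorimetry (ITC). `metafold` implements the
computational core of such a study for R users: forward models for the
observables, a Bayesian hybrid score, a simulated-annealing refiner, the
thermodynamic analyses, and a seeded synthetic-data module that generates
every input with known ground truth so the whole pipeline can be
validated end to end.

## The models at the core

* **SAXS forward model** — the Debye double sum
  `I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij)/(q r_ij)` with 4-Gaussian
  Cromer–Mann form factors and a Fraser dummy-atom excluded-solvent
  correction (`debye_intensity()`, compiled kernel; `debye_reference()`
  is the independent plain-R path). Measured curves are reduced to 43
  *representative intensities* by a degree-16 polynomial fit evaluated on
  the grid 0.03–0.45 Å⁻¹ (`prepare_representative_intensities()`).
* **Metainference score** — a Gaussian likelihood per representative
  intensity, `E = Σ (λ f_i − d_i)²/(2σ_i²) + log σ_i`, with a scale
  nuisance λ under a flat prior on [0.9, 1.1], combined with harmonic
  upper-wall restraints (ring-stacking interfaces at 3.5 Å, salt bridges
  at 4 Å, per-segment secondary-structure RMSD at 0 Å) and a minimal
  physical term.
* **RDC analysis** — Saupe-tensor fitting by SVD with Q-factor and
  correlation (`fit_tensor_svd()`), and the refinement-time restraint
  `E = −20000 × cor(D_calc, D_exp)` kJ/mol applied to couplings averaged
  over two replicas (`rdc_correlation_energy()`).
* **Refinement** — simulated-annealing Monte Carlo over rigid-body and
  linker-torsion moves, temperature cycling 300→100→300 K, data terms at
  a 10-step stride, and selection of the lowest-metainference-energy
  sample from the final cycles (`run_annealing()`, `select_refined()`).
* **ITC** — one-site injection heats with displaced-volume dilution and
  weighted Levenberg–Marquardt fitting of (N, K_D, ΔH), with
  ΔG = RT ln K_D and ΔS = (ΔH − ΔG)/T at R = 1.987 cal/(mol K)
  (`one_site_heats()`, `fit_one_site()`, `kd_from_enthalpy_entropy()`).
* **NMR observables** — combined CSPs, exponential relaxation fits with
  duplicate-delay error propagation, and PRE r⁻⁶ distances
  (`combined_csp()`, `fit_relaxation()`, `pre_distance()`).

## Worked example

Refine a perturbed toy complex against its own synthetic SAXS and RDC
data:

```r
library(metafold)

res <- run_pipeline(default_config(seed = 1))
```

The run takes a few tens of seconds and prints nothing by default
(`verbose = TRUE` logs one line per annealing cycle); the returned object
and the files in the run directory carry the results:

```r
res$rmsd_start    # 8.00  — backbone RMSD of the perturbed start (Å)
res$rmsd_refined  # 1.45  — after refinement and selection (Å)
res$report$rdc    # Q = 0.338, r = 0.940 for the refined model
```

Validating the ground-truth and start models against the same data shows
what those numbers mean: the truth scores chi = 1.03 (consistent with
the 2% noise), Q = 0.065, r = 0.998 and zero restraint energy, while the
8 Å start scores chi = 23.3, Q = 0.645, r = 0.765 and a restraint energy
of ~2×10⁵ kJ/mol. Refinement recovers most of that gap from the data
alone.

The thermodynamic side, using the published titration table as presets:

```r
fit_one_site(simulate_itc("UP1+12-mer", noise_frac = 0))
#> One-site fit: N = 1.010, K_D = 1.55e-08 M, dH = -3.81e+04 cal/mol
#>   dG = -1.065e+04 cal/mol, dS = -92.06 cal/mol/K (T = 298.15 K), c = 1.3e+03

itc_consistency()       # K_D recomputed from each row's dH and dS
complex_mass()$complex_kDa
#> 26.1  — theoretical 1:1 protein+RNA mass (kDa), cf. 26.3 from SLS
```

## Documentation

The methods vignette (`vignettes/metafold-methods.Rmd`) documents the
models, their assumptions, every tunable parameter with its default and
unit, the synthetic-data study conditions, and the package's known
limitations.
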