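---
title: "Integrative refinement of a protein-RNA complex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative refinement of a protein-RNA complex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafold)
```

# Scope

`metafold` implements a desk-scale integrative structure-determination
pipeline for a two-domain RNA-binding protein bound to a single-stranded
RNA. The scientific setting is the tandem-RRM fragment of hnRNP A1 (UP1,
residues 1-196) recognizing two UAG motifs of a 12-mer RNA derived from
the pri-mir-18a terminal loop: a high-resolution crystal structure fixes
the domain folds and the RNA-binding interfaces, while solution data --
SAXS curves, amide residual dipolar couplings (RDCs), PRE profiles and
calorimetric titrations -- determine the domain arrangement, the solution
stoichiometry and the binding thermodynamics. Everything here runs on a
synthetic toy complex with known ground truth, so each stage of the
pipeline can be validated end to end without external data.

# Forward models

## SAXS by the Debye formula

The orientationally averaged scattering intensity of an atomic model is
the exact double sum

$$ I(q) \;=\; \sum_{i}\sum_{j} f_i(q)\, f_j(q)\,
   \frac{\sin(q r_{ij})}{q r_{ij}}, $$

with $\sin(x)/x \to 1$ as $x \to 0$. Atomic form factors $f_i(q)$ use the
4-Gaussian Cromer-Mann parametrization; the solvent is handled by the
Fraser dummy-atom correction, subtracting a Gaussian excluded-volume term
$\rho_s V_i \exp(-V_i^{2/3} q^2 / 4\pi)$ with bulk density
$\rho_s = 0.334\,e/\mathrm{\AA}^3$. No hydration-shell term is modelled;
this is a documented fidelity limit (shell contrast matters most above
$q \approx 0.2\,\mathrm{\AA}^{-1}$ for real data, and the synthetic data
are generated by the same forward model, so the pipeline's internal
consistency is unaffected). The production evaluator is a compiled kernel;
an interpreted-R implementation (`debye_reference()`) provides an
independent path used for validation, and the test suite additionally
compares both against a literal naive double loop on small random models.

## Representative intensities

Measured curves are reduced to *representative intensities* before
restraint use: the intensities up to $0.5\,\mathrm{\AA}^{-1}$ are fitted
with a 16th-degree polynomial (after rescaling $q$ to $[-1,1]$ and using
an orthogonal basis, which keeps the normal equations well conditioned),
and the fit is evaluated on the regular grid
$0.03$-$0.45\,\mathrm{\AA}^{-1}$ in steps of $0.01$, giving 43 points.
This smooths counting noise while preserving the curve shape; the
per-point restraint then acts on a small, information-dense set rather
than on hundreds of correlated raw points. An approximate
experiment-to-model scale is estimated once as the mean ratio of
experimental to calculated intensities; a residual scale nuisance is
sampled during refinement (below).

## RDCs and the alignment tensor

For validation and reporting, couplings are fitted by singular value
decomposition of the 5-parameter Saupe problem
$D_i = \mathbf{b}_i^{\mathsf T} S\, \mathbf{b}_i$ over unit bond vectors,
with the dipolar prefactor and bond length absorbed into the tensor scale
(so the tensor is reported in Hz and no N-H bond length needs to be
assumed). Quality is summarized by
$Q = \sqrt{\sum (D^\mathrm{calc}-D^\mathrm{exp})^2 / \sum (D^\mathrm{exp})^2}$
and the Pearson correlation. An independent normal-equation solver
cross-checks the SVD path.

During refinement the tensor is *not* refit: following the
correlation-restraint approach, couplings are back-calculated under a
fixed axial tensor and a linear energy
$E = \mathrm{slope} \times r(D^\mathrm{calc}, D^\mathrm{exp})$ with slope
$-20000$ kJ/mol rewards correlation with the measured couplings. Because
Pearson correlation is invariant to affine rescaling, the fixed tensor's
magnitude is immaterial. To account for multiple possible alignments of
the complex in the medium, the restraint acts on the *average* couplings
of two replicas, each replica carrying every other restraint
independently; this is also why the restraint is deliberately softer than
a per-structure tensor fit.

# The hybrid energy

## Metainference SAXS term

The representative intensities enter a Bayesian score with a Gaussian
likelihood per data point,

$$ E = \sum_i \left[ \frac{(\lambda f_i - d_i)^2}{2\sigma_i^2}
       + \log \sigma_i \right], $$

in the no-replica, zero-ensemble-error limit in which metainference
reduces to inferential structure determination. The scale nuisance
$\lambda$ carries a flat prior on $[0.9, 1.1]$ and is updated by
Metropolis-within-Gibbs moves; proposals outside the prior are rejected
before evaluation. Two uncertainty modes are provided: a fixed
$\sigma_i$ per point (deterministic, used by default and in tests) and a
sampled global $\sigma$ scale with a Jeffreys prior, initialized large so
the data restraint tightens gradually over the run.

## Structural restraints

Three restraint types mirror the information a crystal structure
contributes, all as one-sided harmonic *upper walls*
$E = k\,(v - c)^2$ for $v > c$ (no $\tfrac12$ factor; continuous and
once-differentiable at the wall):

* **Stacking interfaces** -- distances between aromatic ring centroids of
  each Phe/nucleotide recognition pair, center 3.5 A, $k = 1000$ kJ/mol.
* **Salt bridges** -- the minimum distance between Arg guanidinium
  nitrogens and Asp carboxylate oxygens of the two inter-domain bridges,
  center 4 A, $k = 1000$ kJ/mol.
* **Secondary structure** -- the superposed backbone RMSD of each
  secondary-structure segment to the reference model, center 0 A,
  $k = 10000$ kJ/mol. Each segment is superposed independently, so the
  restraint preserves internal fold without fixing the inter-domain
  arrangement (which is exactly what the solution data must determine).

## Surrogate physical term

Explicit-solvent molecular dynamics is out of scope; its role -- keeping
chains intact and sterically sensible -- is played by a minimal physical
term: harmonic virtual bonds between consecutive residues along each
chain (protein C(i)-N(i+1), RNA O3'(i)-P(i+1); reference lengths recorded
from the reference model, $k = 200$ kJ/mol/A^2) plus soft-sphere
repulsion $k(d_0-d)^2$ below $d_0 = 2.5$ A between non-bonded pairs
($k = 10$ kJ/mol/A^2). It deliberately carries no attractive or
torsional chemistry: inter-domain arrangement is left entirely to the
data terms and restraints.

# Simulated-annealing refinement

Sampling is Monte Carlo rather than molecular dynamics: the degrees of
freedom are rigid-body perturbations of the second domain (with its bound
RNA nucleotides riding along) and single backbone torsions (phi/psi) in
the linker. Move amplitudes (5 degrees rotation, 0.5 A translation,
10 degrees torsion at the hot end) scale linearly with $T/T_\mathrm{high}$.
The temperature sweeps a triangular cycle between 300 K and 100 K;
Metropolis acceptance uses $k_B$ in kJ/(mol K). The nominal
picosecond period of the original annealing protocol has no direct MC
equivalent; one cycle here is one full 300-100-300 K sweep over
`2 * steps_per_half` steps, a deliberate and documented mapping.

The metainference SAXS term is evaluated every 10th step (proposals on
those steps face the full energy difference; nuisance updates happen at
the same stride and reuse cached forward values); structural restraints,
the physical term and the RDC correlation act at every step. At the hot
pass of every cycle, each replica is snapshotted; the refined model is
the snapshot with the lowest metainference energy among the high-
temperature samples of the last `selection_window` cycles, ties broken by
the earliest step. When the SAXS term is disabled the selection falls
back to the remaining hybrid energy.

**Problem sizes.** The package's desk-scale defaults (`default_config()`)
run 30 cycles of 40 steps with a selection window of 10 cycles and two
replicas, on a toy complex of ~400 atoms; one refinement takes tens of
seconds on a laptop core. These sizes were chosen once as the study
conditions for the recovery and ablation experiments; `anneal_schedule()`
itself defaults to the full-scale protocol (300 cycles, selection over
the last 30).

# The synthetic toy complex

`make_toy_complex()` builds the ground truth deterministically: two
16-residue helical pseudo-domains (chain A residues 1-16 and 25-40)
joined by an 8-residue flexible linker, and a 12-nucleotide RNA (chain B,
sequence AGUAGAUUAGCA) running along both domains, nucleotides 1-6
assigned to domain 1 and 7-12 to domain 2. Residues carry full backbone
N/CA/C/O plus an amide H (giving RDC bond vectors that sample many
orientations); four Phe residues and their partner nucleotides carry
six-membered rings placed so every stacking restraint is satisfied at
exactly 3.3 A, and the two Arg/Asp bridges carry charged-group
pseudo-atoms placed 3.6 A apart. The truth therefore has zero restraint
energy by construction, and its surrogate-physical energy is within a few
kJ/mol of the minimum.

The perturbed start model applies one random linker-torsion direction,
scaled by bisection until the superposed backbone RMSD hits the requested
value (8 A by default) within the +/-10% contract band. Torsion
perturbation (rather than a rigid jump) keeps the protein chain intact,
as any physical perturbation would.

What the toy does *not* emulate: side-chain chemistry and rotamers, real
secondary-structure content, RNA base identity beyond naming, hydration,
and the crystallographic scale of the real system. Passing the recovery
experiment therefore demonstrates that the inference machinery -- forward
models, restraints, sampler and selection rule -- can reconstruct a known
arrangement from its own synthetic data; it does not certify accuracy on
real experimental curves.

## Synthetic observables

Each generator is a pure function of its arguments and a seed; one global
seed expands into per-generator streams through a fixed affine rule
(`split_seed()`), so adding a generator never shifts existing streams.
Zero-noise outputs equal the corresponding forward models exactly, which
the tests exploit as round-trip oracles (SAXS scale, RDC tensor, ITC
parameters, PRE distances, relaxation times).

* **SAXS** -- Debye curve plus relative Gaussian noise (2% by default,
  the level also assumed by the metainference term).
* **RDC** -- couplings from a known axial tensor (principal axis along
  the laboratory z, $D_a = 4$ Hz) for all amide N-H bonds, plus Gaussian
  noise (0.3 Hz in the pipeline defaults).
* **ITC** -- one-site heats for any row of the published titration table
  (`itc_presets()`); see below for the noise model.
* **NMR** -- PRE ratios from the label-to-amide distances of the model,
  exponential relaxation decays on the published 12-delay series with
  two duplicate delays, and free/bound shift tables whose perturbations
  mark the RNA-facing residues.

# ITC: model, conventions and study conditions

The one-site isotherm uses the closed-form root of the mass-action
quadratic with stoichiometry $N$ binding sites per cell-species molecule.
Cell concentrations follow an overfill displacement convention: each
injection of volume $dV$ into cell volume $V_0$ multiplies the cell
species by $(1 - dV/V_0)$ and adds $X_s\,dV/V_0$ of titrant; the
injection heat is $Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2$, the last
term accounting for heat content carried out with the displaced liquid.
A consequence of this convention is that re-binning injections changes
the displaced-heat correction at second order in $dV/V_0$; total heats
agree across designs to ~0.1%, not to machine precision.

Fitting is nonlinear least squares over $(N, \ln K_D, \Delta H)$
(Levenberg-Marquardt), weighted by per-injection uncertainties when the
experiment carries them. Derived quantities use
$\Delta G = RT \ln K_D$ and $\Delta S = (\Delta H - \Delta G)/T$ with
$R = 1.987$ cal/(mol K) and $T = 298.15$ K, matching the calorie-based
units of the reference titration values.

**Study conditions.** The published protocol gives concentration ranges
(cell RNA 20-100 uM, syringe protein 300-1000 uM) chosen "depending on
the affinity"; the presets therefore use the low ends (20/300 uM) for
sub-100 nM binders and mid-range values (60/650 uM) otherwise. Even so,
the nanomolar rows sit at Wiseman $c$-values above 1000, where $K_D$ is
weakly identified from a single isotherm -- visible in the published
+/-22% uncertainty on the tightest row. Three design choices, fixed once,
define the recovery experiment: per-injection noise of 0.5% of each
heat's magnitude plus a 0.1%-of-peak floor (emulating
baseline-integration error); three replicate titrations, as the protocol
prescribes, fitted jointly through their mean; and weighting by the known
uncertainties. Under these conditions $K_D$ recovery is within ~4%
across seeds.

# NMR observables

* **CSP** -- combined perturbation
  $\sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$ with the common
  weighting $\alpha = 0.2$ (configurable; conventions for the nitrogen
  weight vary between studies). Exchange-broadened residues are carried
  as an explicit category, never as zero.
* **Relaxation** -- per-residue monoexponential fits
  $I(t) = I_0 e^{-t/T}$; intensity noise estimated from duplicate delays
  is propagated into the uncertainty of $T$; non-decaying residues are
  flagged invalid rather than returned.
* **PRE** -- the intensity ratio model
  $I_\mathrm{para}/I_\mathrm{dia} = R_2 e^{-\Gamma_2 t}/(R_2 + \Gamma_2)$
  is inverted numerically (monotone in $\Gamma_2$; bisection tolerance
  $10^{-10}$) and converted to distances by
  $r = (K_\mathrm{PRE}/\Gamma_2)^{1/6}$, with $K_\mathrm{PRE}$ from a
  configurable effective correlation time (default 5 ns at 600 MHz,
  nitroxide prefactor $1.23\times10^{16}\,\mathrm{\AA^6 s^{-2}}$).
  Ratios at 1 become lower-bound records, vanishing ratios upper bounds;
  absolute distances are labelled approximate and the supported use is
  qualitative profile comparison (free versus bound), which is how
  unchanged domain arrangement is established.

# Numerical choices and degenerate inputs

* Superposition is closed-form least squares (Kabsch via SVD) with equal
  weights; reflections are excluded by the determinant sign correction.
* Polynomial restraint preparation warns on rank deficiency instead of
  failing, and rejects grids outside the fitted range (with a 1e-9
  tolerance against floating-point edge effects).
* The Guinier fit shrinks its window until $q R_g \le 1.3$ and refuses
  windows of fewer than 5 points.
* The tensor fit rejects fewer than 5 bonds or an orientation design of
  rank below 5 (singular values under $10^{-10}$ of the largest).
* Selection ties break to the earliest step; `which.min` semantics make
  this deterministic.
* All randomness flows through explicit seeds; samplers save and restore
  the caller's RNG state.

# Known limitations

* No hydration shell in the SAXS model, no distance binning options, and
  hydrogens contribute their own form factors rather than being folded
  into heavy atoms.
* The surrogate physical term is not a force field; it cannot rank
  near-native conformations by packing quality, only prevent gross
  pathology. Recovered models inherit this resolution limit.
* The RDC restraint assumes the alignment frame of the synthetic tensor;
  real data would require either a tensor estimate or the steric
  prediction the correlation method was designed to avoid.
* The ITC model is strictly single-site; titrations with coupled folding
  equilibria (observed for some stem-loop constructs) are outside its
  model class and are expected to fail the fit, by design.
* PDB support covers ATOM/HETATM/TER/END without insertion codes,
  altlocs or mmCIF.
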