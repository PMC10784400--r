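---
title: "In vivo metabolic control analysis: models, methods, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vivo metabolic control analysis: models, methods, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invivomca)
```

## The problem

Metabolic control analysis (MCA) asks which enzymes limit a steady-state
flux: the flux control coefficient (FCC) of enzyme $k$ on flux $J_j$ is the
normalized sensitivity $C^J_{jk} = \partial \ln J_j / \partial \ln e_k$, and
over all steps of the system the FCCs on any flux sum to 1. Measuring FCCs
*in vivo* — in production-process cells rather than in a reconstituted
system — requires estimating all enzyme elasticities
$\varepsilon_{ji} = \partial \ln v_j / \partial \ln c_i$ from perturbation
data and then converting them into control coefficients through the
network's stoichiometry.

`invivomca` implements this workflow for a reduced *Escherichia coli*
central-carbon + L-cysteine network (37 enzymatic reactions, 40 balanced
metabolites; glycolysis, TCA cycle, pentose phosphate pathway, and the
serine/cysteine branch with its two competing cysteine synthases and the
O-acetylserine exporter). The workflow has four stages:

1. **Thermodynamic flux analysis (TFA).** A mixed-integer linear program
   over fluxes $v_j$, log-concentrations $\ln c_i$ and direction binaries:
   steady-state mass balance $N v = 0$, the affine Gibbs energy
   $\Delta G_j = \Delta G^{\circ\prime}_j + RT \sum_i n_{ij} \ln c_i$,
   big-M coupling that forces $v_j > 0 \Rightarrow \Delta G_j < 0$ (which
   also eliminates thermodynamically infeasible internal loops), and
   measured extracellular rates / intracellular concentrations as window
   constraints. Maximising the biomass demand gives an optimal flux
   distribution; variability analysis at 99.9% of that optimum gives
   ranges for every flux, log-concentration and reaction Gibbs energy.
2. **Equilibrium classification.** 10,000 Monte-Carlo draws of the
   log-concentrations, uniform within their TFA ranges, give a Gibbs-energy
   distribution per reaction; a reaction is *near equilibrium* when both
   middle quartiles fall inside the closed window $[-10, 0]$ kJ/mol. The
   PTS glucose uptake system is always treated as far from equilibrium
   (irreversible phosphorylation cascade).
3. **Dual-regime elasticities.** Near-equilibrium reactions get the
   thermokinetic affinity form
   $\varepsilon_{ji} = n_{ij} RT / \Delta G_j$, which diverges as
   $\Delta G_j \to 0^-$ and decays as the reaction becomes strongly
   exergonic. Far-from-equilibrium reactions are fitted by lin-log
   regression across the perturbation steady states:
   $v_{jk}/v_{j0} - 1 = \sum_i \varepsilon_{ji} \ln(c_{ik}/c_{i0})$,
   with the reference production state as normalization point and
   per-state fluxes taken from the per-state TFA optima.
4. **Control coefficients.** With $N = L N_0$ (link-matrix decomposition;
   the packaged model carries three conserved cofactor pools — adenylate,
   NAD(H), NADP(H)), unscaled elasticities
   $\partial v/\partial s = \mathrm{diag}(J) E\, \mathrm{diag}(s)^{-1}$
   give the concentration-control matrix
   $\Gamma = -L (N_0 (\partial v/\partial s) L)^{-1} N_0$ and the
   flux-control matrix $\Theta = I + (\partial v/\partial s)\Gamma$,
   normalized back by $J$ and $s$. Summation
   ($\sum_k C^J_{jk} = 1$, $\sum_k C^S_{mk} = 0$) and, on moiety-free
   networks, connectivity residuals are reported by `theorem_check()`.
   Uncertainty is propagated by re-drawing concentrations and steady-state
   fluxes within their TFA ranges, re-routing the elasticities, and
   recomputing the coefficients (10,000 cycles by default; singular draws
   are counted and skipped, never imputed).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `T` | 305.15 K | process temperature (32 °C); `RT` = 2.537 kJ/mol |
| `objective_fraction` | 0.999 | optimum fraction retained in variability analysis |
| `big_M` | 1000 kJ/mol | direction-coupling constant |
| `tol_dg` | 1e-3 kJ/mol | strict-inequality surrogate for $\Delta G \lessgtr 0$ |
| concentration bounds | 1e-8 … 0.1 M | defaults for unmeasured metabolites |
| measurement windows | value ± 1.96 sd | 95% windows; 10% relative floor only when the sd is absent; sd = 0 means exactly known |
| equilibrium window | $[-10, 0]$ kJ/mol | closed interval on both middle quartiles |
| `dg_floor`, `eps_cap` | 0.1 kJ/mol, 25 | guards for the diverging thermokinetic form |
| lin-log ridge | cond > 1e6 → $\lambda = 10^{-6} s_{max}$ | fallback for ill-conditioned designs |
| Monte-Carlo cycles | 10,000 | classification and control-coefficient propagation |

## The solver backend

The TFA program is a genuine MILP (two direction binaries per interior
reaction). The package formulates it entirely in R and solves it with the
HiGHS solvers through SciPy's `milp` interface, via a small bundled Python
driver (`inst/python/milp_backend.py`) invoked per batch: one process
handles a whole state's optimum plus all of its variability objectives, and
all thirteen states are solved in two batched invocations. The interpreter
is located via `options(invivomca.python=)`, `INVIVOMCA_PYTHON`, or
`python` on the PATH.

## The synthetic perturbation experiment

The fermentation data behind this kind of study (LC-MS metabolomics of
quenched samples plus feeding-step extracellular rates) are not publicly
deposited, so the package ships a kinetic ground truth that *generates*
such data and an oracle that scores the whole estimation chain against it.

The toy pathway (`toy_model()`) has 9 enzymatic reactions over 8
metabolites plus supply, respiration and product-export boundary steps. It
mirrors the cysteine-branch competition motif: a glycolysis-like backbone
feeds a serine branch to an O-acetylserine (OAS) analogue consumed by two
synthases with distinct boundary sulphur co-substrates (direct sulfide
route; two-step sulfocysteine route) and drained by an exporter whose rate
constant is five times the synthases' — the export-dominant situation in
which the exporter holds negative control over cysteine synthesis while the
synthases hold the largest positive self-control among the enzymes.

Design choices that matter:

* **Far-from-equilibrium kinetics with product inhibition.** Every step is
  irreversible (assigned standard Gibbs energies well below −10 kJ/mol),
  so every row stays in the lin-log regime, where mass-action local
  elasticities are recoverable by regression. Product inhibition on the
  committed steps propagates downstream perturbations upstream; this, plus
  a second carbon entry (the pyruvate-like feed regime), gives every
  metabolite at least two independent excitation routes — the condition
  for the regression design matrix to be identifiable. Declared
  `effectors` in the network model name exactly these feedback
  metabolites; for irreversible reactions, products that are not declared
  effectors are excluded from the regression (an irreversible step cannot
  respond to its products).
* **Feeding design.** Four regimes (glucose, pyruvate, and two
  sulphur-source mixtures) × three feeding levels plus the reference state
  give 13 steady states. The three levels are geometric factors centred on
  the reference supply, so the steps bracket the reference symmetrically in
  log-concentration; a one-sided (all-increasing) design would leave the
  quadratic linearization error of the lin-log form uncancelled and bias
  every fitted elasticity upward.
* **Noise.** Multiplicative lognormal with sd 0.05 on concentrations and
  measured rates — a typical LC-MS replicate spread. Boundary medium
  concentrations are also "measured" and enter the regression as
  additional regressors whose fitted columns are discarded (they are
  parameter, not variable, elasticities); without them the effect of a
  changing feed would be mis-attributed to interior metabolites.

What the toy does **not** emulate: enzyme-level drift during the
perturbation (assumed absent over the short cultivation), quenching and
extraction losses, correlated measurement error across metabolites, and
genome-scale context (the reduced model's boundary fluxes stand in for the
rest of metabolism). Passing tests therefore show that the estimation
chain is correct and well-behaved under clean, known kinetics — not that
real fermentation data of this size determine every coefficient.

## Numerical choices

* Quartiles use linear interpolation (type 7); the equilibrium window is
  closed, so samples exactly at −10 or 0 count as inside.
* Matrix solves use `solve()` on the reduced Jacobian, never an explicit
  inverse; the condition number is checked and a structurally singular
  reference state is an error, not a silent NaN.
* The Monte-Carlo flux draws stay on the steady-state manifold: hit-and-run
  in the null space of $N$ inside the TFA flux box, so the summation
  theorems hold for every draw exactly. The joint distribution is an
  approximation (independent uniform concentration draws; no correlation
  structure between states), as is the uniform-in-range scheme itself.
* Infeasible TFA problems are diagnosed by staged relaxation: drop the
  Gibbs constraints, then the concentration windows, then the rate windows,
  and report the first family whose removal restores feasibility.
* Per-stage seeds are derived from the top-level seed by a fixed affine
  map (`derive_seed()`), so any stage can be re-run in isolation and every
  output is reproducible from the manifest.

## Known limitations

* **Lin-log linearization bias.** The regression fits a first-order model
  in log-concentration ratios to data from finitely perturbed states; at
  the default design amplitudes the surviving bias is visible in
  coefficients whose true magnitude is small, although every control
  coefficient with |truth| > 0.05 keeps its sign on noise-free data (this
  is asserted by the test suite).
* **Noise floor.** Metabolites whose steady-state excitation across the 12
  states is at or below the measurement noise (in the toy: serine and OAS,
  which strong feedback and the dominant exporter clamp) have elasticity
  rows that are unidentifiable at 5% noise, and the control-matrix
  inversion amplifies those errors. Median estimates over replicate
  datasets then recover the large coefficients and the mechanism readout
  (negative exporter control, synthase self-control) but not every small
  coefficient's sign. The acceptance suite measures this directly and the
  corresponding criterion is reported as failing rather than weakened.
* The thermokinetic affinity form is exact only asymptotically at
  equilibrium; between the −10 kJ/mol window edge and true equilibrium it
  and mass-action elasticities can differ substantially. The package
  follows the standard dual-regime rule rather than attempting to blend
  the regimes.
* Exchange (supply/drain) steps participate in the control computation —
  the summation theorem needs them — but rankings and the "largest
  self-control" comparisons are reported over the interior enzymatic steps
  only; a boundary supply with no feedback trivially carries a self-FCC
  near 1 and is an experimental condition, not an actionable enzyme.

## Problem sizes used by the test and acceptance runs

The shipped tests run the classification sampler at 300–2,000 cycles, the
control-coefficient Monte-Carlo at 10–30 cycles, and the replicate study at
20 datasets with the point estimator; the acceptance script uses 10,000
classification cycles, a 2,000-cycle propagation run, and 20 replicate
datasets. These sizes are the package's own verification choices; the
analysis defaults remain 10,000 cycles for both samplers.
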