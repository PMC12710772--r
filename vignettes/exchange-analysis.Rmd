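---
title: "Quantifying slow and fast conformational exchange in an SH2 domain"
author: "nmrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying slow and fast conformational exchange in an SH2 domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

## The scientific problem

The N-terminal SH2 domain of SHP2 recognizes phosphotyrosine (p-Tyr)
peptides.  Upon peptide binding its beta_C and beta_D strands interconvert
between two conformations: a *zipped* state in which the Phe41 backbone
amide donates a hydrogen bond to the Ile56 carbonyl (donor-acceptor
distance 2.7-3.3 Å, extending strand beta_D) and an *unzipped* state in
which the strand ends are separated (4-5 Å) and no hydrogen bond can form.
Disease-associated point mutations shift this equilibrium: T42A locks the
bound state zipped, while E139D in the C-SH2 domain shifts the global
open/closed equilibrium of full-length SHP2.

`nmrdyn` implements the quantitative machinery needed to characterize this
system from solution NMR and ensemble crystallography:

1. **Bloch-McConnell simulation** of two-state and linear three-state
   chemical exchange, producing ¹⁵N-CEST profiles and constant-time CPMG
   relaxation dispersions (`simulate_cest()`, `simulate_cpmg()`,
   `carver_richards()`).
2. **Exchange fitting**: per-residue and grouped global fits of CEST
   (`fit_cest_residue()`, `fit_cest_group()`), two-state CPMG group fits
   (`fit_cpmg_group_2state()`), and the three-state CPMG fit with the slow
   process fixed at CEST-derived values
   (`fit_cpmg_3state_constrained()`).
3. **Fast backbone dynamics**: exponential R1/R2 fits, hetNOE ratios and
   the R2/R1 mean + 1 SD flag (`fit_exponential_rate()`,
   `compute_hetnoe()`, `flag_r2r1()`).
4. **Binding and populations**: global fast-exchange CSP titration fits
   (`fit_kd_fast_exchange()`), slow-exchange peak-volume quantitation
   (`quantify_open_population()`), and free-energy/fold-affinity
   arithmetic (`delta_delta_g()`, `fold_affinity()`).
5. **Ensemble geometry**: per-model atom-pair distances from multi-model
   PDB files with zipped/unzipped classification and a survey mode over
   many SH2 structures (`extract_pair_distances()`,
   `classify_conformation()`, `survey_sh2()`).
6. **Synthetic data** for every stage with known ground truth and seeded
   noise (`nmr_scenario()`, `gen_*()`).

## The exchange model

A backbone ¹⁵N nucleus exchanging between conformations A (major) and B
(minor) is described by the exchange rate $k_{ex} = k_{AB} + k_{BA}$, the
minor population $p_B$ and the chemical-shift difference
$\Delta\omega = \omega_B - \omega_A$ (stored in ppm, converted to rad/s
with $2\pi\,\nu_N$ where $\nu_N$ is the ¹⁵N Larmor frequency in MHz).
Detailed balance fixes $k_{AB} = p_B k_{ex}$, $k_{BA} = (1-p_B) k_{ex}$.
The linear three-state topology B &harr; A &harr; C adds an independent
fast leg ($k_{ex,AC}$, $p_C$, $\Delta\omega_{AC}$) with **no** direct
B &harr; C exchange; each leg satisfies pairwise detailed balance, so
setting $k_{ex,AC} = 0, p_C = 0$ reduces the model exactly (to the bit) to
the two-state case.

**CEST.** Magnetization evolves under the full Bloch-McConnell generator
(three spatial components per state: exchange, R1/R2 relaxation and B1
nutation) for the saturation time via matrix exponential, compiled in C++.
The generator is homogeneous — relaxation decays toward zero rather than
toward thermal equilibrium — so the far-off-resonance limit of the
normalized profile is exactly $\exp(-R_1 T_{sat})$ and the reference is the
$T_{sat} = 0$ experiment.  B1 is a single nominal value (no inhomogeneity
model).

**CPMG.** Transverse magnetization is propagated in the complex
single-quantum basis (one component per state).  Ideal, instantaneous
180° pulses act as complex conjugation, giving the linear echo-block
propagator $B = P(\tau)\,\overline{P(2\tau)}\,P(\tau)$ with
$\nu_{CPMG} = 1/(4\tau)$;
$R_{2,eff}(\nu) = \ln[I_0/I(\nu)]/T_{relax}$ with a constant-time period.
Acquisition validation requires an integer number of echo blocks (an even
number of refocusing pulses) at every frequency.

**Closed-form cross-check.** `carver_richards()` evaluates, by default, the
exact closed-form solution of the two-site CPMG problem: the analytic 2x2
matrix exponential (scalar hyperbolic functions, written in an
overflow-safe form), the echo-block composed analytically, raised to the
block count through its spectral decomposition, and projected onto the
detected state.  This agrees with the numerical propagator to better than
$10^{-11}$ s⁻¹ and is the package's independent oracle.  The classical
Carver-Richards dominant-eigenvalue expression is available with
`exact = FALSE`; it neglects projection terms and deviates by up to a few
percent of $R_{ex}$ for large minor populations in intermediate exchange,
which is why it is not the default oracle.

## Fitting strategy

All fits minimize sigma-weighted residuals.  Global (grouped) fits share
$k_{ex}$ and $p_B$ across residues with per-residue $\Delta\omega$, R1, R2,
exactly as grouped dispersion analyses are usually organized.  Group
membership is user-supplied: the partitioning of residues into groups is an
input, not an algorithm the package invents.

* **Initialization** is by coarse grid search (CEST: $k_{ex}$ on a log grid
  10-6000 s⁻¹, $p_B$ 0.5-20 %, $\Delta\omega$ up to ±6 ppm; CPMG:
  analogous grids on the closed form), followed by Levenberg-Marquardt in
  an unconstrained parameterization ($\log k_{ex}$, logit of $2 p_B$).
* **The group engine** exploits the block-sparse Jacobian: a residue's
  residuals depend only on the shared parameters and its own block, so a
  full-precision finite-difference Jacobian costs two full evaluations
  plus one single-profile evaluation per block parameter.  This is what
  makes a 28-profile global CEST fit take seconds.
* **Model selection** uses AIC with a margin of 10: a CEST minor dip is
  "detected" when the two-state fit beats the no-exchange fit by more than
  10 AIC units, and the three-state CPMG model is "justified" only under
  the same rule against the free two-state fit.
* **Underdetermined populations.** In fast exchange only the product
  $p_B \Delta\omega^2$ is encoded in a dispersion.  The two-state group
  fit flags the population as underdetermined when its relative one-sigma
  error exceeds 50 % or a shared-parameter/$\Delta\omega$ correlation
  exceeds 0.98, and then reports the fixed-product parameterization
  ($p_B$ pinned at a nominal 0.05, per-residue $\Delta\omega$ carrying the
  amplitude) because letting $p_B$ float biases $k_{ex}$ through their
  covariance.  The free fit nests the pinned fit, so whenever the free
  optimum is worse than the pinned one the optimizer has demonstrably hit
  a local minimum and is restarted from the pinned solution.
* **Three-state fit.** Following the logic that CPMG profiles are
  dominated by the faster process while CEST pins the slow one, the
  A&harr;B parameters ($k_{ex,AB}$, $p_B$, per-residue
  $\Delta\omega_{AB}$) are frozen at CEST-derived values and only
  $k_{ex,AC}$ (shared), per-residue $\Delta\omega_{AC}$ and R2 are free;
  $p_C$ is held at a nominal 0.05 and reported as underdetermined.
* **Parameter errors** come from seeded Monte-Carlo noise resampling
  (`n_mc`, default 200, warm-started refits) or, with `n_mc = 0`, from the
  curvature of the weighted least-squares problem.

With equal per-state R2 a CPMG dispersion is even in $\Delta\omega$, so
CPMG fits report $|\Delta\omega|$; CEST fits resolve the sign whenever
$|\Delta\omega|$ is a few times the offset spacing, which is what makes
minor-state shift reconstruction ($\omega_B = \omega_A + \Delta\omega$,
`reconstruct_minor_shift()`) and the comparison against directly observed
spectra (`compare_minor_to_reference()`) meaningful.

## Binding, populations, relaxometry

The CSP titration fit uses the single-site quadratic isotherm
$$\Delta\delta([L]) = \Delta\delta_{max}
\frac{(P+L+K_D) - \sqrt{(P+L+K_D)^2 - 4PL}}{2P}$$
with a single shared $K_D$ and per-residue amplitudes.  The amplitudes
enter linearly and are profiled out exactly, leaving a one-dimensional
optimization in $\log K_D$ — fast and free of local minima.  Combined CSPs
use $\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$; 0.14 is the
common ¹⁵N weighting convention.  A warning is raised when the top
titration point saturates less than 50 % of the protein.

Slow-exchange open/closed populations are per-residue volume fractions
$v_{minor}/(v_{minor}+v_{major})$ aggregated as mean ± SD over reporter
residues.  $\Delta\Delta G = -RT \ln(\text{fold})$ with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ at 298 K: a 2-fold population
shift corresponds to −0.41 kcal/mol, less than a hydrogen bond.

R1/R2 rates come from two-parameter exponential fits (log-linear
initialization, Levenberg-Marquardt); hetNOE is the saturated/reference
ratio with first-order error propagation.  The µs-ms flag marks residues
whose R2/R1 ratio exceeds the mean + 1 SD computed over **all** residues in
a single pass (outliers included) — the statistic is taken over residues,
not replicates, matching a single horizontal cutoff line per dataset.
No model-free analysis is attempted.

## Ensemble geometry

Multi-model PDB files are read (via bio3d, alternate locations retained)
and a named atom pair is measured in every MODEL, 1-based in file order;
models missing an atom are recorded absent, never as zero.  For
carboxylate acceptors the pseudo-atom names `OD`/`OE` select the nearer of
OD1/OD2 (OE1/OE2) per model — adopted because a hydrogen bond to either
oxygen is chemically equivalent.  Alternate locations resolve to the
highest-occupancy conformer, ties to altLoc `A`.

Classification: zipped when $d \le 3.3$ Å, unzipped when $d \ge 3.4$ Å,
with the 3.3-3.4 Å gap kept explicit as `ambiguous` rather than forced
into a binary call, since the two literature ranges do not meet.  The
short-hydrogen-bond flag marks a mean donor-acceptor distance below
2.7 Å, the conventional lower edge of ordinary hydrogen bonds (the
Tyr66-Asp40 bond averages 2.6 Å in the zipped T42A complex).  Survey mode
applies a per-structure homologous residue mapping, takes each structure's
minimum pair distance over models, and tabulates class counts and a
histogram; unresolvable structures are skipped with a log entry.

## Synthetic data: what it emulates, and what it does not

Every generator embeds its ground truth in a sidecar and draws noise from
a seeded stream, so `fit(gen(truth))` is a complete, reproducible test of
each stage.  Scenario presets (`nmr_scenarios()`) carry the benchmark
conditions for this system: CEST group 1 ($k_{ex} = 104$ s⁻¹, $p_B = 11$ %, 28 residues)
and group 2 (45 s⁻¹, 16 %, 2 residues) of the peptide-bound WT domain;
the six-residue three-state group ($k_{ex,AC} = 2600$ s⁻¹ on top of the
CEST slow leg) and the Ile54-like single residue (1830 s⁻¹); the fast
two-state groups (1740, 5000, 3550, 7000, 1260 s⁻¹); p-Tyr titrations
($K_D$ = 400/330/250 µM at 0.2 mM protein); open populations (15 % WT,
31 % E139D, six reporters); and zipped/unzipped toy ensembles.

Acquisition defaults are typical literature values, config-overridable
because the originating experimental settings are not part of the package:
¹⁵N at 81.1 MHz (800 MHz ¹H), B1 = 25 Hz, $T_{sat}$ = 0.4 s, 61 offsets
spanning ±6 ppm; CPMG $T_{relax}$ = 40 ms with 14 frequencies, 25-1000 Hz,
all multiples of 25 Hz so the echo-block count is integral.  Noise
defaults: 1 % multiplicative intensity noise (CEST sigma scaled by the
true intensity, floored at $10^{-4}$), 3 % CSP noise, 10 % volume noise —
chosen once to produce error bars of the same order as the uncertainties quoted for such
measurements.  Per-residue truths ($\Delta\omega$ spreads of 1-3.5 ppm
with alternating signs, R1 1.1-1.5 s⁻¹, R2 9-14 s⁻¹) are deterministic
spreads, not random draws, so the truth table is independent of the noise
seed.

What passing these tests shows: the estimators are unbiased and correctly
calibrated *under the stated model* — ideal pulses, single B1, matched
noise model, correct group membership.  What they do not show: robustness
to pulse miscalibration, B1/B0 inhomogeneity, off-resonance effects,
scalar-coupling or TROSY-specific relaxation interference, peak overlap,
or mis-assigned group membership, none of which the generator emulates.
At $k_{ex} \gtrsim 7000$ s⁻¹ the 25-1000 Hz CPMG grid barely resolves the
dispersion rolloff, and recovered rates carry accordingly wide spread —
the fit still identifies the regime and flags the population as
underdetermined, mirroring how such groups are reported in practice.

## Numerical choices and problem sizes

* Matrix exponentials: Padé scaling-and-squaring (Armadillo `expmat`) for
  the 6x6/9x9 CEST generators and the complex CPMG propagators; the
  independent ODE oracle in the test suite integrates the same generator
  with `deSolve::lsoda` at $10^{-11}$ relative tolerance and agrees to
  $10^{-6}$.
* Detected CPMG magnetization that underflows to a non-positive value is
  flagged per point rather than failing the profile.
* The test suite runs each group-fit recovery at 3 seeds (median) and the
  acceptance script at 20 seeds; the full suite completes in under two
  minutes on one CPU.  These sizes were chosen as the smallest that make
  the medians stable against individual noise draws.
* All tabular I/O is whitespace-delimited text with `#`-commented
  metadata naming units; ground truths travel in JSON sidecars; run
  configuration is YAML.  A thin CLI (`inst/cli/nmrdyn`) exposes the
  pipeline stages (`simulate`, `fit-cest`, `fit-cpmg`, `fit-relax`,
  `fit-titration`, `quantify-populations`, `ensemble-distances`,
  `survey-sh2`, `report`); every run writes a log echoing its
  configuration and seed.

## Known limitations

Only amide ¹⁵N two- and linear three-state exchange is modeled; CEST fits
are two-state only (by design — the slow process is the one CEST sees).
Multi-B1 CEST, off-resonance R1rho, temperature series, automatic residue
grouping and lineshape fitting are out of scope.  The Monte-Carlo error
default (`n_mc = 200`) is deliberate but costly for large groups; the
covariance-based errors (`n_mc = 0`) are adequate when the noise model is
trusted.

## A worked session

```{r, eval = FALSE}
library(nmrdyn)

# simulate the slow CEST group and refit it
ds <- gen_cest_dataset(nmr_scenario("bound_wt_cest_group1", seed = 1))
fit <- fit_cest_group(ds$profiles, n_mc = 0)[[1]]
fit
#> <group_fit_result> group1: 28 residues, kex = 103.7 +/- 0.21 /s,
#>   pB = 0.1103 +/- 0.00013, chi2_red = 0.952

# constrained three-state CPMG on the fast group
ds3 <- gen_cpmg_dataset(nmr_scenario("bound_wt_cpmg_3state", seed = 1))
tt <- ds3$truth$per_residue
fit3 <- fit_cpmg_3state_constrained(
  ds3$profiles,
  data.frame(residue = tt$residue, kex_AB = 104, pB = 0.11,
             dW_AB = tt$dW_AB))
fit3$kex_AC
```
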