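# nmrdyn

Chemical-exchange NMR dynamics and ensemble geometry for SH2 domains.

SH2 domains recognize phosphotyrosine peptides, and in the N-terminal SH2
domain of SHP2 the bound state interconverts between a *zipped* β-sheet
conformation (the Phe41 amide–Ile56 carbonyl hydrogen bond forms,
2.7–3.3 Å) and an *unzipped* one (4–5 Å, no hydrogen bond). `nmrdyn` is an
R package for quantifying this kind of conformational equilibrium from
solution NMR and multi-model crystallographic ensembles:

* **Bloch–McConnell simulation** of two-state and linear three-state
  (B↔A↔C) ¹⁵N exchange: CEST profiles (`simulate_cest()`), constant-time
  CPMG relaxation dispersions (`simulate_cpmg()`), and an exact closed-form
  two-site dispersion used as an independent oracle (`carver_richards()`).
* **Exchange fitting**: per-residue and grouped global two-state CEST fits
  with shared (kex, pB) and Monte-Carlo errors (`fit_cest_residue()`,
  `fit_cest_group()`); Rex screening and two-state CPMG group fits with an
  explicit underdetermined-population rule (`screen_rex()`,
  `fit_cpmg_group_2state()`); and the three-state CPMG fit with the slow
  A↔B leg frozen at CEST-derived values
  (`fit_cpmg_3state_constrained()`).
* **Minor-state spectroscopy**: reconstruction of minor-state chemical
  shifts (ω_B = ω_A + Δω) and comparison against directly observed spectra
  (`reconstruct_minor_shift()`, `compare_minor_to_reference()`).
* **Fast dynamics**: R1/R2 exponential fits, hetNOE ratios with propagated
  errors, R2/R1 mean + 1 SD flagging (`fit_exponential_rate()`,
  `compute_hetnoe()`, `flag_r2r1()`).
* **Binding and populations**: global quadratic-isotherm CSP titration K_D
  fits, slow-exchange peak-volume open populations, ΔΔG and fold-affinity
  arithmetic (`fit_kd_fast_exchange()`, `quantify_open_population()`,
  `delta_delta_g()`, `fold_affinity()`).
* **Ensemble geometry**: per-model atom-pair distances from multi-model
  PDBs, zipped/unzipped/ambiguous classification (≤3.3 Å / ≥3.4 Å),
  short-hydrogen-bond reporting, and a survey mode over many SH2
  structures (`extract_pair_distances()`, `classify_conformation()`,
  `short_hbond_report()`, `survey_sh2()`).
* **Synthetic data** for every stage with known ground truth and seeded
  noise (`nmr_scenario()`, `gen_cest_dataset()`, `gen_cpmg_dataset()`,
  `gen_titration_dataset()`, `gen_volume_dataset()`,
  `gen_relaxation_dataset()`, `gen_toy_ensemble()`), so the entire
  pipeline is validated by parameter recovery.

The model core: two-site exchange A↔B with kex = k_AB + k_BA, minor
population pB (k_AB = pB·kex by detailed balance) and shift difference
Δω = ω_B − ω_A. CEST evolves the full 3-components-per-state
Bloch–McConnell generator by matrix exponential (compiled C++); CPMG
propagates complex transverse magnetization through τ–180°–2τ–180°–τ echo
blocks with ideal pulses and reports R₂,eff(ν) = ln[I₀/I(ν)]/T_relax. See
`vignettes/exchange-analysis.Rmd` for the model, the fitting strategy and
all numerical conventions.

## Worked example

Simulate the 28-residue slow-exchange CEST group at its reported truth
(kex = 104 s⁻¹, pB = 11 %) with 1 % intensity noise, then refit it
globally:

```r
library(nmrdyn)
ds  <- gen_cest_dataset(nmr_scenario("bound_wt_cest_group1", seed = 7))
fit <- fit_cest_group(ds$profiles, n_mc = 0)[[1]]
fit
#> <group_fit_result> group1: 28 residues, kex = 103.7 +/- 0.21 /s,
#>   pB = 0.1103 +/- 0.00013, chi2_red = 0.952
```

The shared exchange rate (103.7 s⁻¹) and minor population (11.03 %) come
back at the generating truth, and the reduced χ² near 1 says the fit's
noise model matches the generator's.

Constrained three-state CPMG — the slow A↔B leg fixed to CEST values,
extracting the fast A↔C rate:

```r
ds3 <- gen_cpmg_dataset(nmr_scenario("bound_wt_cpmg_3state", seed = 7))
tt  <- ds3$truth$per_residue
fit3 <- fit_cpmg_3state_constrained(
  ds3$profiles,
  data.frame(residue = tt$residue, kex_AB = 104, pB = 0.11,
             dW_AB = tt$dW_AB))
fit3
#> <cpmg_3state_fit> kex_AC = 2566 +/- 42 /s (pC fixed at 0.05,
#>   underdetermined); chi2_red = 0.757; 3-state justified over 2-state
#>   (dAIC = 225.2)
```

The fast rate is recovered (truth 2600 s⁻¹) and the model-selection report
confirms the two-state fit cannot account for the low-frequency deviations
left by the slow process (χ²_red 10.9 → 0.76).

Toy ensembles and classification:

```r
f <- tempfile(fileext = ".pdb")
gen_toy_ensemble(c(rep(2.9, 16), rep(4.5, 4)), file = f)
eds <- extract_pair_distances(f, atom_pair_spec("F41N-I56O", 41, "N", 56, "O"))
table(eds$labels)
#>   zipped unzipped
#>       16        4
```

A thin command-line interface wraps the same functions:

```sh
inst/cli/nmrdyn simulate --scenario bound_wt_cest_group1 --seed 7 --out out/
inst/cli/nmrdyn fit-cest --input out/cest.tsv --out out/
```

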