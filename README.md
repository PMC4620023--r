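# ocupkpd

Release kinetics, one-compartment ocular pharmacokinetics, MIC-anchored
PK/PD indices and superposition dosing simulation — the computational
chain used to evaluate a sustained-release ophthalmic formulation (for
example drug-loaded mucoadhesive microspheres) against a conventional
eye-drop solution.

The package is for formulation and pharmacokinetics scientists who have
(a) in vitro cumulative-release tables from a dissolution or Franz-cell
study, and/or (b) sparse aqueous-humor concentration–time data from a
destructive-sampling animal study (one eye per measurement), and/or
(c) only the published summary parameters of such a study, and who want
the downstream dosing conclusions recomputed reproducibly.

## What it computes

* **Release kinetics** — fits five classical dissolution models to
  cumulative release Q(t): first order Q = Q₀(1 − e^(−k₁t)); Higuchi
  Q = k_H √t; Baker–Lonsdale (exponential spherical-matrix form)
  Q = Q∞(1 − (6/π²)e^(−k_BL t)); Korsmeyer–Peppas Q = k tⁿ;
  Hixson–Crowell (Q₀ − Q)^⅓ = Q₀^⅓ − k_HC t. Models are ranked by
  R² = 1 − SSE/SST and the release mechanism is classified from the
  Peppas exponent (n < 0.45 Fickian; 0.45 ≤ n < 0.89 anomalous;
  n = 0.89 case-II; n > 0.89 super case-II).
* **Compartmental PK** — the Bateman curve
  C(t) = A(e^(−K_e t) − e^(−K_a t)) with closed-form
  T_max = ln(K_a/K_e)/(K_a − K_e), C_max, t₁/₂ = ln2/K_e and
  AUC₀₋∞ = A(1/K_e − 1/K_a); terminal log-linear K_e estimation;
  nonlinear fitting from replicate-mean data; and reconstruction of the
  curve behind a published summary table from (K_a, K_e, C_max).
* **NCA** — linear trapezoidal AUC with a virtual (0, 0) pre-dose anchor,
  tail extrapolation AUC₀₋∞ = AUC₀₋t + C_last/K_e, and relative
  bioavailability (AUC_test·Dose_ref)/(AUC_ref·Dose_test).
* **PK/PD** — C_max/MIC₉₀, AUC₀₋₂₄/MIC₉₀, time and AUC above the MIC,
  and the dosing interval τ = the post-peak time at which the single-dose
  curve falls to k×MIC₉₀ (default k = 2).
* **Dosing simulation** — multi-dose profiles by superposition of
  time-shifted single-dose curves, with instillation counts on a
  half-open horizon and pre-dose troughs.
* **Synthetic data** — seeded generators for destructive-sampling
  concentration profiles (lognormal noise, LLOQ censoring) and for
  release curves (additive noise, isotonic projection), including a
  biphasic burst-release preset.

## Worked example

Summary mode reproduces the downstream dosing conclusions from published
table values alone (rates in 1/h, concentrations in µg/mL, AUC in
h·µg/mL):

```r
library(ocupkpd)
report <- analyze(list(
  mode = "summary", mic90_ug_ml = 1.22, threshold_multiplier = 2,
  horizon_h = 75,
  arms = list(
    test      = list(ka = 0.7252, ke = 0.1233, cmax = 51.23,
                     auc_0_24 = 607.187, label = "microspheres"),
    reference = list(ka = 1.2981, ke = 0.1662, cmax = 18.98,
                     auc_0_24 = 121.634, label = "solution"))))
report
```

```
-- arm 'test' (microspheres) --
<bateman_fit> A = 88.73 ug/mL, Ka = 0.7252 /h, Ke = 0.1233 /h (summary)
  Tmax = 2.944 h, Cmax = 51.23 ug/mL, t1/2 = 5.622 h
<nca_result> Cmax = 51.23 ug/mL at 2.94 h; AUC(0-24) = 607.19, AUC(0-Inf) = 644.51 h*ug/mL (5.8% extrapolated, clast predicted)
<pkpd_report> MIC90 = 1.22 ug/mL, k = 2
  Cmax/MIC90      = 41.9918 (summary)
  AUC24/MIC90     = 497.6943 h (summary)
  AUC above MIC   = 530.7131 h*ug/mL [0-24 h]
  T above MIC     = 34.744 h;  T above 2*MIC = 29.099 h
  dosing interval = 29.146 h (down-crossing of 2*MIC)
<dosing_simulation> 3 instillation(s) every 29.15 h over 75 h
  pre-dose troughs: 2.443, 2.510 ug/mL
...
relative bioavailability (test vs reference): 4.992
Cmax fold: 2.699; instillations 3 vs 6
```

Reading: the sustained-release arm's reconstructed curve peaks at 51.23
µg/mL around 2.9 h, delivers a 4.99-fold AUC (and 2.70-fold C_max)
advantage over the solution, stays above twice the MIC₉₀ for ~29 h, and
therefore needs 3 instillations over 75 h where the solution needs 6.

Release kinetics on a synthetic burst-release curve:

```r
prof <- gen_release_profile("biphasic_burst", times = c(0.25, 0.5, 1:12),
                            sd = 1, seed = 7)
select_release_models(prof)
```

```
             model  r_squared   n_value n_params status rank
1 korsmeyer_peppas  0.9130343 0.1471437        2     ok    1
2   baker_lonsdale  0.8131217        NA        1     ok    2
3          higuchi -1.0255132        NA        1     ok    3
...
```

The power law wins the ranking and its exponent (n = 0.147 < 0.45)
classifies the release as Fickian diffusion.

Data mode (`mode = "data"` with `conc_csv` per arm, CSV header
`time_h,conc_ug_ml[,replicate][,arm]`) runs the same chain from raw
concentration tables via `fit_bateman()` and observed-data NCA;
`write_analysis_report()` emits JSON/CSV outputs.

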