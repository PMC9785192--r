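# pbpkddi

Whole-body physiologically based pharmacokinetic (PBPK) simulation of the
ruxolitinib–posaconazole drug–drug interaction (DDI).

Ruxolitinib (RUX), a JAK1/2 inhibitor used for steroid-refractory graft
versus host disease, is cleared almost entirely by hepatic CYP3A4 and
CYP2C9. Patients routinely receive posaconazole (POS), a strong
competitive CYP3A4 inhibitor, as antifungal prophylaxis, so RUX exposure
rises under co-administration and dosing guidance is inconsistent. This
package implements the full mechanistic pipeline needed to quantify that
interaction in silico, for pharmacometricians and clinical-pharmacology
researchers:

* **Virtual individuals and populations** — organ volumes, regional blood
  flows, enzyme concentrations and GFR, allometrically scaled from an
  embedded reference adult; truncated-normal demographic sampling.
* **Drug distribution** — tissue-to-plasma partition coefficients by the
  Rodgers–Rowland tissue-composition equations or the Poulin–Theil
  method.
* **Mechanistic oral absorption** — a five-segment gastrointestinal
  lumen with pH-dependent solubility, Weibull release
  (F(t) = 1 − exp(−ln2·((t−t_lag)/t50)^b)), Noyes–Whitney particle
  dissolution with supersaturation and first-order precipitation, meal
  effects on gastric emptying, and gut-wall CYP3A4 first-pass.
* **Whole-body ODE engine** — the classic ~15-organ perfusion-limited
  topology for one or two compounds, integrated with a stiff solver
  (compiled right-hand side, event-restart at every dose) and a full
  mass-balance ledger (relative error < 1e-6).
* **DDI coupling** — competitive inhibition v = CL_spec·[E]·C_u /
  (1 + I_u/Ki) applied in liver and gut mucosa with the perpetrator's
  local unbound concentration; exposure ratios
  AUC_ratio = AUC_victim+perp / AUC_victim alone (likewise Cmax);
  Ki estimation by seeded multi-start least squares on log10
  concentrations against midazolam interaction profiles.
* **Evaluation statistics** — PE/MPE/MAPE, mean relative deviation
  MRD = 10^sqrt(mean((log10 c_pred − log10 c_obs)^2)), 2-fold criteria,
  5–95% population prediction intervals with coverage, and local
  sensitivity analysis (variation range 10, 9 steps).
* **Synthetic data** — dense study-design profiles and sparse
  clinical-routine TDM samples with dose-time uncertainty, with known
  ground truth for calibration and recovery tests.

## Worked example

Simulate the standard regimens (10 mg RUX twice daily ± 300 mg POS
delayed-release tablet once daily, 10 days) for the reference adult and
summarise the day-10 dosing interval:

```r
library(pbpkddi)

rux <- builtin_compound("ruxolitinib")
pos <- builtin_compound("posaconazole")
rux_reg <- load_regimen(system.file("extdata", "regimen_rux_10mg_bid.yaml",
                                    package = "pbpkddi"))
pos_reg <- load_regimen(system.file("extdata", "regimen_pos_300mg_qd.yaml",
                                    package = "pbpkddi"))

dd <- simulate_ddi(list(compound = rux, regimen = rux_reg),
                   list(compound = pos, regimen = pos_reg),
                   build_individual(demographics()),
                   interval = c(216, 228))
glance(dd)
#>        victim  perpetrator n cmax_ratio auc_last_ratio cmax_with cmax_alone
#> 1 ruxolitinib posaconazole 1      1.274          1.505     150.5      118.1
#>   auc_with auc_alone
#> 1    361.7     240.4
```

RUX alone reaches a steady-state Cmax of 118 ng/mL with an interval
AUC of 240 ng·h/mL; under POS the AUC rises ~1.5-fold and Cmax
~1.27-fold — the CYP3A4 share of RUX clearance (fm ≈ 0.44) bounds the
maximum possible AUC ratio, which is why the increase saturates with
POS dose. `autoplot(dd)` shows the per-subject ratio distribution for
population runs; `tidy()`/`glance()` methods return tibbles throughout.

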