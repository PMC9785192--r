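---
title: "Methods: whole-body PBPK modeling of the ruxolitinib-posaconazole interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modeling of the ruxolitinib-posaconazole interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, its assumptions, the provenance of
every parameter class, the numerical choices, and the limits of what the
test suite demonstrates.

## Model structure

### Physiology

A virtual individual carries organ volumes, regional blood flows,
tissue-composition fractions, hepatic and gut-wall enzyme
concentrations, GFR and hematocrit. All values descend from a single
embedded reference adult (male, 30 y, 73 kg, 176 cm, cardiac output
5.6 L/min) with ICRP-type organ data. Scaling is deliberately simple
and fully auditable: volumes scale linearly with body weight, flows
with weight^0.75, GFR with body surface area (DuBois) against 1.73 m²
with sex-specific reference values (125/105 mL/min), and females get a
mild composition shift (+25% adipose, −15% muscle). The "rest"
compartment closes the flow balance exactly, so the sum of systemic
organ flows equals cardiac output to machine precision — an invariant
the tests assert on every sampled individual.

Population variability is independent truncated-normal sampling of
age, weight and height plus a Bernoulli sex draw, followed by this
deterministic scaling. Correlated covariate sampling (as full
population databases use) is intentionally out of scope; medians of
simulated exposures are insensitive to those correlations at the
population sizes used here, which is what the reported endpoints are.

The transplant-cohort population used for the day-10 simulations
(`gvhd_population_spec()`) uses healthy physiology with cohort-typical
demographics: age 55 ± 12 (18–75), weight 75 ± 14 kg (48–115),
height 172 ± 10 cm, 40% female, n = 100. No disease-specific
physiology is modeled — no quantitative disease model exists for this
population, so healthy virtual individuals with matched demographics
are the defensible substrate, and deviations between such simulations
and clinical-routine observations are expected and informative.

### Distribution

Tissue-to-plasma partition coefficients come from tissue composition.
Two methods are implemented behind one interface, selected per
compound:

* **Rodgers–Rowland.** Moderate-to-strong bases (any basic pKa ≥ 7)
  use the acidic-phospholipid association class, with the association
  constant back-calculated from the blood-to-plasma ratio and
  hematocrit. Neutrals, weak bases and acids use the extended class
  with tissue albumin binding through a tissue:plasma albumin ratio.
  Ruxolitinib (weak base, pKa 4.3) and midazolam (pKa 6.0) use this
  method.
* **Poulin–Theil.** Lipid/water partitioning with fu_t =
  1/(1 + 0.5(1−fu_p)/fu_p) for non-adipose tissue and the
  ionization-corrected D for adipose. Posaconazole uses this method.

A scalar, loop-based transcription of the Rodgers–Rowland equations
lives in the test helpers as an independent oracle; the vectorized
implementation must agree with it to 1e-12.

### Oral absorption

The gastrointestinal tract is five lumped lumen segments (stomach,
duodenum, jejunum, ileum, colon) with a fixed pH profile (1.6, 5.6,
6.5, 7.0, 6.8), luminal water volumes (50/30/80/80/30 mL), effective
absorptive areas and first-order transit (gastric emptying half-time
15 min fasted; small-intestinal residence ≈ 3.4 h; colon ≈ 14 h).
Each segment tracks three pools per compound: drug still inside the
formulation, solid (particles or precipitate) and dissolved. Only
dissolved drug permeates, at flux P_eff × area × concentration, into
the gut-wall compartment where mucosal CYP3A4 acts before the portal
vein.

* **Weibull release** uses the release hazard h(t) =
  f(t)/(1−F(t)) of F(t) = 1 − exp(−ln2·((t−t_lag)/t50)^shape), with t
  measured since the most recent dose. With the release times used
  here (t50 = 15 min and 145 min) release is complete long before the
  next dose, so the hazard-since-last-dose formulation is exact in
  practice. The delayed-release tablet adds a gastric release block
  (enteric coating) on top of its 30-min lag.
* **Particle dissolution** is Noyes–Whitney for monodisperse spheres,
  dM/dt = −(3D/(r·h·ρ))·M·(Cs − C), with the compound's pH-dependent
  solubility as Cs. The implementation keeps the per-mass surface
  constant (fixed effective radius); a constant-surface-area variant
  exists for verification against the linear sink-condition solution.
* **Supersaturation/precipitation**: when C > Cs the excess
  precipitates first-order (default half-life 10 min, configurable);
  the precipitate joins the solid pool and can re-dissolve — the
  "treated as soluble" bookkeeping that enlarges the dissolvable
  mass. The threshold is Cs itself; neither a metastable
  supersaturation limit nor nucleation kinetics are printed anywhere,
  so the simplest tunable rule was chosen and exposed in the
  formulation file.
* **Meals** slow gastric emptying by a half-time multiplier
  1 + kcal/320, linear in caloric content (841 kcal ≈ 3.6-fold), with
  the effect decaying back to fasted state with a 1.5-h time
  constant. The meal's solid fraction is carried for reporting but
  does not drive the modifier; calories are the only documented input
  channel. This reproduces the qualitative food effect for the
  suspension (greater absorbed fraction fed than fasted) without
  claiming a mechanistic fat model.

### Systemic model and elimination

The body is the classic perfusion-limited topology: lung, adipose,
bone, brain, heart, kidney, muscle, skin, gonads, spleen, stomach
wall, gut wall, liver, a closing "rest" compartment, and arterial and
venous blood pools. Metabolism is first order throughout (no
Michaelis–Menten saturation, deliberately): for each enzyme process,
v = CL_spec·[E]·C_unbound·V_organ with the unbound equilibrated plasma
concentration as driver (well-stirred assumption). Renal filtration is
gfr_fraction × GFR × fu_p × C_arterial; biliary clearance is a
specific rate on unbound liver concentration, routed directly to an
elimination ledger (no enterohepatic recirculation). A catalytic-rate
(kcat) process without a printed Km is linearized into an effective
specific clearance and labeled as such in the compound file.

The right-hand side is compiled C (deSolve's compiled-model
interface). Amounts are in µmol (lumen masses in mg), time in hours.
The solver is `lsoda` with default tolerances rtol 1e-8 / atol 1e-10
for single simulations (population loops use 1e-6/1e-9; the grid
refinement and superposition tests bound the effect of this choice
well below 1%). Integration restarts at every dose time, infusion
edge and meal event via zero-impulse events, so discontinuities never
cross a solver step. Mass balance — dose = formulation + solid +
dissolved + transited-out + in-body + cumulatively eliminated — is
checked at every output time; the suite requires relative error
< 1e-6.

A `minimal` topology (one well-stirred compartment with the same
elimination terms) exists for verification: the i.v. bolus solution
must match C(t) = (D/V)·e^{−kt} to < 0.01%, and the clearance
sensitivity of AUC must be −1.

### The interaction

Competitive CYP3A4 inhibition multiplies the victim's CYP3A4 rate by
1/(1 + I_u/Ki) wherever the enzyme is expressed (liver and gut
mucosa). The driving concentration is the perpetrator's local unbound
tissue concentration (fu_p × C_tissue/Kp); an unbound-venous-plasma
alternative is available (`inhibition_driver = "plasma"`), since the
reference software's internal choice is not documented. Using the
local liver concentration is the standard mechanistic choice and
produces the larger gut contribution that makes the oral-victim AUC
ratio exceed the i.v.-victim ratio — a structural pattern the tests
assert with the midazolam probe.

Both DDI arms run on identical individuals and seeds, so ratio spread
reflects only the interaction. Ki estimation minimizes squared log10
concentration residuals over the with-perpetrator datasets with
seeded multi-start bounded search on log10(Ki); squared-log residuals
are consistent with the log-scale MRD metric used for evaluation. The
recovery experiment plants Ki = 5.22e-3 µmol/L, adds 15%
multiplicative residual noise, and requires the estimate within 20%
in at least 8 of 10 seeds.

### Evaluation statistics

PE_i = (c_pred,i − c_obs,i)/c_obs,i × 100%; MPE is the mean of PE and
MAPE the mean of |PE| (the absolute value and, for MRD, the square
root are written explicitly; both are occasionally lost in rendered
formula transcriptions, but the definitions are unambiguous from the
cited metric). MRD = 10^sqrt(mean((log10 c_pred − log10 c_obs)^2)),
which equals the fold-error for a single pair. The 2-fold criterion
counts ratios inside [0.5, 2] with **inclusive** boundaries; the
convention is not universal, so it is stated here and pinned by a
test. Below-LLOQ observations are excluded from all statistics and
from coverage numerators and denominators, with the exclusion count
reported. Prediction intervals are pointwise empirical 5–95%
quantiles over subjects, and coverage interpolates the band linearly
in time at the observation instants.

Local sensitivity scans a parameter over log-spaced multipliers in
[1/10, 10] with at most 9 steps and reports S =
(ΔAUC/AUC)/(Δp/p) centered at the base point, likewise for Cmax.

## Parameter provenance and calibration

Parameters fall into three classes, annotated field-by-field in the
YAML files under `inst/extdata`:

1. **Printed literature values, carried verbatim**: the specific CYP
   clearances of ruxolitinib (0.46 and 0.65 L/µmol/min for CYP3A4 and
   CYP2C9), the optimized Ki (5.22e-3 µmol/L) and its literature start
   (0.42 µmol/L), all Weibull and particle formulation parameters
   (t50 145/15 min, shapes 1.67/1.10, lag 30 min, radius 1.9 µm,
   unstirred layer 140 µm, density 0.37 g/cm³), the two tagged
   permeabilities (5.05e-5 cm/min suspension; 4.80e-5 cm/s
   delayed-release tablet — both preserved with explicit unit tags and
   normalized to cm/min at load, preventing silent 60-fold errors),
   the two solubility anchors (0.79 mg/mL at pH 1; 0.001 mg/mL at
   pH 7), and the meal conventions (841/200 kcal, solid fraction 0.8).
2. **Derived calibrations with a stated closed form**: the
   solubility gain per charge (27.65) solves the two-anchor system of
   the pH-solubility model exactly; the calculated-permeability
   constant (3.3147e-5) fixes P = K·10^(0.5·logP)/sqrt(MW) to the
   documented posaconazole value 1.81e-4 cm/min.
3. **Identified values**: quantities whose sources live in
   unpublished supplementary material (posaconazole logP, fu_p,
   UGT1A4 and biliary clearance, per-segment adapted intestinal
   solubility of the tablet; ruxolitinib effective permeability;
   midazolam probe clearance; hepatic and gut enzyme concentrations)
   were identified against published exposure metrics — standard PBPK
   parameter identification against clinical endpoints, at this
   package's scale. They are
   plain YAML fields, flagged `identified`, and meant to be replaced
   wherever measured values exist.

Two mapping factors deserve explicit mention. "Specific"
permeabilities in the source convention are referenced to villous
mucosal area, which is far larger than this package's smooth-surface
segment areas; the suspension formulation therefore carries an
`area_amplification` of 40 (within the anatomical villous
amplification range) and the tablet, whose permeability is an
apparent cell-monolayer value, carries 1.3 as the in vitro → in vivo
effective mapping. Both are declared in the formulation files, next
to the verbatim values they map.

## Problem sizes and numerical settings

The reported endpoints use n = 100 virtual individuals, 10 simulated
treatment days, an output grid of 0.1 h, and NCA on the day-10
interval (216–228 h for the twice-daily victim, 216–240 h for the
once-daily perpetrator). The day-10 reporting window follows the
published day-10 convention; whether single-dose or steady-state
interval metrics were meant in the interaction section is not stated
anywhere, so steady state on day 10 is the package default and both
are computable. The Ki recovery experiment uses two interaction arms
(200 and 400 mg), three subjects and twelve samples per arm, and a
0.5-h evaluation grid. The coverage calibration uses a 100-subject
band and 40 held-out subjects. These sizes were chosen as the
smallest that make the Monte-Carlo error comfortably smaller than the
tolerances being checked.

## Known limitations

* Saturable metabolism, autoinduction, time-dependent inhibition,
  transporters and metabolite kinetics are not modeled (first-order
  everywhere, the standard choice for these compounds).
* The five-segment lumen is coarser than a full compartmental
  absorption-transit model; regional fluid dynamics, bile-micelle
  solubilization and enterohepatic recirculation are absent, so
  absolute suspension bioavailability is approximate even though its
  qualitative behavior (solubility-limited absorption, food effect,
  precipitation) is mechanistic.
* Blood-to-plasma partitioning is simplified (B:P enters only the
  strong-base partition class); venous blood and plasma
  concentrations are treated as equal for reporting.
* The synthetic-data generator emulates design features (sampling
  schedules, log-normal noise, dose-time jitter, co-timing
  assumptions) but not covariate effects, co-medication or disease
  progression — so green calibration tests demonstrate internal
  consistency of the pipeline, not fidelity to any real cohort.
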