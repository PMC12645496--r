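---
title: "Mechanistic model, synthetic cohorts, and model-informed prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic model, synthetic cohorts, and model-informed prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gctov)
```

## The model

`gctov` simulates granulosa cell tumors of the ovary under combination
therapy with a TRAIL-producing oncolytic virus and the procaspase-3 activator
PAC-1. The state couples five subsystems:

* **Tumor cell cycle.** Quiescent cells `Q` enter the G1 phase at rate `a1`,
  progress into a chain of `j = 6` transit compartments `A1..A6`
  (the active phases) at rate `a2`, traverse them at `ktr = j/tau`, and
  return to `Q` with mitotic doubling (`2 ktr Aj`). Apoptosis removes G1
  cells at `d2 (1 + E)` and active-phase cells at `d3 (1 + E)`, where `E`
  is the drug effect. The transit chain gives an Erlang-distributed
  cell-cycle duration with mean `tau` — the standard delay construction in
  cell-population and signal-transduction models.
* **Oncolytic virus.** Free virions `V` infect cycling cells (G1 plus all
  active compartments) with the saturating per-cell hazard
  `kappa V / (eta_half + V)`; infected cells `I` lyse at `delta`, releasing
  `alpha` virions each, and virions decay at `omega`.
* **Innate immunity.** Infected cells drive cytokine production from the
  homeostatic `Cprod_star` toward `Cprod_max` with half-effect `psi_half`;
  cytokine `C` recruits phagocytes `P` at `kcp C / (C_half + C)`, and
  phagocytes kill tumor cells at `kp P / (1 + k Q)`-type saturating rates.
* **PAC-1 pharmacokinetics.** Oral depot `PA` (ng) absorbs at `ka` into the
  plasma concentration `PPAC` (ng/ml, volume `V_PAC`), with elimination
  `kep` and a peripheral compartment `Pe` (`k12P`, `k21P`).
* **TRAIL disposition.** Free TRAIL `T` follows an irreversible-binding
  target-mediated (TMDD) model with receptor pool `R0`, binding `kon`,
  complex internalization `kint`, elimination `kel`, and a peripheral amount
  compartment `TA`; infected-cell lysis adds `alpha_T delta I`.

The pharmacodynamic effect combines two Hill terms
`E_x = Emax_x c^gamma_x / (EC50_x^gamma_x + c^gamma_x)` as
`E = E_P + E_T + Psi E_P E_T` by default, with the interaction weight `Psi`;
Bliss independence (`E_P + E_T - E_P E_T`) and a PAC-1-only reduction are
available via `gct_config(pd_combination=)` for robustness checks. The
combination rule, and the saturating form of the cytokine production
`Cprod(I)`, are modelling choices of this package: the published sources for
this system state the ingredients (maximal efficacies, EC50s, Hill slopes,
potency; homeostatic and maximal production rates) but not the composite
formulas.

### Corrected equation variants

The printed equation system this model descends from carries several
typographic inconsistencies. Each is resolved behind a `gct_config()` flag so
the literal readings remain simulable:

* `variant_infection_sign`: the infection target is `G1 + N` (all cycling
  cells; default) rather than the printed `G1 - N`, which can drive infected
  cells negative.
* `variant_g1_entry`: entry into `A1` uses `a2 G1` (consistent with the G1
  balance; default) rather than the printed `a1 G1`.
* `variant_active_total`: the total active population `N` is the algebraic
  sum of the transit compartments (default); the redundant printed ODE for
  `N` can be integrated instead (`ode_eq5`).
* PAC-1 plasma balance uses `-(kep + k12P)` (the printed `kep - k12P` is
  negative with the tabulated rates and destabilizes the subsystem); oral
  absorption is `ka PA / V_PAC`; the TRAIL central/peripheral transfer is
  amount-conserving (`-k12 T + k21 TA/V` against `dTA/dt = k12 V T - k21 TA`);
  and the bound-TRAIL equation uses the standard irreversible-TMDD form
  `kon (R0 - TP) T - kint TP`.

### Derived quantities

`Tprod` is not a free parameter: it is chosen so the drug-free, tumor-free
TRAIL subsystem rests at the homeostatic concentration `T* = 0.0809` ng/ml,
giving `Tprod = kel T* + kon T* (R0 - TP*)` with
`TP* = kon R0 T* / (kint + kon T*)` (about 4.60 ng/ml/day). The infection-free
immune equilibrium is `C* = Cprod_star / k_elim`, `P* = phi(C*) / gamma_P`.
A 100-day tumor-free simulation holds `C`, `P` and `T` at these values to
well under 0.5% — the package's homeostasis check.

### Units

Tumor cells, phagocytes and virions are carried in scaled units of
`cells_per_unit = 1e10`; volumes convert at `cells_per_cc = 1e9` cells/cm^3,
so 1 cc is 0.1 scaled units. Doses convert mg to ng (`1e6`); an MOI `m`
inoculum against `n` cells deposits `m n / 1e10` scaled virions at time
zero. `alpha_T` is applied per scaled cell-unit.

## Numerics

Integration uses the adaptive explicit Runge-Kutta 4(5) pair
(`deSolve`, `rtol = 1e-6`, `atol = 1e-9`, `hmax = 0.25` d) over a compiled C
translation of the derivative field; an R reference implementation
(`gct_rhs()`) defines the field readably and is cross-checked against both
an independent hand-written oracle and the compiled core in the test suite.
Dosing is impulsive: the solver is restarted at every dose event with the
target state incremented (oral depot in ng, virions in scaled units), which
keeps the field autonomous between events. A fixed-step classical RK4 with
`dt = 1e-4` d serves as the solver oracle: day-21 burden under the reference
protocol (21 daily 375 mg doses, MOI 0.03 on 1e9 cells) agrees with the
adaptive solution to about 1e-9 relative. The field is
non-negativity-preserving under the corrected variants; `clip_negative`
additionally projects the state at zero before derivative evaluation to
guard the literal variants.

## Sensitivity analysis

`local_sensitivity()` perturbs one parameter at a time over nine evenly
spaced fractions spanning −85%..+85%, re-simulates the reference protocol,
and scores each parameter by the maximal absolute relative change of day-21
tumor burden; ranking is by descending influence with alphabetical
tie-break. `j` is excluded (scaling an integer compartment count is
ill-defined), `tau` enters only through `ktr` (it is retained as an inert
control: its influence is exactly zero), and the `Emax`/`Psi` parameters are
excluded because a ±85% scaling leaves their admissible (0,1) range.

Measured on the corrected model, the ranking is dominated by the innate
immune loop: `kcp` and `kp` tie at the top (final burden depends on their
product — phagocyte recruitment is linear in `kcp` and killing linear in
`kp`), followed by `Cprod_star`, `C_half`, `gamma_P` and `k_elim`. The
cell-cycle rates `a2` and `d2` are mid-table and `a1` is far down. The
mechanism is visible in the parameters: `psi_half` is about 1.1e6 cells, so
any infection saturates cytokine production and recruits phagocytes toward
`kcp/gamma_P`, making immune kill the controlling term of final burden. A
characterization sometimes given for this system — that the cell-cycle entry
and apoptosis rates `a1` and `d2` dominate final tumor volume — does not
hold under these equations and parameter values; the package reports the
measured ranking rather than asserting it.

## The synthetic cohort generator

The generator emulates the *schema* of clinical GCT cohorts — per-patient
covariates plus either continuous MRI tumor volumes at 3-4 time points or a
tertile-coded size category — with outcomes produced by the model itself, so
every downstream stage is testable without external data. Defaults
(all configurable):

* n = 500 patients; age ~ Normal(55, 12) truncated to [18, 90];
  BMI ~ Normal(27, 5) truncated to [15, 50]; ethnicity and laterality
  categoricals; mutation/stage prevalences BRCA 0.10, TP53 0.20,
  PIK3CA 0.15, lymph-node 0.30.
* Baseline volume log-normal with median 8 cc and 0.5 log-sd; multiplicative
  log-normal measurement noise with 0.1 log-sd on every recorded volume.
* Covariates act through the mechanism: lymph-node positivity multiplies
  `a1` by 1.2, BRCA multiplies `d2` by 1.15, TP53 by 0.85, PIK3CA
  multiplies `a1` by 1.10. The per-patient parameters are stored in a hidden
  ground-truth side table that allows exact reconstruction of the pre-noise
  volumes.
* Treatment and observation: daily 375 mg PAC-1 for 21 days and MRI at
  days {0, 7, 14, 21} (four-point grid) or {0, 10, 21} (three-point). Two
  properties of the corrected model drove these choices. First, at
  homeostasis the phagocyte kill rate (~0.41/day) exceeds net proliferation
  (~0.27/day), so simulated tumors regress even untreated; observation
  grids months apart would record volumes at 1e-30 cc and below, which no
  imaging cohort could contain. Second, any viral inoculum ignites the
  cytokine-phagocyte surge (kill rates of tens per day) and eliminates the
  tumor within days — larger tumors sooner — so the generator's default
  protocol is drug-only (`moi = 0`), emulating cohorts under systemic
  therapy, and the observation grid spans the treatment course where
  successive volumes remain of comparable magnitude. The full-virus
  reference protocol remains the default everywhere outside the generator.

What the generator does **not** emulate: registry-realistic covariate
marginals, inter-patient random parameter variability beyond the covariate
channels, missingness, or imaging detection limits. Passing tests on these
cohorts therefore demonstrate internal consistency of the pipeline — not
transportability to real MRI series.

## Enrichment

`enrich_continuous()` re-simulates each patient from their observed baseline
volume under the treatment protocol and appends the requested model
variables at the requested times (default: tumor burden and the infection,
immune and drug states at the post-baseline MRI times). With an
`effect_map`, the simulation additionally individualizes parameters through
the patient's observed covariates — the same mechanistic map the generator
uses — which is the mode the pipeline and the package's evaluations use.
On a noise-free cohort the appended burden features reproduce the observed
volumes exactly (the informativeness-by-construction premise); both modes
are deterministic functions of the observed row.

`enrich_categorical()` implements the tertile protocol: each size-category
group receives one shared Uniform(0, 100) cc initial volume (a per-patient
mode is available), the model is solved per group, and appended features are
tertile-coded before merging. The shared-draw reading makes the appended
columns group-constant — effectively a re-coding of the size category — and
is retained because it is the literal protocol; the per-patient mode is the
statistically meaningful alternative.

## Evaluation harness

`fit_linear_report()` is OLS with intercept; it reports 5-fold
cross-validated RMSE (the default evaluation; the in-sample RMSE with
divisor n is also reported), per-coefficient two-sided t-test p-values, the
F-test p-value, and the features significant at 0.05. `fit_nn_repeated()`
is the repeated single-hidden-layer protocol: 50 units (`nnet`), stratified
70/30 splits, features standardized by training-split statistics, repeated
(default 100 times) with fresh splits and initializations; confusion-matrix
metrics are macro-averaged over classes and then averaged over repetitions.
`compare_enrichment()` runs each task twice on identical folds/splits —
clinical columns only versus clinical plus enrichment columns (constant
columns dropped) — and reports the deltas.

Measured on the default synthetic cohorts, the regression benefit of
enrichment is near zero: with a drug-only protocol the mapping from baseline
to later volumes is almost linear and identical for patients with the same
covariates, so the appended features are (almost) linear transforms of
`Volume1` and the covariate dummies already in the design. The
cross-validated RMSE difference is then dominated by fold noise, and the
"features help" direction holds in only about half of the seeds. This is a
structural property of the synthetic world — a mechanistic feature can only
help prediction when the mechanism is nonlinear in, or draws on information
beyond, the existing covariates — and is reported as measured rather than
asserted. The package's calibration checks (null p-value uniformity,
chance-level accuracy on permuted labels, leakage controls) all hold.

## Parameter recovery

`fit_growth_params()` refits selected parameters (default `a1`, `d2`) by
Levenberg-Marquardt least squares on log volumes across a set of observed
trajectories, starting from 1.5x the true values; the log-parameter scale
keeps rates positive, and the Gauss-Newton steps handle the shallow
(a1, d2) ridge far better than derivative-free search. The packaged evaluation
uses 20 trajectories with baselines drawn from the cohort distribution,
observed every 2-3 days over the 21-day course under the drug-only
protocol: under the viral protocol the immune-surge onset time is so
sensitive to the baseline that log-residuals are dominated by surge-phase
misalignment and noisy refits do not converge meaningfully. Noise-free
recovery is exact to ~1e-4 relative; with 5% log-normal observation noise
the median error over ten replicates is reported by the acceptance script.

## Problem sizes

Desk-scale defaults keep every check inside a few minutes on one CPU:
cohorts of 500 patients, 10 generator seeds for directional claims,
100-repetition neural protocols on one cohort, 1000 random states for the
derivative-field oracle, and a 1e-4-day fixed-step oracle for the solver
check. Registry-scale cohort sizes (10^4-4x10^4 patients) are supported by
the same code paths.
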