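# ufhpk — population pharmacokinetics of unfractionated heparin in cardiopulmonary bypass

Unfractionated heparin (UFH) given during cardiopulmonary bypass (CPB)
is neutralized at the end of surgery with protamine sulfate, yet
anticoagulant activity can reappear hours later — *heparin rebound* —
as drug bound in a peripheral pool redistributes back into plasma.
`ufhpk` is an R package for pharmacometricians and perfusion
researchers that models this process end to end: it fits a
two-compartment population pharmacokinetic model to plasma anti-FIIa
activity measured during and after CPB, validates the fit, and
simulates post-operative protamine regimens to score rebound.

## The model

Amounts in the central (`X_c`) and peripheral (`X_p`) compartments
follow first-order kinetics,

```
dX_c/dt = K21·X_p − (K12 + K10)·X_c
dX_p/dt = K12·X_c − K21·X_p
```

parameterized as clearances and volumes (`K10 = CL/V_c`, `K12 = Q/V_c`,
`K21 = Q/V_p`). Irregular intravenous boluses are combined by exact
superposition of the closed-form single-dose solution (hybrid rates α,
β). Protamine neutralization at time `T_neu` instantly clears the
central compartment (`X_c := 0`) while leaving `X_p` intact; the
subsequent back-distribution

```
X_c(T_neu + τ) = K21·B·(e^(−βτ) − e^(−ατ)) / (α − β),   B = X_p(T_neu)
```

is the rebound curve, peaking at `τ* = ln(α/β)/(α−β)`. On top of the
structural model sit log-normal inter-individual variability, a hybrid
(proportional + additive) residual-error model, and linear/conditional
covariate effects — estimated by FOCE with interaction
(`foce_fit()`), with stepwise covariate selection at the ΔOFV
thresholds 6.63 (forward, p = 0.01) and 10.83 (backward, p = 0.001).
Bootstrap, visual predictive check and CWRES diagnostics
(`bootstrap_model()`, `vpc()`, `gof_table()`) validate a fit. Because
no individual-level clinical dataset is public, a synthetic trial
generator (`generate_trial()`) reproduces the study design — dosing at
375 IU/kg + 125 IU/kg priming, 30-min intra-CPB sampling, post-op
samples at 2/4/8/12/24 h, the 1:29 assay dilution into the 0.0–0.6
IU/mL anti-FIIa window — so every stage is testable offline.

## Worked example

A typical subject receives the mean loading dose (24805 IU) and mean
priming dose (8516 IU) at time zero and is neutralized at the mean CPB
time, 2.04 h, with the reference population estimates (CL 1.18 L/h,
V_c 3.04 L, Q 0.171 L/h, V_p 8.01 L):

```r
library(ufhpk)
p <- pk_params(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
h <- dosing_history(c(0, 0), c(24805, 8516), t_neu = 2.04)

rebound_peak(h, p)
#> $time
#> [1] 9.466541
#> $conc
#> [1] 0.03358178

round(concentration(2.04 + c(2, 4, 8, 12, 24), h, p), 4)
#> [1] 0.0223 0.0306 0.0335 0.0320 0.0258
```

The rebound peaks 7.4 h after neutralization at 0.034 IU/mL; among the
scheduled post-operative samples the 8-h one is maximal, and activity
is still above the 0.02 IU/mL persistence threshold at 24 h — the
signature of heparin rebound. The derived distribution-phase rate α =
0.447 /h corresponds to an initial half-life of 93 min.

Comparing protamine infusion regimens under the clamp model (central
compartment held at zero while the infusion runs):

```r
compare_regimens(h, p, horizon = 48)
#> Protamine regimen comparison (rebound metrics):
#>           label   peak t_peak conc_24h time_above
#>      bolus only 0.0336   7.43   0.0258       36.0
#>   25 mg/h x 6 h 0.0295  13.40   0.0253       28.7
#>   25 mg/h x 8 h 0.0283  15.40   0.0252       26.2
#>  25 mg/h x 12 h 0.0260  19.40   0.0248       21.2
#>  25 mg/h x 16 h 0.0239  23.40   0.0238       16.1
#>  25 mg/h x 24 h 0.0201  31.40   0.0000        2.4
```

Longer infusions strictly lower the rebound peak; the 24-h infusion
suppresses it best, mirroring the published comparison of 6-h vs 24-h
regimens.

A pipeline-style interface is also available: `ufh_cli(c("simulate",
"--config", "run.yaml"))` (and `fit`, `bootstrap`, `vpc`, `gof`,
`regimen`) with a YAML run configuration; see `inst/scripts/ufhpk.R`
for an `Rscript` launcher.

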