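---
title: "Modelling unfractionated heparin during and after cardiopulmonary bypass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling unfractionated heparin during and after cardiopulmonary bypass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufhpk)
```

## The problem

Cardiac surgery on cardiopulmonary bypass (CPB) requires full
heparinization with unfractionated heparin (UFH), reversed at the end of
bypass with protamine sulfate.  Hours after an apparently complete
neutralization, anticoagulant activity can reappear in plasma — *heparin
rebound* — a recognized contributor to post-operative bleeding.  The
mechanistic explanation modelled here is distributional: UFH bound in a
peripheral pool (plasma proteins, endothelium, macrophages) escapes
neutralization, then redistributes back into plasma after the protamine
is gone.

`ufhpk` implements a population pharmacokinetic analysis of this
process.  Plasma UFH is measured as anti-FIIa activity (IU/mL), the
assay surrogate used throughout; "concentration" below always means
central-compartment anti-FIIa activity.

## Structural model

A two-compartment model with first-order elimination, dosed by
intravenous boluses:

$$
\frac{dX_c}{dt} = K_{21}X_p - (K_{12}+K_{10})X_c, \qquad
\frac{dX_p}{dt} = K_{12}X_c - K_{21}X_p,
$$

parameterized in clearance–volume form ($CL$, $V_c$, $Q$, $V_p$; $K_{10}
= CL/V_c$, $K_{12} = Q/V_c$, $K_{21} = Q/V_p$).  The closed-form
solution uses the hybrid rates $\alpha,\beta$ (eigenvalue magnitudes of
the disposition matrix), with bolus doses combined by superposition of
shifted single-dose terms.  Irregular intra-operative boluses are
therefore handled exactly, without numerical integration.

Neutralization at time $T_{neu}$ is modelled as an instantaneous reset:
$X_c(T_{neu}) := 0$ while $X_p$ is untouched.  From that initial
condition the central compartment refills by back-distribution and
drains again:

$$
X_c(T_{neu}+\tau) =
\frac{K_{21}\,B\,(e^{-\beta\tau} - e^{-\alpha\tau})}{\alpha-\beta},
\qquad B = X_p(T_{neu}),
$$

a single-humped rebound curve peaking at $\tau^* =
\ln(\alpha/\beta)/(\alpha-\beta)$.  At the reference estimates
($CL$ 1.18 L/h, $V_c$ 3.04 L, $Q$ 0.171 L/h, $V_p$ 8.01 L) this gives
$\alpha = 0.447\,h^{-1}$ (distribution half-life 93 min) and a rebound
peak 7.4 h after neutralization:

```{r}
p <- pk_params(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
h <- dosing_history(c(0, 0), c(24805, 8516), t_neu = 2.04)
rebound_peak(h, p)
concentration(2.04 + c(2, 4, 8, 12, 24), h, p)
```

Numerical choices worth knowing:

* Units are IU (amounts), L (volumes), h (times); concentrations are
  reported in IU/mL through a single division by 1000 at the profile
  boundary.  Bioavailability is fixed at 1 (intravenous dosing).
* When the two hybrid rates coincide to within $10^{-9}$ relative
  (an unphysiological corner), the $\alpha-\beta$ quotients switch to
  their L'Hôpital limit forms to avoid cancellation.
* Doses are rejected after $T_{neu}$ — the piecewise model defines no
  such branch — and a dose falling exactly on an output time
  contributes fully at that time (post-bolus state, the NONMEM event
  convention).
* An independent check via `ode_profile()` integrates the differential
  equations with `deSolve::lsoda` (impulse dose events, a replacement
  event at the reset) at tolerances `1e-10`/`1e-12`; the test suite
  holds closed form and integrator to within $10^{-6}$ relative over
  200 random parameter/dosing scenarios.

## Population model

Inter-individual variability is exponential, $P_i = P_{pop}e^{\eta_i}$
with $\eta_i \sim N(0, \omega^2)$ and a diagonal $\omega^2$ per
parameter (variances fixed to zero disable the effect — the reference
model fixes $\omega^2_{V_p} = 0$).  Residual error is the hybrid model
$C_{obs} = C_{pred}(1+\varepsilon_1) + \varepsilon_2$; the additive
variance may be fixed to zero, giving the purely proportional error of
the reference model ($\sigma^2_{pro} = 0.139$).  Both configurations
are supported because the additive term, while part of the model
definition, is often estimated away in this kind of data.

Covariates act on the typical values: continuous effects (body weight,
age) linearly, $P_i = P_{pop}(1 + \theta_{COV}(\overline{COV} -
COV_i))$ with a *signed* coefficient and a centring reference that
defaults to the sample mean (66 kg and 53.4 y for the reference
scenario); the categorical sex effect conditionally, multiplier 1 for
males (coded 0) and $\theta$ for females.

## The synthetic trial generator

No individual-level clinical dataset is available, so all estimation
and validation machinery is exercised on synthetic trials that emulate
the adult CPB study design:

* 32 completers; weight truncated-normal (mean 66, sd 9, bounds 41–82
  kg), age (53.4, 13, 18–74 y), 19/32 female.  Only mean and range are
  published for the covariates; the sd values place the bounds near
  ±2.5 sd.
* Dosing: 375 IU/kg at time zero (3 mg/kg at the 125 IU/mg label
  factor), 125 IU/kg pump-priming bolus at CPB start, and 0–2 irregular
  boluses of 1000–5000 IU at uniform times inside the bypass period.
  The distribution of the irregular boluses is not published; these
  defaults keep simulated total doses in the reported 25000–45000 IU
  span.  The 10-minute gap between the loading dose and CPB start is
  collapsed to zero, the published time origin.
* CPB duration (= neutralization time) truncated-normal (2.04, 0.5,
  0.95–3.29 h).
* Sampling every 30 min during CPB from 10 min after the loading dose,
  and nominally 2, 4, 8, 12, 24 h after neutralization with Gaussian
  jitter (sd 0.1 h), matching the documented deviation of actual from
  scheduled times.
* Assay: pre-neutralization samples are diluted 1 part plasma + 29
  parts pooled normal plasma (so ÷30) into the 0.0–0.6 IU/mL anti-FIIa
  window and back-calculated (reportable ceiling 18 IU/mL);
  post-neutralization samples run neat.  Readings at or below the lower
  bound are flagged below quantitation (blank observation, excluded
  from fitting by the M1 convention).  Diluted readings above the
  window ceiling are treated as re-assayed at a higher dilution — the
  routine laboratory response to an over-range sample, and the only
  reading consistent with reported plateau activities up to 19 IU/mL,
  above the 18 IU/mL ceiling a single 1:29 dilution could report.
  Under proportional error the dilution factor cancels, so the
  re-assayed report equals the unclamped measurement.  (An earlier
  hard-ceiling variant of the generator censored ~1% of observations —
  precisely the information-rich early samples — and induced a
  systematic upward clearance bias of ~9% in replicate refits; the
  re-dilution model removes it.)  Neat post-neutralization readings
  cap at the window bound, which rebound-scale activities never
  approach.

What the generator does *not* emulate: hemodilution and temperature
effects of the CPB circuit, ultrafiltration, assay-plate drift, or any
pharmacodynamic feedback from the patient's coagulation status to the
irregular dosing.  Passing tests therefore demonstrate correctness of
the estimation machinery under the stated design, not robustness to
those real-data complications.

## FOCE estimation

`foce_fit()` implements first-order conditional estimation with
interaction.  Per subject, the empirical Bayes $\hat\eta$ minimizes the
penalized joint deviance (residual variance evaluated at the individual
prediction); the prediction is then linearized about $\hat\eta$ and the
Gaussian marginal likelihood of the linearized model accumulated into
$-2\log L$.  Implementation details:

* The inner $\hat\eta$ search is a damped Gauss–Newton iteration with a
  *gradient-norm* stopping rule (default $10^{-8}$), falling back to a
  generic quasi-Newton if a direction fails.  Stopping on the gradient
  rather than on function decrease makes the outer objective a smooth,
  path-independent function of the population parameters; with a
  decrease-based inner stop the outer optimizer reproducibly stalled
  far from the optimum.
* The outer optimization runs `nlminb` on log-transformed structural
  and variance parameters (covariate coefficients on the natural
  scale), restarted from the incumbent until the OFV stabilizes —
  PORT's false-convergence exit is common on nested surfaces.
* The OFV includes its $\log 2\pi$ constants, so tiny closed-form cases
  match textbook normal deviances exactly; $\Delta$OFV-based decisions
  are unaffected.  Absolute values are not comparable to software that
  drops the constants.
* Standard errors come from the inverse central-difference Hessian of
  OFV/2 in the natural parameterization (relative step $10^{-4}$); a
  non-positive-definite Hessian leaves the fit usable with SEs marked
  unavailable.
* Variance components initialized at zero are held fixed at zero;
  paper-faithful runs start the $\theta$s at 50% perturbations of the
  generating values and variances at 0.1.

The test suite compares the FOCE objective against an independent
adaptive Gauss–Hermite quadrature oracle (21 nodes per dimension).  A
measured property of FOCE worth stating plainly: its linearization
error grows roughly in proportion to the residual variance.  At
$\sigma^2_{pro} = 0.005$ the FOCE and quadrature objectives agree to
better than 0.15 (one $\eta$) and 0.5 (two $\eta$s) on 3–5-subject
toys; at the reference-scale $\sigma^2_{pro} \approx 0.14$ the gap on
such toys can reach one OFV unit.  The agreement tests therefore use
low-noise toys, where any residual discrepancy would indicate an
implementation defect rather than the known approximation error.

Stepwise covariate selection follows the forward-inclusion /
backward-elimination convention: a candidate enters if it lowers the
OFV by more than $\chi^2_1(0.01) = 6.63$ and survives elimination only
if its removal raises the OFV by more than $\chi^2_1(0.001) = 10.83$.
Under a null model the forward test's empirical type-I rate in the
suite's 200-replicate calibration is 1%, with the 99th percentile of
$\Delta$OFV at 5.4 — consistent with the nominal $\chi^2_1$ reference.

## Validation machinery

* `bootstrap_model()` resamples subjects with replacement to the
  original count and refits (default 1000 replicates, 95% percentile
  intervals with 90% available — published summaries use both
  conventions).  Failures are counted, never silently dropped.
* `vpc()` re-simulates every subject's exact design (default 1000
  replicates) and overlays observed 5/50/95th percentiles on the
  simulated percentile bands.  Bins are the *nominal* design times —
  the 0.5-h intra-CPB grid and the post-operative schedule — with
  jittered actual times assigned to the nearest nominal time; the
  sparse post-operative design makes quantile-based binning unstable.
* `gof_table()` reports PRED ($\eta = 0$), IPRED (empirical Bayes
  $\eta$) and CWRES under the FOCE linearization (residual standardized
  by the Cholesky factor of the linearized marginal covariance).  On
  well-specified 100-subject simulations CWRES are standard normal to
  within mean ±0.1 and sd 0.8–1.2, with ≥99% inside (−4, 4).

## Protamine regimen simulation

The published analysis simulates post-operative protamine infusions
(25 mg/h, 6–24 h) without stating a binding mechanism.  The package's
*clamp* model is the minimal extension of the bolus assumption: while
the infusion runs, anything re-entering the central compartment is
neutralized instantly, so the central activity is pinned at zero and
the peripheral pool drains at $K_{21}$; when the infusion stops,
rebound restarts from the remaining peripheral amount.  Consequences:
the post-infusion peak scales as $e^{-K_{21}D}$ in the duration $D$
(strictly decreasing, every infusion beats bolus-only), and the
infusion *rate* is metadata — any rate sufficient for neutralization is
equivalent.  A stoichiometric-binding model would make the rate
meaningful; it is left as an explicit extension hook.  Simulated
regimen curves are noise-free typical-subject profiles.

```{r}
cmp <- compare_regimens(h, p, horizon = 48)
cmp$metrics[, c("label", "peak", "t_peak", "conc_24h")]
```

## Problem sizes used by the test suite

Simulation studies in the shipped tests are sized for a laptop-scale
run while preserving each check's statistical meaning: the single-seed
recovery fit uses the full 100-subject design; the replicate bias study
uses 5 replicates of 40 subjects (mean-bias standard error ≈ 2.5%,
against a ±10% acceptance band); the likelihood-ratio null calibration
uses 200 replicates of 20 IIV-free subjects; bootstrap consistency uses
50 replicates of an IIV-free 30-subject trial; VPC coverage uses 100
simulation replicates.  The user-facing defaults (`n_rep = 1000`,
`n_sim = 1000`) match the published validation scale.

## Known limitations

* The clamp mechanism ignores protamine kinetics and stoichiometry;
  infusion rate does not enter the prediction.
* No inter-occasion variability, no off-diagonal $\omega$ blocks, no
  saturable elimination, no three-compartment extension.
* BLQ records are discarded (M1) rather than likelihood-integrated
  (M3); rebound-phase observations sit well above the limit, so the
  choice is immaterial for the shipped scenarios.
* FOCE's objective differs from the exact marginal likelihood in
  proportion to the residual noise (quantified above); stepwise
  decisions rest on $\Delta$OFV, which is far less sensitive to this
  than absolute values.
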