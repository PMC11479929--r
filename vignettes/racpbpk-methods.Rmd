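---
title: "Methods: a hybrid PBPK model for ractopamine residues in goats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid PBPK model for ractopamine residues in goats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racpbpk)
```

## The model

`racpbpk` implements a whole-body physiologically based pharmacokinetic
(PBPK) model for ractopamine (RAC), a beta-adrenoceptor agonist growth
promoter, in the goat. The model is *hybrid*: liver, spleen, kidney,
heart and lung are flow-limited (perfusion-limited) compartments whose
venous outflow leaves at the tissue/partition equilibrium
$C_i/P_i$, while muscle, fat, brain and the lumped remaining tissue are
membrane-limited, each split into a vascular and a cellular
sub-compartment exchanging across a permeability barrier at rate
$Pa_i\,(C_{i,\mathrm{blood}} - C_{i,\mathrm{tissue}}/P_i)$.

Oral dosing enters a single gastric compartment (the ruminant
forestomachs lumped into one), empties into the intestine at the
gastric-emptying rate $K_{st}$, and is then absorbed into the liver at
$K_a$ in competition with first-order fecal loss at $K_{gut}$, so the
oral bioavailability is

$$F = \frac{K_a}{K_a + K_{gut}} = \frac{0.9861}{0.9861 + 0.9016} = 0.5224 .$$

Elimination is linear: hepatic clearance $Cl_{he}$ acts on the free
equilibrium liver concentration ($Cl_{he} \cdot P_{free} \cdot
C_{li}/P_{li}$), renal clearance $Cl_{re}$ likewise on the kidney and
routes to a cumulative urine sink. Splenic venous blood drains through
the liver, so the liver receives $(Q_{li}-Q_{sp})$ arterial plus
$Q_{sp}$ splenic inflow; the lung receives the entire venous return.

The state vector holds drug *amounts* (micrograms) in 20 compartments
(including the fecal, hepatic and urinary cumulative sinks), never
concentrations, so conservation of mass is directly assertable: the sum
of all states equals the cumulative administered dose, and the package
verifies this at every output time (tolerance $10^{-6}$ relative).
Because every transfer is linear in the amounts, the entire right-hand
side is a constant matrix $M$ with zero column sums; $M$ doubles as the
analytic Jacobian handed to the stiff integrator, and mass is conserved
by construction even when a sensitivity perturbation deliberately
unbalances the circulatory flows.

Two typographical repairs to the tabulated equations are applied and
commented in the code: the liver accumulation volume is $V_{li}$, and
the spleen/kidney/heart rows read $Q\,(C_{ab} - C/P)$; the brain row
mirrors the muscle row with brain symbols.

### Absorption form

The literal tabulated GI equations carry the bioavailability factor $F$
inside both the intestinal loss and the hepatic uptake terms, which
makes the absorbed fraction $F K_a/(K_{gut}+F K_a) \approx 0.36$ rather
than $F$ itself. The package default is the conventional `standard`
form (absorb $K_a A_{inc}$, excrete $K_{gut} A_{inc}$), which conserves
mass exactly and makes the simulated absorbed fraction equal
$K_a/(K_a+K_{gut})$; the literal form remains available as
`absorption_form = "as_printed"`.

## Parameters and defaults

Organ masses (fractions of body weight) and regional flows (fractions
of cardiac output) are taken from the goat study values; drug-specific
parameters (partition coefficients, permeability fractions, clearances,
absorption constants) are the fitted final estimates, shipped in
`inst/extdata/goat_rac.yaml`. Several physiological quantities are not
part of those tables and are package defaults, chosen once from the
small-ruminant PBPK literature and configurable:

* **Cardiac output** 5.97 L/h per kg BW — the lung-flow basis; a
  one-dimensional calibration helper
  (`calibrate_cardiac_output()`) lets users tune it against plasma
  data.
* **Brain flow** 0.02 of cardiac output, carved out of the
  remaining-tissue flow (the tabulated six fractions already sum to
  100%); **spleen flow** 0.02, carved out of the total hepatic inflow.
* **Blood volume** 0.07 of BW with an arterial fraction of 1/3; the
  remaining-tissue mass is reduced accordingly so masses still sum
  to 1.
* **Vascular (blood) fractions** of the membrane-limited tissues:
  muscle 0.04, fat 0.02, brain 0.04, rest 0.04 — standard PBPK
  vascular-space values.
* **Free fraction** $P_{free} = 1$ (no value was fitted for it; the
  binding parameter becomes active in the sensitivity sweep only when
  $P_{free} < 1$).
* Tissue density is fixed at 1 kg/L so ug/kg and ug/L interconvert
  trivially.

The permeability constants $Pp_i$ are interpreted as fractions of the
tissue's regional blood flow, $Pa_i = Pp_i \, Q_i$ (the common PBPK
convention); an absolute interpretation in L/h/kg is available via
`permeability_mode = "absolute"` since the original convention cannot
be confirmed.

## Simulation numerics

`simulate_pbpk()` integrates with `deSolve::lsoda` at `rtol = 1e-8`,
`atol = 1e-10` ug, passing $M$ as the analytic Jacobian. Doses are
instantaneous state jumps applied through solver events (hard restarts
at each dose time), never narrow forcing pulses. The default output
grid is 0.1 h for the first 24 h after each dose and 1 h elsewhere.
Membrane-limited tissue concentrations are reported as
$(A_{\mathrm{blood}} + A_{\mathrm{tissue}})/V_{\mathrm{tissue}}$;
"plasma" is the venous blood concentration divided by a configurable
blood:plasma ratio (default 1, since the source of the reference plasma
predictions — venous, arterial, or plasma-corrected — is not
documented). Halving the solver tolerances moves simulated
concentrations by well under 0.01%, and the repeated-dose solution
coincides with the superposition of time-shifted single-dose solutions,
as the linearity of the system requires.

## Non-compartmental analysis

The NCA follows the conventions of standard PK software, since the
original analysis settings are not documented: the terminal rate
constant $\lambda_z$ is chosen by the best-fit rule (maximum adjusted
$R^2$ over all terminal log-linear windows of at least three points
starting strictly after the observed maximum, ties to the longer
window); AUC/AUMC use the linear-up/log-down trapezoid (exact for
mono-exponential decline; all-linear available) with
$C_{last}/\lambda_z$ tail extrapolation; intravenous profiles are
anchored at a $C_0$ obtained by log-linear back-extrapolation of the
first two samples. Concentrations below the LOQ (0.5 ug/L) are
excluded from the $\lambda_z$ fit and treated as missing, not zero, in
the trapezoids. Per-animal NCA with arithmetic mean and SD rows mirrors
the convention of reporting means of individual-animal parameters
(which is why dose/mean-AUC need not equal the mean clearance).

## Parameter estimation

No objective function or optimizer settings are documented for the
original fit, so `fit_params()` uses bounded Levenberg-Marquardt least
squares (`minpack.lm::nls.lm`) on log-scale residuals
$\log(pred+\varepsilon) - \log(obs+\varepsilon)$ with
$\varepsilon = \mathrm{LOQ}/2$, pooled over matrices — appropriate for
residue data spanning three decades. A weighted untransformed variant
is available. Per-parameter standard deviations come from the Jacobian
at the optimum (linearization) and are approximate. Joint fitting of
all 18 drug parameters from sparse residue data is ill-conditioned;
the recommended (and tested) workflow fits an identifiable subset —
absorption and clearance from plasma, partitions from their own
tissues — from explicit starting values, optionally in stages.

## Sensitivity analysis

`sensitivity_coefficient()` implements the forward finite difference
$SC = (f(x+\Delta x)-f(x))/\Delta x$ with $\Delta x = 0.01\,x$ by
default (central variant available, and the two agree to first order on
the smooth functionals used here), and $NSC = SC \cdot x / f(x)$;
$|NSC| \ge 0.25$ flags a sensitive parameter. Because sensitivity of a
residue model is judged during the *post-exposure* period, the default
output functional is the tissue (or plasma) concentration at a fixed
time after the last dose — 168 h, the middle of the depletion window —
rather than an exposure-window AUC; both alternatives (window AUC,
Cmax) are selectable and the choice is recorded in the output. Flow
perturbations act on the resolved absolute flows, so a single regional
flow can be varied without renormalizing the circulation; drug mass
remains conserved by construction.

At the default parameterization the strongest elasticities for plasma,
liver and kidney are hepatic clearance (negative), the muscle partition
and muscle flow/permeability (the dominant depletion reservoir), the
remaining-tissue permeability (positive: it controls the slow terminal
reservoir), and the absorption constants. Cardiac output is negative
but does not dominate: with clearance fixed in L/h/kg, raising total
flow mainly accelerates inter-compartment equilibration. The hepatic
flow elasticity is slightly *positive* (a faster liver flow lowers the
hepatic extraction ratio), and body mass has elasticity near $-1$ when
dose amounts are held fixed in micrograms (exactly 0 when doses are
re-resolved per kg, since every volume, flow and clearance scales
linearly with body mass). A parameterization in which cardiac output
dominates all outputs with large negative elasticity, all regional
flows are negative and body mass is strongly positive would require
allometric (sub-linear) flow scaling or absolute-valued organ sizes,
neither of which this model uses.

## Monte Carlo withdrawal times

`withdrawal_report()` simulates the residue-depletion scenario (28
daily oral gavages of 1.0 mg/kg BW) for a population of virtual
animals: the sensitive drug parameters (hepatic clearance, the three
absorption constants, the liver/kidney/muscle/rest partitions, the
muscle and rest permeabilities) are drawn independently per individual
from mean-preserving lognormal distributions, CV 0.20, truncated at
three log-scale SDs — the variability settings are package defaults
(the original Monte Carlo distributions are not documented) and are
fully configurable. Per individual and tissue, the withdrawal time
(WT) is the time after the last dose at which the concentration falls
below the tissue MRL (CAC limits: muscle 10, fat 10, liver 40, kidney
90 ug/kg) *and stays below it*, located at the final down-crossing
with log-linear refinement between grid points.

The population summary is the distribution-free one-sided 95/95 upper
tolerance bound: the $k$-th order statistic of the per-individual WTs,
where $k$ is the smallest integer with
$P(\mathrm{Binomial}(n, 0.95) \le k-1) \ge 0.95$ ($k = 484$ at
$n = 500$; $n \ge 59$ is required for any such bound). Days are
reported as the ceiling of hours/24. WT is monotone in MRL, dose and
exposure length, and the bound never falls below the median.

At the shipped defaults (seed 1, $n = 500$) the 95/95 withdrawal times
are muscle 8 d, fat 6 d, liver 5 d, kidney 3 d. The ordering is a
structural consequence of the fitted partition coefficients: for
tissues that track a monotonically decaying plasma curve, WTs order by
the plasma thresholds $\mathrm{MRL}_i/P_i$ (kidney 50.8, liver 15.6,
fat 13.3, muscle 9.4 ug/L), so the kidney — whose partition
coefficient is below the liver's and which has no other accumulation
mechanism in this model class — is always the *first* edible tissue to
clear. Residue surveys for beta-agonists typically find the kidney
residue-dominant; reproducing a kidney-longest withdrawal profile
would require a larger effective kidney partition or an explicit renal
accumulation process, which the present parameter set does not
contain. This is a known, documented limitation of the model as
parameterized.

## The synthetic-data generator

`generate_observed()` and `generate_validation_set()` produce observed
datasets with the statistical structure of the in-vivo study: the
noise-free mean is the simulator output itself (one shared code path,
no duplicated model), multiplied per animal and sample by
median-preserving lognormal noise with CV 0.15 (the scale of typical
residue-assay relative SDs), with values below the LOQ (0.5 ug/kg or
ug/L) flagged `"<LOQ"` rather than substituted and values below the
LOD (0.15) dropped. The sampling schedules are the study's (plasma at
5 min-96 h; tissues at withdrawal days 1-21 after a 28-day exposure).
The generator emulates assay noise and censoring only — not
between-animal kinetic variability, receptor-mediated tissue binding,
or matrix-specific recovery bias — so tests passing on fixtures
demonstrate internal consistency of the pipeline, not field accuracy
for real goats.

## Problem sizes and runtimes

The test-suite and acceptance runs use: 500-individual Monte Carlo
populations over a 28-day exposure plus 45-day washout (about a minute
of CPU); sensitivity sweeps of ~28 parameters x 3 outputs (seconds);
parameter-recovery fits of 4 free parameters against three synthetic
matrices (about a minute each); dense-grid NCA profiles of ~1000
points. Reduced solver tolerances (`rtol 1e-6`) are used inside
iterative fitting loops; reported results always use the default
tolerances.

## Known limitations

* Flow-limited kidney and liver cannot yield kidney-dominant residue
  depletion at the fitted partition coefficients (see above).
* Enterohepatic recirculation, metabolite kinetics, saturable
  clearance and receptor binding are out of scope; elimination is
  strictly linear.
* The blood:plasma ratio is 1 by default; hematocrit is carried but
  only becomes active if that ratio is configured from it.
* Reported fit standard deviations are linearization-based
  approximations; near-zero published SDs for the original fit are not
  reproducible without the original objective and weighting.
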