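---
title: "The power-equation model of CNS oxygen toxicity at rest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The power-equation model of CNS oxygen toxicity at rest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnsot)
```

## The model and its assumptions

Breathing oxygen above roughly 2 bar puts the central nervous system at risk
of toxicity (CNS-OT): nausea, twitching, sensory disturbance, convulsions,
unconsciousness. The model implemented here treats toxicity as the crossing
of an accumulated dose threshold. A continuous exposure of $t$ minutes at
oxygen partial pressure $P_{O_2}$ bar accumulates the **CNS-OT index**

$$K = t^2 \, P_{O_2}^{\,c},$$

and the dose at which symptoms appear is lognormal across exposures:
$\tfrac{1}{2}\ln K$ at onset is Normal$(\mu, \sigma)$, so the risk
accumulated by index $K$ is

$$P = \Phi\!\left(\frac{\tfrac{1}{2}\ln K - \mu}{\sigma}\right).$$

Substituting $K$ shows the equivalent survival formulation: the symptom
onset time $T$ at fixed pressure is lognormal with location
$\mu - (c/2)\ln P_{O_2}$ and scale $\sigma$ — a lognormal accelerated
failure time (AFT) model in $\ln P_{O_2}$. The package keeps these two
faces of the model identical by construction: `cns_ot_risk()` evaluated at
`cns_ot_index(t, po2, c)` equals the AFT event-time CDF exactly, and
`fit_mle()` estimates $(c, \mu, \sigma)$ from right-censored records of
exactly this model.

Key assumptions worth keeping in view:

* **Power-law dose accumulation** in time squared, with all pressure
  dependence in the exponent $c$.
* **Homogeneous susceptibility scale**: one $\sigma$ per condition. The
  heterogeneous source experiments behind the published fits showed varying
  scales; the published solution averaged them, and the fitter here
  estimates a single pooled $\sigma$ per condition by maximum likelihood,
  which is the standard AFT treatment of the same idea.
* **Exchangeability across eras and protocols** of the compiled historical
  exposures.
* **Rest means 1 MET**, either dry or immersed in thermoneutral
  (~33&nbsp;°C) water; immersion and workload are separate effects, which
  is why the registry carries separate immersed/dry sets and a distinct
  4.4-MET active-diving set.

## Parameters and registry

| set | condition | c | $\mu$ | $\sigma$ | $K_c$ |
|---|---|---|---|---|---|
| `IMMERSED_REST` | immersed, 1 MET | 10.93 | 8.99 | 0.81 | $6.42\times10^7$ |
| `DRY_REST` | dry, 1 MET | 12.99 | 11.34 | 0.65 | $7.10\times10^9$ |
| `ACTIVE_4_4` | active, 4.4 MET | 6.8 | 9.63 | 2.02 | $e^{18.02}$ |

$c$ is dimensionless; $\mu$ and $\sigma$ are on the scale of
$\tfrac{1}{2}\ln K$ (log minutes-squared-bar); $K_c = e^{2\mu}$ is the
50%-risk index in $\mathrm{min}^2\,\mathrm{bar}^c$. For the two at-rest
sets the printed $K_c$ and $e^{2\mu}$ agree within rounding
($|\ln K_c - 2\mu| < 0.02$), and the package asserts that invariant. The
published active-diving set is internally inconsistent in this respect
($e^{2\cdot 9.63} \neq e^{18.02}$); both constants are stored exactly as
published and the invariant is deliberately not asserted for it.

A notational point: the published risk transforms write the numerator
variously as $\ln(K^{0.5})$ and $\ln(K)^{0.5}$. Only the reading
$\tfrac{1}{2}\ln K$ makes $K_c = e^{2\mu}$ match the printed critical
indices, so that reading is used everywhere.

All pressures are bar throughout; `convert_po2()` exists for ATA/kPa/mmHg
input but is never applied implicitly.

## Air breaks, recovery, and profile accumulation

During an air break the index decays exponentially,

$$K_{rec} = K\, e^{-0.079\, t_{rec}}$$

with $t_{rec}$ in minutes (`decay_index()`; half-life
$\ln 2 / 0.079 \approx 8.8$ min). When oxygen breathing resumes — possibly
at a different pressure — accumulation restarts from the **equivalent
time** $t_{eq} = \sqrt{K / P_{O_2}^{\,c}}$, the continuous oxygen time at
the new pressure that would have produced the current index
(`equivalent_time()`). An oxygen segment of $d$ minutes then advances

$$K \leftarrow (t_{eq} + d)^2 \, P_{O_2}^{\,c}.$$

`accumulate_profile()` walks an ordered list of segments this way from
$K = 0$, recording index and risk at every boundary. Design choices made
where the mechanism was open:

* **Air breaks are pure recovery.** The low inspired $P_{O_2}$ of an air
  segment (≈0.6 bar at 2.8 bar ambient) accrues nothing; it only decays the
  index. This treatment reproduces both worked clinical predictions below.
* **Pressure changes without a break** are handled by the same
  equivalent-time carry-over.
* **Auto-classification**: a segment without an explicit kind is air when
  its $P_{O_2}$ is below 1.0 bar, else oxygen. Toxic accrual in the data
  envelope starts well above 2 bar, so 1.0 bar is conservative; the
  threshold is an explicit argument.
* **The one-hour 2.5-bar treatment with a 10-min air break** is encoded as
  two 30-min oxygen segments around the break (the break does not count
  toward the treatment hour). Encoded that way, the model predicts a 1.17%
  incidence against the published 1.16% (the residual is parameter
  rounding); the first three oxygen periods of U.S. Navy Treatment Table 6
  give 12.66% against the published 12.7%. Both profiles ship in
  `inst/extdata/profiles/` and both predictions are asserted in the test
  suite.

```{r}
pr <- read_profile(system.file("extdata/profiles", "usn_tt6_first3.yaml",
                               package = "cnsot"))
attr(accumulate_profile(pr), "final_risk")
```

Degenerate inputs: $K = 0$ maps to risk 0 (the continuous limit rather
than an error), zero-duration segments are identities, and empty profiles
are rejected at construction.

## Metabolic-rate interpolation

Between the two fitted workloads the exponent falls linearly,
$c = 12.14 - 1.21\,\mathrm{MET}$, with the critical index held at
$K_c = 6.57\times10^7$ (the geometric mean of the 1 and 4.4 MET values,
whose logs are 17.98 and 18.02). Nothing is known about how $\sigma$
varies with workload, so `interpolate_met()` returns a reduced object
without $\sigma$, and every risk-computing function refuses it explicitly
rather than silently assuming a scale. Evaluating the printed formula at
its own 4.4-MET endpoint gives 6.816 where the published endpoint rounds
to 6.80; the formula is treated as authoritative for the operation.
Requests outside [1, 4.4] MET require an explicit `extrapolate = TRUE` and
carry a warning attribute.

## Maximum-likelihood fitting

`neg_log_likelihood()` scores right-censored records: events contribute the
lognormal density at their onset time, censored exposures the lognormal
survival at their end time. Records are taken at face value — an event's
time is its symptom-onset time, a non-event is right-censored at exposure
end; the historical sources mix reporting conventions, and this is the
standard AFT reading of them.

`fit_mle()` minimises the negative log-likelihood over
$(c, \mu, \ln\sigma)$ — the log transform keeps $\sigma$ positive — with
BFGS and the analytic gradient, from five deterministic starts
($c_0 \in \{2, 6, 10, 14, 18\}$, with $\mu_0$ matched to the event times at
each $c_0$) to guard against local minima; relative objective tolerance
$10^{-12}$, and a gradient-norm check decides the convergence flag.
Standard errors come from the inverse observed information at the optimum,
delta-transformed back to the $\sigma$ scale; $K_c$ and its lognormal CI
are $e^{2\mu \pm 1.96 \cdot 2\,SE_\mu}$. A dataset with a single pressure
level or no events is rejected as unidentifiable rather than fitted.

Equality of immersed and dry conditions is tested two ways, as in the
original analysis: a joint Wald statistic on the 3-vector of parameter
differences with summed covariances, and a likelihood-ratio statistic
$2(\ell_{sep} - \ell_{pooled})$, both $\chi^2_3$. The published
individual-level records are not available, so the published estimates are
not re-derived from data; they are registry constants, and the fitter is
validated by parameter recovery from data simulated at those constants,
plus an independent cross-check against `survival::survreg` on the same
records.

## Synthetic data and the embedded compilation

`simulate_records()` draws onset times from the exact model
(lognormal at location $\mu - (c/2)\ln P_{O_2}$), censoring at each
level's maximum exposure time; it is deterministic given its seed and
restores the caller's RNG state. The default envelopes used throughout the
tests mirror the historical study conditions: pressures within
2.26–3.67 bar and censoring at 120 min, the at-rest time scale.

`rest_exposure_groups()` embeds the compiled group summaries behind the
published fits — three immersed groups (219 exposures, 105 with symptoms)
and seven dry groups (507 exposures, 136 with symptoms) plus one dry group
of 14 symptom-free 120-min exposures at 2.54 bar that the original
analysis excluded after a goodness-of-fit assessment. That group is
carried with `excluded = TRUE` and dropped by default — a documented
filter, not a hidden one; no automated outlier exclusion is implemented.
(The stated immersed pressure range 2.26–3.24 bar and the 4.08/3.44-bar
immersed groups in the compilation do not quite agree; the rows are stored
as published and the discrepancy left alone.)

`expand_groups()` reconstructs individual records from the group moments
via a lognormal moment match — lognormal rather than normal because times
are positive and the model itself is lognormal. The result is flagged
`reconstructed` and is demonstration data only: the real individual times
are unpublished, and moment-matched draws carry none of their structure.

## What the simulations do and do not show

Because the generator draws from the model itself, passing recovery and
calibration checks demonstrates that the estimator and tests are correct
*under the model* — they say nothing about model adequacy for real
exposures, where susceptibility varies between subjects and within a
subject over days, protocols differ systematically, and symptom reporting
is noisy. Checked properties, at the problem sizes the package's own test
suite uses:

* recovery of $c$ within ±0.15 from 20,000 simulated immersed-at-rest
  records over pressures {2.3, 2.6, 2.9, 3.2} bar;
* 95% CI coverage of all three parameters within 93–97% over 200
  replicates of 2,000 records;
* Wald/LR null rejection near the nominal 5% over 100 replicate pairs of
  900 records, and $p < 0.001$ for both tests when the two conditions are
  simulated at their respective published truths with the historical
  sample sizes;
* profile accumulation within 0.1% of a 0.001-min-step brute-force
  integrator ($dK/dt = 2\sqrt{K}\,P_{O_2}^{c/2}$ on oxygen,
  $-0.079K$ on air) on 50 random profiles.

## Known limitations

* No pulmonary oxygen toxicity (UPTD/OTU), no water-temperature or
  thermal-stress corrections, no within-subject susceptibility modelling.
* The recovery-resumption mechanism (equivalent time) is the reconstruction
  that reproduces the two published clinical predictions; alternative
  carry-over schemes are not distinguishable from the published numbers
  alone.
* Interpolated-MET parameter sets cannot produce risks, by design.
* Only the lognormal AFT family is implemented; no Weibull/log-logistic
  alternatives, frailty terms, or Bayesian estimation.
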