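# cnsot

Risk prediction for **central nervous system oxygen toxicity (CNS-OT)** in
people breathing hyperbaric oxygen **at rest** — patients in a hyperbaric
chamber, or divers resting immersed in thermoneutral water. CNS-OT symptoms
(nausea, twitching, visual and hearing disturbance, convulsions, loss of
consciousness) constrain every hyperbaric oxygen treatment table and
saturation-diving schedule; this package computes the symptom risk of a
planned exposure and fits the underlying model to new data.

## The model

A continuous exposure of `t` minutes at oxygen partial pressure `PO2` (bar)
accumulates the power-law dose index

    K = t^2 * PO2^c

and the probability of CNS-OT by the time the index reaches K is

    P = Phi( (0.5*ln K - mu) / sigma )

i.e. half the log index at symptom onset is Normal(mu, sigma). This is a
lognormal accelerated-failure-time model: `ln T ~ Normal(mu - (c/2) ln PO2,
sigma)`. The critical index `Kc = exp(2*mu)` is the dose at 50% risk.

Fitted at-rest parameter sets ship in a registry:

| set | condition | c | mu | sigma | Kc |
|---|---|---|---|---|---|
| `IMMERSED_REST` | immersed, 1 MET | 10.93 | 8.99 | 0.81 | 6.42e7 |
| `DRY_REST` | dry chamber, 1 MET | 12.99 | 11.34 | 0.65 | 7.10e9 |
| `ACTIVE_4_4` | active diving, 4.4 MET | 6.8 | 9.63 | 2.02 | exp(18.02) |

During an air break the index recovers exponentially,
`K <- K * exp(-0.079 * t_rec)`, and oxygen accumulation resumes via the
*equivalent time* `t_eq = sqrt(K / PO2^c)` at the new pressure. For
submerged exposures at intermediate workloads the exponent interpolates
linearly, `c = 12.14 - 1.21 * MET` with `Kc = 6.57e7`; no sigma is known
between the endpoints, so interpolated sets are deliberately not
risk-capable.

## Worked example

Score the first three oxygen periods of U.S. Navy Treatment Table 6
(20 min of oxygen at 2.8 bar, three times, with 5-min air breaks):

```r
library(cnsot)
pr <- exposure_profile(list(
  segment(2.8, 20), segment(0.6, 5),
  segment(2.8, 20), segment(0.6, 5),
  segment(2.8, 20)), "DRY_REST")
accumulate_profile(pr)
#> CNS-OT risk trajectory
#>  time_min          K        risk
#>         0          0 0.000000000
#>        20  257420316 0.005400671
#>        25  173418928 0.002166064
#>        45  853410210 0.051856370
#>        50  574925424 0.026743947
#>        70 1601754562 0.126561693
#> final K = 1.601755e+09   final risk = 0.1266 (12.7%)
```

The index climbs during each oxygen period, each air break claws some of it
back, and the schedule ends at a predicted 12.7% incidence. A single
continuous exposure is one call:

```r
p <- cns_params("DRY_REST")
cns_ot_risk(cns_ot_index(60, 2.5, p$c), p)   # 0.0232 — 60 min at 2.5 bar
time_for_risk(0.01, 2.8, p)                  # 23.1 min to reach 1% risk
```

The same operations are scriptable from a shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cnsot", package = "cnsot"))')
Rscript $CLI risk 60 2.5 DRY_REST
Rscript $CLI profile inst/extdata/profiles/usn_tt6_first3.yaml
Rscript $CLI simulate --condition IMMERSED_REST --n 500 --seed 7 --out rec.csv
Rscript $CLI fit rec.csv
```

Fitting new data uses `fit_mle()` on right-censored exposure records
(`po2`, `time`, `event`), with Wald and likelihood-ratio tests
(`wald_test()`, `lr_test()`) for immersed-vs-dry parameter equality, and
`simulate_records()` / `rest_exposure_groups()` supplying synthetic records
and the embedded historical group summaries.

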