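# threathazard

Why does *not knowing when* a threat will arrive feel worse than knowing?
One statistical answer: as seconds pass without the event, the
conditional probability that it happens *now* — the **hazard rate** —
climbs, even when the marginal per-second probability of the event is
flat. `threathazard` turns that idea into a tested analysis pipeline for
threat-anticipation experiments: it models discrete threat schedules and
their hazard dynamics, constructs condition pairs whose threat
probability is matched while their hazard is dissociated, simulates a
cohort of learning-and-avoiding agents on that design, and runs the
avoidance and fear/anxiety analysis battery such data call for.

It is aimed at researchers in computational psychiatry and affective
science who want to reason about, or simulate, the temporal statistics
of aversive anticipation before (or instead of) collecting shocks.

## The model

A trial is a discrete grid of whole seconds `t = 0, 1, ..., T-1`. A
**threat schedule** is a probability mass function `p(t)` giving the
chance the shock lands during second `t`; every learning trial ends in
shock, so `Σ p(t) = 1`. From the pmf the package derives

- survival `S(t) = 1 − Σ_{s<t} p(s)` — the chance of reaching second
  `t` unscathed,
- hazard `h(t) = p(t) / S(t)` — the conditional shock probability at
  `t` given survival so far,
- cumulative hazard `H = Σ_t h(t)`.

For a countdown certain to end in shock at its final step, `h` is
`0, 0, 0, 1` and `H = 1`. For an equal-probability four-step schedule
(`p = .25` everywhere), `h` is `.25, .33, .5, 1` (two-decimal display)
and `H = .25 + .33 + .5 + 1 = 2.08`: temporal uncertainty leaves total
probability untouched but inflates cumulative hazard. The experimental
design exploits the same algebra: two 30-s schedules share an identical
pmf over the middle 20 s, but the "early" condition has spent its
remaining mass before that window, so its in-window hazard is strictly
higher at every matched second.

## Worked example

```r
library(threathazard)

sched <- make_uniform_uncertain(4)
hazard_rate(sched)
#> <hazard_profile>
#>  t survival hazard cum_hazard
#>  0     1.00 0.2500     0.2500
#>  1     0.75 0.3333     0.5833
#>  2     0.50 0.5000     1.0833
#>  3     0.25 1.0000     2.0833

pair <- design_matched_pair()      # 30-s trials, matched window 6-25 s
verify_pair(pair)
#> <design_report>
#>   matched pmf in window : TRUE
#>   early hazard dominance: TRUE
#>   early cum. hazard >   : TRUE
#>   E[shock time] early 9.49 s, late 18.99 s
#>   window hazard gap: min 0.0300, max 0.9550

res <- run_all(default_config(seed = 11))
res$report
#> <avoidance_report>
#>   log-rank: chi2 = 293.59, p = 8.23e-66
#>   epoch  6-10s: escape 0.238 vs 0.095, t = 3.84, p = 0.00024
#>   epoch 11-15s: escape 0.231 vs 0.130, t = 1.89, p = 0.0629
#>   epoch 16-20s: escape 0.378 vs 0.140, t = 4.34, p = 4.5e-05
#>   epoch 21-25s: escape 0.603 vs 0.176, t = 4.87, p = 1.05e-05
#>   earnings: early 6.9 vs late 15.7 cents (56.0% less), t = -27.45, p = 5.18e-28
#>   rating ~ hazard: mean slope 5.94, t = 8.23, p = 3.19e-10
#>   forced choice: 13/21 early, p = 0.383
#>   final trial: U = 228.5, p = 0.84 (residualised p = 0.89)
```

Reading the report: the simulated hazard-tracking cohort escapes the
early-threat condition far more (log-rank on escape times with shocks as
censoring), escapes more in every probability-matched epoch
(escape-given-entry proportions, early vs late), forfeits earnings in
the early condition, and its fear/anxiety ratings rise with the hazard
rate at the rated second. Subset-level outcomes (the 21-participant
forced choice and final-trial rank-sum) are noisier and vary by seed, as
they do in small subsamples generally. `run_all(config, out_dir)` also
writes `pair.json`, `trials.csv`, `forced_choice.csv`, `report.json`,
survival curves and a `run.log`; the same stages are scriptable via
`inst/cli/threathazard.R` (`design | simulate | analyze | run-all`).

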