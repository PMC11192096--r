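---
title: "Hazard dynamics of uncertain threat anticipation: models, simulator, analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard dynamics of uncertain threat anticipation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threathazard)
```

## The statistical object

`threathazard` works at one-second resolution on 0-based trial time;
timepoint `t` means "during second `t`". A threat schedule is a proper
pmf `p(t)` of shock time over the trial grid — proper because in the
learning phase every trial ends in shock. Three derived quantities carry
the package's science:

* survival `S(t) = 1 − Σ_{s<t} p(s)`,
* hazard `h(t) = p(t)/S(t)`, the conditional shock probability given
  survival to `t`,
* cumulative hazard `H = Σ h(t)`.

The identities `p(t) = S(t)·h(t)` (checked exactly in the tests), `h = 1`
at the last support point of any proper pmf, and `H = 1` iff the pmf is
a point mass give the algebraic skeleton. `H` exceeds 1 for *any*
temporally uncertain schedule, which is why paradigms that compare
certain with uncertain countdowns — or predictable with unpredictable
blocks (`make_npu_schedules()`) — confound "uncertainty" with hazard
dynamics. Numerical conventions: pmf normalisation is checked to 1e-9
absolute; the hazard profile truncates at the last support point rather
than emitting 0/0 beyond it; the ratio is clamped at 1 against roundoff;
full precision is kept everywhere, with `round_hazard()` supplying the
two-decimal display convention under which the uniform-4 example prints
`.25 + .33 + .5 + 1 = 2.08` (full precision 2.0833...).

## The matched, dissociated design

`design_matched_pair()` builds the pair of 30-s conditions at the heart
of the paradigm: identical pmf over a matched window (default seconds
6–25, the middle 20 s), with the remaining mass placed entirely
*before* the window (early condition) or *after* it (late condition).
Matching the window pmf while moving the off-window mass dissociates
probability from hazard by pure algebra: inside the window both
conditions have the same `p(t)`, but the early condition's survival is
smaller by exactly the off-window mass, so its hazard is strictly larger
at every matched second. This holds for every valid parameterization
(the test suite sweeps 1,000 random designs), not just the default.

The exact shapes are parameterized because only the constraints, not the
pmfs, are pinned down: off-window mass is uniform over its region, and
the shared window pmf is exponentially tilted,
`p(t) ∝ exp(−window_decay·(t − start))`. Defaults `window_mass = 0.62`,
`window_decay = 0.053` were solved (once, analytically) so the expected
shock times are 9.49 s (early) and 18.99 s (late), the ballpark reported
for such designs; they are configuration values, not claims. Cumulative
hazard is also higher for the early condition at the default and nearby
designs, and `verify_pair()` reports it as a separate check
(`cumulative_ok`) because it is *not* a theorem of the family: a design
with a very long post-window region concentrates many high-hazard
seconds in the late condition and can reverse the cumulative ordering
even while per-second window dominance holds.

## The synthetic cohort

The generator emulates the study conditions: N = 42 participants, two
conditions learned from 50 unavoidable shocks each (interleaved in
pseudo-random order), a testing phase earning 1¢ per survived second
until escape or shock, periodic 0–10 fear/anxiety ratings, one final
inescapable trial per condition for a 21-participant subset, and a
forced-choice question for a 21-participant subset.

**Learning.** An agent's estimate of a condition is the empirical
shock-time histogram plus a pseudo-count (`smoothing`, default 0.5 per
second) normalised to a proper pmf — the minimal learner consistent with
"participants learned the statistics". Ratings prompted during learning
use the post-learning estimate, a simplification that ignores
within-phase learning dynamics.

**Policy.** At each second the agent escapes with probability
`plogis(α + β·signal(t))`, where the signal is the *learned* hazard
(hazard tracker) or learned pmf (probability tracker) — never the true
schedule. The tracker dichotomy operationalises the competing
hypotheses; the logistic rule is the minimal monotone stochastic choice
rule, and β is the recoverable parameter. Within a second the escape
decision is evaluated *before* the shock lands, so a certain-`T`
schedule leaves `T` escape opportunities and a constant-policy agent
escapes with probability `1 − (1 − plogis(α))^T`, the closed form the
tests check. Testing trials end at the first event; a proper true
schedule guarantees one, and the defensive fallback (shock at the final
second) is unreachable for proper schedules.

**Ratings and choice.** Ratings are `clip(gain·signal + ε, 0, 10)` with
Gaussian ε, prompted at a recorded second drawn uniformly from the
elapsed trial and stored in `rating_time_s`. The forced choice is the
condition with the higher mean of the agent's own experienced ratings
(ties random), so it degrades gracefully to chance when `gain = 0`.

**Population defaults.** Intercept −5.5 (SD 0.75) log-odds, slope 25
(SD 3) per unit signal, gain 10 (SD 2), noise SD 1, chosen once so the
simulated cohort is strongly avoidant — the regime the paradigm's
reported effect sizes (epoch t-statistics near 8, a log-rank statistic
in the hundreds) imply for real participants. A steep slope is needed
because a 50-draw histogram over 30 bins is jagged: per-second hazard
estimates carry sampling noise of similar magnitude to the early/late
hazard gap at the window's start, and a shallower policy lets that noise
swamp the signal. With 1-s bins and 50 shocks this learner is noisier
than humans, who generalise across neighbouring seconds; the package
keeps the histogram learner for transparency and compensates with
policy steepness rather than adding a smoothing kernel.

**Determinism.** One integer seed fixes the entire dataset; the
acceptance tests check byte-identical CSV output across repeated runs.

**What passing tests do not show.** The generator has no habituation,
no drift in escape policy, no shock-intensity effects, no
order/counterbalancing structure beyond shuffling, and an invented
rating instrument; agreement between analyses and this generator
validates the pipeline's logic, not any claim about real participants.

## The analysis battery

* `kaplan_meier()` / `log_rank()` — escape is the event, a delivered
  shock right-censors the escape time at its second. Both are written
  in-package (the estimator is part of the contribution's logic) and are
  cross-checked against `survival::survfit()`/`survdiff()` in the tests.
* `epoch_avoidance()` — per participant, condition and epoch: the
  fraction of trials *entering* the epoch that end in escape inside it;
  conditions compared per epoch with an independent-samples Student t,
  the paradigm's stated test. Because both condition samples share
  participants, heterogeneity across participants makes this t
  conservative (it over-estimates the variance of the difference); the
  calibration study therefore uses homogeneous null cohorts, and real
  heterogeneous nulls can only push rejection *below* nominal.
* `earnings_comparison()` — per-participant mean testing earnings,
  paired t, and the percentage shortfall `100·(late − early)/late`.
* `rating_association()` — a two-stage summary-statistics model: stage
  1 regresses each participant's ratings on the true schedule's hazard
  (or pmf) at the recorded rating second, optionally adjusting for
  cumulative shocks received; stage 2 tests the per-participant slopes
  against zero. This replaces mixed-model machinery deliberately: it is
  fully specified, library-free, and asymptotically comparable for
  balanced designs. Participants with fewer than 3 usable rated
  observations are dropped with a warning.
* `forced_choice_test()` — exact binomial against 0.5, two-sided by the
  doubled-smaller-tail convention `min(1, 2·min(tails))`.
* `final_trial_comparison()` and `rank_sum_test()` — Wilcoxon rank-sum
  with midranks; exact permutation p by complete enumeration when the
  combined n is at most 12, tie-corrected normal approximation
  otherwise; repeated on ratings residualised (pooled OLS) for
  cumulative shock count.

## Calibration and the dissociation

Two simulation studies anchor the battery (both in the acceptance
tests, at sizes chosen to keep the default run fast while leaving
negligible Monte-Carlo error):

**Type-I calibration** uses 1,000 exchangeable null cohorts: identical
schedules (`window_mass = 1`), tracker-blind homogeneous agents (β = 0,
gain = 0, intercept SD 0, baseline escape ≈ .08/s), 20 participants ×
20 learning / 10 testing trials. Every test's rejection rate at α = .05
must sit in the 99% binomial band around .05. Homogeneity matters for
the reason above; the whole-cohort choice subset of 20 keeps the
discrete binomial test's exact size (.0414) inside the band.

**Dissociation** uses 100 study-scale hazard-tracker cohorts: at least
95 must jointly show a significant log-rank (p < .005), greater early
escape in all four matched epochs, lower early earnings, a positive and
significant rating–hazard slope, and an early-majority forced choice.
Probability-tracker cohorts must show no beyond-chance *early-higher*
escape differences in the matched window — inside the window their
tracked signal is identical across conditions. Two subtleties are worth
naming. First, probability trackers do show a small systematic
early-*lower* escape proportion within epochs: the early condition's
higher true hazard censors more of each epoch before an escape can
happen. That competing-risk artifact runs opposite to the dissociation
signature and is why the check is one-directional. Second, outside the
window the conditions differ in pmf by design, so probability trackers
legitimately avoid the early condition in seconds 0–5 and the
*whole-trial* log-rank does not separate the trackers; only the
matched-window epoch analysis does, which is precisely the design's
point.

## Known limitations

The per-second histogram learner ignores temporal generalisation; the
rating instrument and the testing-phase trial count are invented
(defaults: 0–10 scale, 25 trials per condition) because the originals
are not derivable from published material; learning-phase ratings use
the end-of-phase estimate; and the printed statistics of any real cohort
(specific χ², t, U values) are properties of those participants — the
package reproduces the qualitative pattern, and its acceptance targets
are confined to the exact worked-example hazard quantities.
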