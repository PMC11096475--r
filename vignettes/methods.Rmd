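---
title: "Methods: appraisal-stratified pooling and the synthetic bias model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: appraisal-stratified pooling and the synthetic bias model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqsmeta)
```

## The problem

Systematic reviews of clinical trials qualify their conclusions by trial
quality. Two appraisal instruments take very different routes to that
qualification. Cochrane's RoB 2 tool yields an overall per-trial rating
(low risk / some concerns / high risk) and review conclusions rest on the
low-risk stratum. The Composite Quality Score, version 2B (CQS-2B), rates
four binary criteria — randomization reported (I), allocation concealment
by an independent agent (II), double blinding (III), and at least 100
subjects per arm (IV) — multiplies the scores into an overall 0/1
appraisal, and summarizes partial compliance as a *corroboration level*:
the number of consecutive satisfied criteria starting at Criterion I,
frozen at the first failure. `cqsmeta` implements the full comparison
pipeline between these two appraisal routes, plus a synthetic corpus
generator so that every stage can be exercised against known truth.

## The pipeline

Given a trial table (arm summaries per trial × comparison × outcome) and
an appraisal table (four criterion scores and one RoB 2 rating per trial),
`run_pipeline()`:

1. scores appraisals (`score_cqs_table()`); C-level is the leading-ones
   count of the score quadruple, so e.g. (1,1,0,1) is C2 — a later 1 never
   repairs an earlier failure. A trial failing Criterion I sits at C0: a
   non-randomized report corroborates nothing. The four-score product is
   kept separately as `overall`;
2. excludes comparisons with fewer distinct trials than
   `min_trials_per_comparison` (default 5);
3. computes per-trial effects. The default measure is Hedges' g — the
   second stage pools across outcomes on different measurement scales, so
   a unitless standardized difference is the only dimensionally coherent
   default; raw mean differences and log odds ratios are available per
   configuration;
4. stratifies each comparison × outcome cell twice: by RoB 2 rating and by
   C-level. Each tool's strata partition the cell;
5. pools every stratum (first stage). Continuous data use
   inverse-variance DerSimonian–Laird random effects; dichotomous data may
   use Mantel–Haenszel weights with the Robins–Breslow–Greenland variance.
   The often-quoted recipe "Mantel–Haenszel statistics with a
   random-effects model" has no continuous-data analogue, so this split is
   the closest coherent reading and is fixed here by design;
6. selects, per cell, the stratum each tool licenses: RoB 2 uses the
   `low` stratum (cells without low-risk trials are skipped and logged);
   the CQS-2B uses the *highest C-level with data*, however few trials sit
   there;
7. pools the selected first-stage results per tool across all comparisons
   and outcomes (second stage), treating each first-stage estimate
   (θ, se²) as one input — a two-stage rather than joint refit reading,
   fixed by design;
8. compares the two second-stage estimates with a two-sided Wald z-test
   (`z = (θ_a − θ_b)/√(se_a² + se_b²)`), 5% significance by default;
9. maps each selected stratum to a qualitative conclusion. RoB 2 cells
   conclude "beneficial" iff the pooled CI excludes zero on the outcome's
   beneficial side (configured per outcome, since e.g. LDL-lowering and
   HDL-raising differ in sign); otherwise "no benefit". CQS-2B cells below
   C4 always yield "no conclusion", with the first failed criterion naming
   the bias mechanism: lack of randomization (I), lack of allocation
   concealment (II), lack of double blinding (III), too low sample size
   (IV). A C4 stratum would be judged by the same CI rule as RoB 2.

Strata that are not selected are still pooled and reported for
transparency, but never enter the second stage or the conclusions.

## Statistical machinery

All pooling is method-of-moments DerSimonian–Laird: with fixed-effect
weights `w_i = 1/v_i`, `Q = Σ w_i (θ_i − θ_F)²`,
`τ² = max(0, (Q − df)/C)` where `C = Σw_i − Σw_i²/Σw_i`, re-weighting by
`w*_i = 1/(v_i + τ²)`. Heterogeneity is reported as
`I² = max(0, (Q − df)/Q)·100` (printed to one decimal) and the chi-square
upper-tail p-value of Q. Conventions fixed for totality: a single-estimate
stratum passes through with `Q = 0, df = 0, τ² = 0, I² = 0, p_Q = 1`
(single-trial strata are routine — the highest C-level often holds one
trial). CIs use the normal quantile (1.96 at 95%); no Knapp–Hartung or
t-type small-sample adjustment is applied, keeping the plain Wald
machinery throughout. Hedges' g applies the small-sample correction
`J = 1 − 3/(4(n_t+n_c−2)−1)` to both the estimate and its variance. 2×2
tables with a zero cell receive a 0.5 continuity correction in all four
cells; tables with no events (or all events) in both arms are rejected as
carrying no odds-ratio information. Rows reporting standard errors instead
of SDs are converted at read time (`sd = se·√n`) and flagged.

## The synthetic corpus generator

`generate_corpus()` draws two-arm trials with known truth. Per trial:
design flags (randomized, concealed, blinded) are independent Bernoulli
draws at configured prevalences; a per-arm size is fixed or drawn
uniformly from a range; the true effect is `δ_i = δ + u_i` with
`u_i ~ N(0, τ²_gen)`. Bias is then applied to the *population* effect on
the SMD scale — this makes recovery targets well-defined, since the
distortion meta-epidemiological studies describe is of the underlying
estimated effect, not added measurement noise:

* no concealment: `δ_i ← δ_i + 0.15` (additive SMD, the published
  meta-epidemiological estimate);
* no blinding: `δ_i ← δ_i · 1.11` (11%, midpoint of the published 9–13%
  range; both endpoints configurable);
* per-arm n below 100: `δ_i ← δ_i · 1.33` (33%, as published).

The composition order (additive concealment, then multiplicative blinding,
then multiplicative small-n) is arbitrary in principle; it is fixed and
documented so results are reproducible. The published relative
overestimations are treated as relative inflation of the SMD-scale effect;
whether their source ratios were of odds ratios or SMDs is not stated
there, and this reading is the generator's documented choice.

Observed data follow the normal theory the effect measures assume: sample
means `~ N(μ, σ²/n)` and sample variances `~ σ² χ²_{n−1}/(n−1)`. CQS
scores are a deterministic function of the flags and n (criteria I–III
from the flags, IV from `n ≥ 100`); only the RoB 2 rating can deviate from
its flag-derived value, at a configurable noise rate — so appraisal noise
can be studied on the RoB 2 side without ever corrupting the CQS side. The
flag-derived RoB 2 rating is `low` when all three safeguards hold, `some
concerns` when exactly one fails, `high` otherwise.

Default corpus settings emulate the kind of review the pipeline targets:
34 trials over four comparisons of 18/5/9/4 records (sizes summing past
the trial count make the first trials serve two comparisons, as happens in
real reviews), one continuous outcome, per-arm sizes of 20–80 (so no trial
reaches C4), near-universal randomization, rare concealment, true SMD
−0.07 and `τ²_gen = 0`. What the generator does *not* emulate: correlated
design flags (a correlation knob is deliberately absent; flags are
independent unless prevalences are set to 0/1), individual-participant
structure, dropout, non-normal outcomes, or RoB 2's five internal domains.
Passing tests therefore show the pipeline's statistics are correct under
its own model, not that real trial corpora satisfy that model.

`recover_bias()` inverts the generator: it contrasts DL-pooled estimates
between trials exposed and not exposed to one mechanism — additive bias as
a difference of pooled estimates, relative bias as
`100·(pooled_exposed/pooled_unexposed − 1)` with a delta-method
Monte-Carlo SE. The contrast is unbiased when the strata differ only in
the flag under study, which the recovery studies arrange by construction.

## Problem sizes and numerical checks

The test suite runs everything at desk scale: the C-level engine is
checked exhaustively (16 quadruples) against a brute-force leading-ones
oracle; DL pooling against a loop-written oracle on 1000 random instances
at 1e−10 relative tolerance, and against `metafor`'s DL estimator;
Mantel–Haenszel against `metafor::rma.mh`. Type-I error of the Q test is
simulated under homogeneity (k = 10, 10,000 replicates). The Wald
comparison's type-I error is simulated with k = 50 studies per stratum and
true τ² = 0.05: the DL Wald test is only asymptotically nominal, and at
small k with τ² truncated at zero its size drifts conservative, so the
check is run in a regime where the weights are consistent. Bias recovery
uses 500 trials per stratum (per-arm n 150 for the concealment contrast,
50 vs 200 for the small-sample contrast), accepted within three
Monte-Carlo SEs. τ² recovery uses k = 200 studies averaged over 20
replicates, within ±20%.

## Known limitations

* The second stage treats first-stage pooled estimates across outcomes as
  exchangeable; estimates from the same trial entering several comparisons
  are pooled independently with no cross-comparison variance correction.
* DL is the only τ² estimator (no REML / Paule–Mandel), matching the
  method being modelled; heterogeneity p-values at very small k are
  low-powered by construction.
* The conclusion mapper implements only the CI-exclusion rule and the
  C-level gate — no GRADE-style certainty grading.
* Binary criterion scores only; partially reported criteria ("probably
  yes") have no representation, since the CQS-2B as applied is strictly
  0/1.
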