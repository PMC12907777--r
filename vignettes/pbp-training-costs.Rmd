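---
title: "Costing proficiency-based progression training: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing proficiency-based progression training: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpcost)
```

## The economic question

Proficiency-based progression (PBP) training requires trainees to meet an
expert-derived, metric-based benchmark. In a four-arm randomized trial of
robotic suturing training (12 trainees per arm), curricula with decreasing
PBP adherence — full PBP, e-learning, traditional lectures, conventional
apprenticeship — showed monotonically worse learning efficiency: more trials,
more hands-on hours, more laboratory days, and in the apprenticeship arm only
7 of 12 trainees reached the benchmark at all. PBP, however, carries a fixed
one-time cost of €132 377 for metric development, validation and e-learning
content, charged to the PBP-derived arms only.

`pbpcost` formalises the resulting trade-off. Each curriculum `g` has a
per-trainee **variable cost**

$$v_g = 2450\,€/\text{day} \times \text{lab days} + 200\,€/\text{night}
\times \text{hotel nights},$$

laboratory time billed in full or half days only, at most 3.5 days. The
per-trainee cost at cohort size $N$ is $v_g + F/N$ for fixed-cost-bearing
curricula and the constant $v_g$ for apprenticeship; totals are
$N v_g + F$ and $N v_g$. Cost equivalence between a fixed-cost curriculum
$a$ and a flat one $b$ solves $v_a + F/N = v_b$:

$$N^* = \frac{F}{v_b - v_a}.$$

## Calibrating the variable costs

The trial publishes per-trainee and total costs, never $v_g$ directly. The
canonical calibration (`osset_profiles("printed")`) inverts the 12-trainee
figures: $v_g$ = published per-trainee cost at 12 minus the rounded
amortized share €11 031, giving $v_1 = 14\,139 - 11\,031 = 3\,108$,
$v_2 = 174\,144/12 - 11\,031 = 3\,481$, $v_3 = 182\,604/12 - 11\,031 =
4\,186$, and $v_4 = 84\,804/12 = 7\,067$ (no fixed cost). This path
reproduces the largest number of published values exactly. The alternative
(`"records"`) averages `trainee_cost()` over a cohort of records; the two
agree only approximately because the published figures carry rounding.

Two consequences are documented rather than hidden:

* **Grid totals vs affine totals.** The published cohort totals at 12 equal
  12 × the *rounded* per-trainee figure (12 × 14 139 = 169 668), while the
  exact affine total is $12 v_1 + F = 169\,673$. The projection grid
  (`project()`) follows the publication's convention (total = size ×
  displayed per-trainee); `total_cost()` is the exact affine model used for
  break-even analysis. The two differ by at most €0.50 per trainee.
* **The break-even point.** With the calibrated values,
  $N^* = 132\,377/(7\,067-3\,108) = 33.44$ trainees (first strictly cheaper
  integer cohort: 34). The published figure of 24.98 trainees is not
  derivable from any published cost combination we could find; the package
  reports its own solver's value and deliberately does not tune toward
  24.98. Both the real-valued $N^*$ and the integer break-even are reported
  because threshold statements mix the two conventions.
* **Large-cohort totals.** Published totals at 50–500 trainees carry
  internal rounding drift (e.g. the apprenticeship total at 500 implies
  $v_4 = 7\,066.67$, the total at 12 implies exactly 7 067). One exact $v_g$
  is kept per calibration; the acceptance suite checks agreement with the
  published totals within 0.1%. The apprenticeship total printed at 100
  trainees is excluded: it lies outside its own printed confidence interval,
  while 100 × 7 067 lies inside it, so we treat it as a typesetting error.

All currency arithmetic is carried in exact integer cents; half-up rounding
to whole euros (`round_half_up()`, halves away from zero) happens only at
display. This convention matches the published amortization schedule
(132 377/12 → 11 031, /500 → 265) and all published percentages
(+14/+103/+162% hands-on time, ~23% and ~110% cost advantages).

## The training-progression model

Cost projection "under the same training conditions" needs a model of how
long training takes. Training is an absorbing Markov chain over trial
counts: each 30-minute trial reaches the benchmark with a state-independent
probability $p$, so trials-to-proficiency is geometric with first-success
parameter $p$, censored at the trial cap (default 30, the number of
30-minute slots plausible under the 3.5-day limit). The expected occupied
trials has the closed form $(1-(1-p)^{\text{cap}})/p$, verified in the test
suite against direct pmf summation, the fundamental matrix of the transition
matrix, and Monte-Carlo simulation at $10^5$ chains (within 3 standard
errors).

## The synthetic-cohort generator

No trainee-level data are deposited, so `generate_cohort()` simulates them.
For each trainee:

* proficiency is Bernoulli with the arm's target rate (1.0 for the three
  PBP-derived arms; 7/12 for apprenticeship, the trial's exact fraction);
* proficient trainees draw trials from the censored geometric and billed
  days from a calibrated distribution on the half-day grid; non-proficient
  trainees sit at the trial cap and the 3.5-day maximum (they consume the
  full laboratory allocation);
* hands-on hours are exactly 0.5 h × trials;
* nights follow `max(1, round_half_up(billed_days))`, which reproduces the
  reported ~1 night for full PBP (mean 1.17 days) and 3 nights for
  apprenticeship (mean 2.67 days).

`calibrate_params()` inverts the generator: $p$ is solved numerically
(monotone bisection via `uniroot`) so the *whole-group* expected trials —
proficiency rate × censored-geometric mean + (1 − rate) × cap — equals the
published group mean; the days distribution is a two-point distribution on
the adjacent half-day grid values whose implied whole-group mean equals the
published mean days. Infeasible targets (mean above the cap, or below the
floor implied by non-proficient trainees at the cap) raise calibration
errors rather than silently clamping.

Calibration anchors per arm: mean trials 5.92 / 6.76 / 12 / 15, mean days
1.17 / 1.29 / 1.5 / 2.67, proficiency 1 / 1 / 1 / 7⁄12. The e-learning arm's
trial count was never published; it is derived from its published 3.38
hands-on hours via the 0.5 h/trial slot. Parameter recovery is tested at
n = 10 000 per arm (means within 2%).

What the generator does **not** emulate, and what passing tests therefore do
not show about real cohorts:

* The published 7.75 hands-on hours for apprenticeship deviates ~3% from
  0.5 h × 15 trials; the generator keeps the exact 0.5 h/trial rule rather
  than inventing a per-trial duration distribution, so it reproduces the
  trials mean, not that hours figure.
* The published aggregates do not identify the split of the apprenticeship
  mean between proficient and non-proficient trainees; with non-proficient
  trainees at the cap of 30, the calibrated proficient subgroup averages
  ~4.3 trials. Only whole-group statistics should be read off the simulated
  arms.
* Within-group variances were never published; the censored geometric fixes
  the trials variance implicitly, and the two-point days distribution is the
  minimal-support choice for a given mean. Where a group's mean days lies
  exactly on the half-day grid (the traditional arm, 1.5 days) the days
  distribution degenerates to a point mass, so that arm's simulated variable
  cost can have zero variance at small n — its bootstrap interval is then
  flagged degenerate rather than treated as an error.
* Robot scheduling contention (three trainees per system rotating in 90-min
  blocks) and within-trial learning curves are out of scope; days are drawn
  from their calibrated distribution rather than derived from hours, because
  the published hours→days relation differs across arms (2.96 h → 1.17 days
  but 6.00 h → 1.5 days), so no single throughput constant reproduces both.

## Uncertainty

Confidence intervals use the percentile bootstrap of the mean per-trainee
variable cost (default 10 000 resamples, seeded); the amortized fixed share
is a known constant added outside the interval, consistent with the
published intervals' constant half-widths across cohort sizes within an arm.
Total-cost intervals scale the per-trainee bounds by $N$. A normal-theory
interval is also provided; the publication does not state which method
produced its intervals, so neither is claimed as "the" original. Coverage of
the percentile bootstrap is validated at 1 000 replicates of samples of 100
(the method's valid regime, expected 93–97% coverage); at the trial's n = 12
the percentile bootstrap is known to undercover slightly (~90–92%), a
documented small-sample limitation.

Between-group differences use a two-sided permutation test on the mean
difference, Monte-Carlo with the add-one correction
$p = (b+1)/(n_\text{perm}+1)$ (default 9 999 permutations, so the smallest
attainable p is $10^{-4}$), or exact enumeration of all label assignments
for small groups. The exact mode agrees with brute-force enumeration in the
tests; Monte-Carlo p-values are seed-deterministic.

## Problem sizes and defaults

| Parameter | Default | Why |
|---|---|---|
| lab day rate | €2 450 / person-day | the centre's actual billing rate |
| hotel night rate | €200 / night | standardized accommodation rate |
| fixed metrics cost | €132 377 | metrics development + validation + e-learning |
| trial cap | 30 trials | 30-min slots feasible within 3.5 days |
| cohort-size grid | 12, 50, 100, 200, 300, 400, 500 | the published projection grid |
| bootstrap resamples | 10 000 | stable 2.5/97.5 percentiles |
| permutations | 9 999 | resolves p < 0.001 |
| recovery cohort | 10 000 trainees | Monte-Carlo error well under the 2% tolerance |
| Markov cross-check | 100 000 chains | 3-SE agreement band ~0.05 trials |

These sizes keep the full test suite and the acceptance script fast while
leaving simulation error far below every tolerance used.
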