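---
title: "Modelling the biopsy diagnosis workflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the biopsy diagnosis workflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathflowsim)
```

## The problem

An anatomic-pathology department diagnoses disease from tissue
specimens. Each biopsy passes through a 36-activity chain — reception,
cutting, paraffin embedding, slicing, staining, and finally the
pathologist's reading of the slide — staffed by a handful of
technicians and pathologists working fixed day shifts. When diagnostic
capacity falls below demand, a backlog of undiagnosed biopsies builds
up and waiting times stretch from days to months, with direct clinical
consequences.

`pathflowsim` models this workflow end to end: it generates the random
service and arrival times, simulates the flow of biopsies through the
chain, quantifies installed productive capacity and staffing needs, and
compares the economics of staffing scenarios. A synthetic biopsy-log
generator stands in for confidential hospital records so that every
estimator in the package can be exercised against known ground truth.

## Random variates: the Box-Muller transform

All stochastic inputs derive from the sine-branch Box-Muller transform:
for independent uniforms $U_1, U_2 \in (0,1)$,

$$x = \sqrt{-2 \ln U_1}\,\sin(2\pi U_2)$$

is standard normal, and $\mu + \sigma x$ gives a general normal
deviate. `sample_normal()` consumes exactly two fresh uniforms per
deviate (verifiable via `draw_count()`); an optional `"paired"` method
also uses the cosine companion, halving consumption. The uniform source
is a seedable stream with private state, so package draws never
interact with the session's global random-number generator, and
uniforms are nudged one machine epsilon away from 0 and 1 because
$\ln 0$ diverges.

Durations must be positive, so service-time sampling uses
*rejection* of non-positive deviates rather than clamping: the shape of
the distribution on the positive support is preserved exactly. The
price is a small upward bias of the realized mean relative to the
nominal $\mu$ — about $+0.17$ min ($1.9\%$) for the slow-reading
component most affected here — which propagates visibly into the
capacity totals discussed below.

## Service times: two-component Gaussian mixtures

Cutting and slide-analysis times are bimodal. The package models each
stage as a two-component normal mixture (`bimodal_model()`):

| stage    | component | mean (min) | SD (min) | weight |
|----------|-----------|-----------:|---------:|-------:|
| cutting  | routine   | 1.1563     | 0.423    | 0.909  |
| cutting  | large sections | 30    | 10       | 0.091  |
| analysis | routine   | 9.2571     | 4.3069   | 0.648  |
| analysis | complex   | 27.389     | 6.001    | 0.352  |

Parameter recovery (`classify_bimodal()`) is deliberately a
threshold-split moment estimator, not an EM fit: values below 16 min
form group 1, values above 20 min group 2, and values inside the gap go
to the nearer threshold (ties to group 1, which preserves the observed
2:1 routine-to-complex ratio). This is the procedure the models were
derived with, and it is transparent — but it is biased wherever a
component straddles the split. For the analysis model the bias is
negligible and 5,000 draws recover means within 0.5 min and proportions
within 0.05. For the wide slow cutting mode ($\sigma = 10$ min),
truncation below the effective 18-min boundary inflates the recovered
mean by about $+2.2$ min irrespective of sample size; the test suite
checks that estimator against its exact region-conditional expectation
rather than pretending the bias away.

A related known inconsistency in the source material: the mixture
weights above (90.9/9.1 and 64.8/35.2) do not match the proportions
implied by the annual combination counts used for capacity planning
(which imply roughly 96/4 and 84/16). The package treats the counts as
given inputs and exposes `combination_weights()` (the
independence-product allocation) for sensitivity analysis only.

## Inferential toolkit

* `chi_square_gof()` computes $\chi^2 = \sum_i (o_i - e_i)^2 / e_i$
  over $k$ cells with $k - 1$ degrees of freedom. (The source text
  describes $k$ as "the number of data"; the conventional and
  internally consistent reading — number of *cells* — is implemented.)
  For continuous samples, `chi_square_gof_normal()` bins into
  equal-probability cells of the fitted normal with
  $k = \max(2, \min(20, \lfloor n/5 \rfloor))$, keeping every expected
  count at or above 5.
* `normality_check()` wraps the Anderson-Darling test (parameters
  estimated); a sample is screened as normal when $p > \alpha$.
  Constant samples are refused with an error rather than given a
  meaningless verdict.
* `validation_interval()` compares a real series $X$ with a simulated
  series $Y$ paired by period:
  $(\bar X - \bar Y) \mp t_{\nu-1,\,1-\alpha}\sqrt{\operatorname{var}(X-Y)/\nu}$.
  The model is accepted when the interval contains zero. The variance
  term is read as the variance of the paired differences divided by
  $\nu$, the standard paired-interval form.
* `sample_size_one_sample_t()` iterates $n$ upward under the *exact*
  noncentral-$t$ power of a two-sided one-sample test (no normal
  approximation), because the planning values it must reproduce —
  $n = 29$ at $\delta = 3$, $\sigma = 4.30$ and $n = 21$ at
  $\delta = 5$, $\sigma = 6.001$, both at $\alpha = 0.05$, power 0.95 —
  are exact-noncentral results.

```{r power}
sample_size_one_sample_t(3, 4.30)
sample_size_one_sample_t(5, 6.001)
```

## The process model and its reconstruction

The 36-activity chain is shipped as `fixture_pathology_process()`. The
flowchart's per-activity means and SDs were never published legibly, so
the fixture is a documented *reconstruction*: the published 40-hour
workload table reports, for 31 activities, the weekly hours required to
process 239 routine biopsies, and the fixture back-derives each
per-unit time as `hours * 60 / 239` minutes. This reproduces every
printed cell exactly (to the table's 3 decimals) by construction. The
five activities with no printed time anywhere (1, 2, 6, 35, 36) carry
0.5-minute placeholders and are flagged in a `placeholder` column.
Because the workload table covers the routine (group-1) stream, the
fixture represents that stream; the full bimodal reality lives in the
capacity module.

Resource assignment follows the department's staffing table: a
cutting-room technician, two histology technicians, and one
pathologist, all on a 40-hour operational week. Transport, storage and
waiting steps are uncontended delays. Stochastic runs
(`fixture_pathology_process(stochastic = TRUE)`) assign each activity
an SD of 20% of its mean — a fixture convention, not an observed
quantity.

## The discrete-event engine

`run_simulation()` is a classic event-driven simulator: weekly arrival
counts are drawn from the demand normal (rounded half-up, floored at
zero), arrival instants are spread uniformly over the week's
operational hours, and entities advance through the chain, queueing
FIFO on each resource's parallel servers. Three design choices matter:

* **Operational time.** The clock counts on-shift hours; since all
  resources in the reference process share one calendar, the mapping
  from wall-clock to operational time is monotone and simulating in
  operational time is exact. Heterogeneous per-resource calendars are
  validated but not interleaved in this version; work in progress
  implicitly pauses off shift.
* **Utilization is workload per station**: busy hours divided by the
  horizon, for every activity including delays. That is the accounting
  used in the published workload table, where the three flagged
  constraints — block refrigeration (19), slide storage (32), and the
  pathologist's walk to the slides (33) — are storage/transport steps,
  not staffed stations. A separate arrival-rate-to-cycle-time
  diagnostic would be redundant here because the same per-unit times
  drive both.
* **Warm-up.** Statistics are accrued in a reporting window after an
  optional `warmup_hours` phase. Reproducing the published per-activity
  workload requires observing the chain in steady flow: without
  warm-up, late-chain activities are starved while the pipeline fills
  and their utilizations understate the steady state.

The published simulation throughput — about 239 biopsies per 40-hour
week — is a *capacity* figure: the chain paced by its most loaded
single activity. `weekly_capacity()` computes exactly that
(`weekly hours / max(mean_min / servers)`, delays counted as single
stations), and the reproduction runs pace arrivals at this rate rather
than flooding the chain, which would inflate upstream activity totals
and contradict the published per-activity unit counts.

```{r des, eval = FALSE}
proc <- fixture_pathology_process()
sim <- run_simulation(proc, demand_spec(weekly_capacity(proc), 0),
                      horizon_hours = 40, replicates = 5, seed = 1,
                      warmup_hours = 40)
find_bottlenecks(sim)        # 19, 32, 33
category_totals(sim)
```

Problem sizes throughout the package (40-h weeks, 5 replicates, a
40-h warm-up, 10 capacity replicates) are the department analysis's own
run configurations and complete in seconds.

## Capacity, staffing, and economics

`capacity_report()` simulates, for each of the four cutting-by-analysis
combinations (annual counts 6,748 / 1,242 / 210 / 112), the pathologist
hours needed to cut and read every biopsy, averaging 10 replicates.
With zero variance this collapses to the closed form
`count * (mu_cut + mu_analysis) / 60`; with the mixture SDs and
positive-only sampling the expectation sits slightly above the nominal
closed form (about +1%, the truncation lift described earlier). The
grand total lands near 2,013–2,029 h; at 1,776 productive hours per
FTE-year (`required_fte()`) this is a 1.13-FTE requirement, a shortfall
of 680.78 h at the current 0.75 FTE and a surplus of 1,095.22 h at a
proposed 1.75 FTE. The 50-week demand year is back-derived from the
published annual demand (7,576 / 151.55 ≈ 50); the package takes both
numbers as stated.

`cost_report()` and `compare_scenarios()` implement the cost-benefit
arithmetic: total cost = fixed + overtime, cost per biopsy =
total / annual output, money at cent precision. The overtime rate
defaults to 2,433.03/320 ≈ 7.603 US$/h, derived from the one scenario
that prices an overtime block, and is overridable. Backlog clearance is
exposed as plain division (`backlog_clearance_months()`); the 7- and
3-month adjustment horizons of the published proposals are inputs, not
model outputs, because the source gives no quantitative backlog model.
Two cent-level arithmetic slips in the published cost table (a total
off by $0.24 from its own addends; a unit cost of 10.64 where the
quotient rounds to 10.65) are documented in the tests; the package
always reports internally consistent arithmetic.

## The synthetic generator

`generate_biopsy_log()` emulates the hospital's (undeposited)
transactional log: weekly arrivals $\sim N(151.55, 18.45)$ rounded to
counts; specialty drawn so the top four specialties jointly carry
81.24% (split 4:3:2:1 within the block — only the block total is an
observed quantity); provenance 87% own hospital / 13% network;
cutting and analysis durations from the bimodal models with the
generating component recorded; and FIFO diagnosis under a weekly
capacity that is unlimited before week 24 and constant (default 28 per
week) thereafter. The default capacity is calibrated so a 43-week run
leaves about 38% of arrivals undiagnosed — the documented shortfall —
and `gap_series()` then shows the received-vs-diagnosed gap opening at
week 24 and growing, the qualitative shape observed in the department's
records.

What the generator does *not* emulate: calendar effects (holidays,
vacation troughs), demand trend and seasonality, correlation between a
biopsy's specialty and its service times, batch processing of histology
racks, and rework loops. Tests passing on synthetic data therefore
demonstrate estimator correctness under the stated model, not fidelity
of that model to any particular hospital.

`recovery_suite()` closes the loop: it generates a log and re-estimates
demand mean/SD (with Anderson-Darling and chi-square screens) and the
mixture proportions and means, reporting estimate against truth.

## Numerical conventions and degenerate inputs

Durations are minutes internally; reports use hours (3 decimals where
the published tables do), money to cents, FTE to hundredths. Weekly
counts round half-up and floor at zero. Zero-variance specifications
are honoured exactly (no noise injected). Requests that can never
succeed fail fast with descriptive errors: positive-only sampling from
a non-positive degenerate normal, classification when every value lies
inside the 16–20-min gap, normality checks on constant samples,
removing the terminal diagnostic activity, a staffed resource with no
on-shift capacity, backlog clearance with no surplus.

## Known limitations

* One shared shift calendar per run; off-shift pausing is implicit.
* The chain is linear (single successor); no rework, priorities, or
  batching.
* Threshold-split recovery is biased for components that straddle the
  split (quantified above); EM fitting is out of scope by design.
* The fixture's resource mapping and placeholder durations are a
  documented reconstruction, not observed data; conclusions that
  depend on them (e.g. which *staffed* resource saturates first) should
  be treated as illustrative.
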