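# pathflowsim

Discrete-event simulation and capacity analysis of a hospital
anatomic-pathology biopsy workflow.

## What this is for

Pathology departments diagnose disease from tissue specimens. A biopsy
traverses a long chain of activities — reception, cutting, paraffin
embedding, slicing, staining, and finally the pathologist's reading of
the slide — and when diagnostic capacity falls short of demand, a
backlog of undiagnosed biopsies accumulates and waiting times stretch
from days to months. `pathflowsim` is for health-systems analysts who
need to quantify that mismatch: how many productive hours the workload
actually requires, which activities bottleneck the flow, how many
full-time-equivalent (FTE) pathologists are needed, and what competing
staffing plans cost per biopsy.

The model core:

* **Box-Muller variates.** All randomness comes from the sine-branch
  transform `x = sqrt(-2 ln U1) sin(2 pi U2)`, two fresh uniforms per
  deviate, on a seedable stream isolated from R's global RNG. Service
  times are positive-only by rejection.
* **Bimodal service times.** Cutting and slide analysis are
  two-component normal mixtures (routine vs complex work), e.g.
  analysis ~ 0.648 N(9.2571, 4.3069²) + 0.352 N(27.389, 6.001²)
  minutes, and a 16/20-minute threshold classifier recovers the
  components from raw durations.
* **Event-driven workflow engine.** Weekly demand ~ N(151.55, 18.45)
  biopsies; entities queue FIFO on shift-constrained resources through
  a 36-activity chain; utilization = busy hours / horizon flags
  bottlenecks at ≥ 90%.
* **Capacity and economics.** Annual pathologist hours by
  cutting-by-analysis combination, FTE requirements at 1,776 h per
  FTE-year, and cent-exact cost-per-biopsy comparison of staffing
  scenarios.
* **Synthetic data.** A generator emulating the hospital's log
  (specialty and provenance mix, backlog onset at week 24) so every
  estimator is testable against ground truth.

## Worked example

How many pathologists does the annual biopsy workload require?

```r
library(pathflowsim)

cap <- capacity_report(replicates = 10, seed = 1)
cap
#> <capacity_report> 10 replicates, seed 1
#>  combination count cut_hours analysis_hours total_hours
#>         C1A1  6748    130.19        1061.13     1191.32
#>         C1A2  1242     24.01         566.96      590.98
#>         C2A1   210    105.53          33.18      138.71
#>         C2A2   112     56.15          51.77      107.92
#>        Total  8312    315.88        1713.05     2028.93

required_fte(cap$grand_total_hours)
#> [1] 1.14
```

Reading the table: cutting and reading all 8,312 biopsies of a year
consumes about 2,029 pathologist-hours — routine-cut/routine-read cases
(C1A1) dominate at ~1,191 h. At 1,776 productive hours per FTE-year
that workload needs ~1.13–1.14 FTE, so the current 0.75-FTE staffing is
roughly 680–700 h short per year while a 1.75-FTE plan has ~1,100 h of
headroom.

Where does the flow itself jam? Simulate the 36-activity chain for five
40-hour weeks (after a 40-hour warm-up), paced at its weekly capacity:

```r
proc <- fixture_pathology_process()
sim <- run_simulation(proc, demand_spec(weekly_capacity(proc), 0),
                      horizon_hours = 40, replicates = 5, seed = 1,
                      warmup_hours = 40)
find_bottlenecks(sim)
#> [1] 19 32 33
#> attr(,"utilization")
#> [1] 1.0008647 0.9390201 0.9227599
```

Activities 19 (block refrigeration), 32 (slide storage) and 33 (the
pathologist's walk to the slides) run above 90% utilization — the
storage and transfer steps around the pathologist, not the microscope
work itself, pace the chain at ~239 biopsies per week.

And what do the staffing plans cost?

```r
compare_scenarios(default_scenarios())[, c("name", "total_cost",
                                           "diagnosis_days",
                                           "cost_per_biopsy")]
#>         name total_cost diagnosis_days cost_per_biopsy
#> 1 proposal 1   46225.00              3            5.57
#> 2 proposal 2   46225.00              3            5.57
#> 3 proposal 3   48658.03              3            5.86
#> 4    current   51631.23            120           10.65
```

Two pathologists cut the diagnosis turnaround from 120 days to 3 and
the unit cost from ~10.6 to 5.57–5.86 US$ per biopsy; the dearer
proposal 3 buys a 320-hour overtime block that clears the 2,468-biopsy
backlog in 3 months instead of 7.

A command-line wrapper is installed at `inst/scripts/pathflowsim`
(subcommands `simulate`, `capacity`, `scenarios`, `validate`, `synth`,
`recover`), writing CSV + JSON reports with a run manifest.

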