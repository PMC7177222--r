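# qvroute

Vehicle scheduling for transferring high-risk individuals to an isolated
region during an epidemic.

## The problem

When an outbreak produces many suspected cases and close contacts, they
must be moved from scattered areas into medical isolation by a limited
fleet of quarantine vehicles.  Each area *a<sub>j</sub>* holds
*b<sub>j</sub>* individuals; vehicle *v<sub>i</sub>* has capacity
*c<sub>i</sub>*, its own travel times *t<sub>i,j</sub>* (origin→area),
*t<sub>i,j,j′</sub>* (area→area), *t′<sub>i,j</sub>* (area→region), and a
loading interval Δ*t<sub>i,j</sub>* between successive individuals
boarding.  A schedule gives every vehicle an ordered area sequence
*x<sub>i</sub>* and, after each non-final area, a direction bit
*y<sub>i,j</sub>* (1 = unload at the region before continuing, 0 = drive
on loaded).  The objective is the cumulative **sum of exposure times**

> min *f*(X, Y) = Σ<sub>j</sub> T<sub>j</sub>,

where each individual's exposure runs from dispatch until boarding —
a minimum-latency objective, not distance.  Areas can exceed any single
vehicle's capacity, so vehicles may shuttle (area ↔ region) and several
vehicles may split one area, governed by rules tied to the minimum fleet
capacity *c*<sub>min</sub>: small areas (*b* ≤ *c*<sub>min</sub>) get one
vehicle only; an area gets at most ⌈*b*/*c*<sub>min</sub>⌉ vehicles; a
vehicle alone at an area shuttles until it is empty; the first vehicle to
arrive at a shared area loads as much as it can.

The package provides, for researchers and emergency-logistics engineers:

* the problem data model with validation, rule checking, and a documented
  JSON interchange format (`qv_instance`, `check_rules`, `load_instance`);
* two independent evaluators of a schedule — the closed-form recursion
  (`evaluate_formula`) and a per-individual discrete-event simulation
  (`evaluate_events`), with a flag marking the domain where they provably
  agree;
* a hybrid **water wave optimization + gradual neighborhood search**
  solver (`wwo_solve`): wavelength-controlled subsequence reversals,
  best-of-swaps breaking on new incumbents, direction-vector refinement,
  completion-time balancing, and linear population reduction;
* a claim-based nearest-area greedy dispatcher (`greedy_solve`) modeling
  the manual practice the optimization replaces;
* a seeded synthetic generator (`generate_instance`) reproducing the
  printed summary characteristics of seven real deployments
  (`deployment_presets`), whose raw data are not public;
* a command line (`inst/cli/qvroute`): `solve`, `evaluate`, `generate`,
  `greedy`.

## Worked example

The two-vehicle, three-area instance used throughout the documentation:
vehicle 1 (capacity 15) visits areas 1, 2, 3 and unloads between areas 2
and 3; vehicle 2 visits areas 2 and 3, unloading in between.

```r
library(qvroute)
inst <- worked_example_instance()
sol  <- worked_example_solution()
ev   <- evaluate_events(inst, sol)
ev
#> qv_evaluation (events): objective 1098 minutes x persons (21.95 min / individual)
ev$timelines[[1]]
#>   area arrival leave capacity_on_arrival rounds loaded
#> 1    1     5.0   9.5                  15      0     10
#> 2    2    19.5  21.5                   5      0      5
#> 3    3    36.5  38.5                  15      0      5
round(ev$area_exposure, 2)
#> [1]  72.5 305.0 720.0
```

Vehicle 1 reaches area 1 at minute 5 and leaves at 9.5 after boarding its
10 individuals at 0.5-minute intervals (their summed exposure: 72.5
minute-persons); it arrives at area 2 at 19.5 carrying 10 of 15, loads the
5 left after vehicle 2's first round, leaves at 21.5, unloads at the
region, and reaches area 3 at 36.5.  The closed-form evaluator reproduces
the identical schedule (`evaluate_formula(inst, sol)`), and the total,
1097.5, is the sum of the per-area exposures.

Improving on the hand schedule and on greedy dispatch:

```r
greedy_solve(inst)$objective
#> [1] 1097.5
res <- wwo_solve(inst, search_config(max_evals = 2000, seed = 1))
res$objective
#> [1] 1040
res$solution
#> v1: 1 ->R-> 3 ->R-> 2
#> v2: 2 -> 3
```

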