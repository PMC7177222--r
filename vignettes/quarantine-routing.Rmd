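---
title: "Scheduling quarantine vehicles to minimize exposure time"
author: "qvroute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling quarantine vehicles to minimize exposure time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvroute)
```

## The problem

During a severe epidemic, suspected cases and close contacts — *high-risk
individuals* — scattered across a city must be moved to a single isolated
region for medical observation as fast as possible.  A fleet of quarantine
vehicles with heterogeneous capacities and speeds is available.  Each area
$a_j$ holds $b_j$ individuals; vehicle $v_i$ has capacity $c_i$, travel
times $t_{i,j}$ (origin to area), $t_{i,j,j'}$ (area to area) and $t'_{i,j}$
(area to region), and a per-area loading interval $\Delta t_{i,j}$ — the
mean time between two successive individuals boarding, reflecting how
dispersed people are within the area.

A schedule assigns each vehicle an ordered sequence of areas $x_i$ and,
after every non-final area, a direction bit $y_{i,j}$: 1 sends the vehicle
back to the isolated region to unload before its next area, 0 sends it
directly onward with its current load.  The objective is the **sum of
exposure durations**: each individual's exposure runs from dispatch (time
0) until they board a vehicle, and we minimize the total over all
individuals — a cumulative (minimum-latency) objective, not route length.
Makespan-style efficiency is only an indirect consequence; what matters is
loading many people early.

Because an area may hold more people than any vehicle can carry, the
problem allows *shuttling* (a vehicle cycles between an area and the
region) and *splitting* (several vehicles serve one area).  Splitting is
governed by rules stated relative to the minimum fleet capacity
$c_{\min}$:

* **R1** — an area with $b_j \le c_{\min}$ is served by one vehicle only;
* **R2** — a vehicle alone at an area may not move on until the area is
  empty (it shuttles);
* **R3** — an area may be assigned to at most
  $k_j = \lceil b_j / c_{\min} \rceil$ vehicles;
* **R4** — at a shared area, the first vehicle to arrive loads as much as
  it can before later arrivals take the rest;
* **R5** — the rules recursively apply to the residual subproblem as
  vehicles are committed.

`check_rules()` verifies R1, R3, coverage and structural bounds statically
(against the global $c_{\min}$ — the conservative reading; the sequential
greedy dispatcher applies the same rules claim-by-claim as it commits
vehicles, which is how we operationalize R5).  R2 and R4 are enforced by
the evaluators by construction.

## Evaluating a schedule

The package evaluates a schedule twice, by two deliberately independent
routes:

**`evaluate_formula()`** implements the closed-form recursion: arrival
times, leave times, residual capacities, shuttle counts, and per-area
exposure totals, e.g. for a single-vehicle visit with $b \le c$ the area
contributes $b\tau + \frac{b(b-1)}{2}\Delta t$, and a shuttling visit adds
$k\,t'\,(2b - (k+1)c)$ for its $k$ round trips.

**`evaluate_events()`** is a discrete-event simulation that loads
individuals one by one and sums their boarding times — no closed forms
anywhere.  It is the package's reference objective, used by the solver.

### The loading clock

The closed forms embody a specific timing model: the $i$-th individual of
an area boards at
$\tau + (i-1)\Delta t + 2t' \times (\text{round trips completed before them})$
— the $\Delta t$ ladder keeps running across shuttle rounds.  The event
simulation enumerates individuals under exactly this clock, so the two
evaluators can be compared meaningfully.  At shared areas, each loading
round restarts its ladder at the round's arrival time, which is what the
round-update recursion states; the package follows it as printed.

### Where the two evaluators agree

The multi-round closed forms are exact only when the vehicle starts an
area freshly reloaded (arrival capacity = full capacity) and its final
round is not exactly full; an exactly-full final round makes the printed
leave-time recursion include a phantom return trip, and a partially loaded
arrival breaks the shuttle-term coefficient.  `evaluate_events()` flags
each run with `meta$formula_consistent`; inside the flagged domain the two
evaluators agree to machine precision on objectives, arrivals and leave
times (this is asserted in the test suite over hundreds of seeded
schedules, and exhaustively for $b \le 60$, $c \le 20$ at full arrival
capacity).  Outside it, the event semantics are authoritative: a vehicle
that fills up returns to the region regardless of its direction bit, and a
vehicle with no free capacity makes a pure reload trip.

### Multi-vehicle coordination

Shared areas are evaluated by a frontier procedure: pending visits are
processed in order of arrival time (ties: lower vehicle index, a
determinism choice); the earliest arriver loads up to its residual
capacity (R4); if individuals remain, the vehicle provisionally shuttles
back and re-enters the frontier; when the area empties, every other
vehicle still headed there is resolved — one that loaded in an earlier
round is restored to its last actual round (it proceeds to its next area
from the region), and one that never loaded skips the visit, its next
arrival recomputed from its last committed departure using the direction
bit that governed that departure.  Skipped visits appear in the timeline
with `loaded = 0` so the provisional arrival times remain inspectable.
One printed inconsistency in the source walk-through (a round load
exceeding the vehicle's capacity) is resolved by always loading
$\min(\text{remaining}, \text{residual capacity})$ per round.

## The hybrid solver

`wwo_solve()` follows the water wave optimization (WWO) template: a small
population (default 8, shrinking linearly to 3 over the budget) evolves
under three operators, plus a direction-vector refinement.

* **Wavelengths.**  Each member's wavelength is its share of the
  population's total objective, $\lambda(Z) = f(Z) / \sum_{Z'} f(Z')$ —
  worse solutions mutate more widely.
* **Propagation.**  Routes are encoded as one permutation string with
  separators.  Each area position triggers, with probability $\lambda$, a
  reversal of a random-length slice starting there; slices crossing
  separators reassign areas between vehicles.  Each triggered reversal is
  evaluated as its own candidate, and the joint application of all
  triggered reversals is evaluated as one additional compound candidate —
  fine moves drive descent, the compound jump offers an escape from local
  optima at a scale set by the wavelength.  The best candidate replaces
  the member only if strictly better.
* **Breaking.**  Whenever a generation produces a new incumbent, each of
  its routes receives $\lceil \alpha n_i \rceil$ random position swaps
  (default $\alpha = 0.25$); the best swap is kept per route only if it
  strictly improves.
* **Gradual neighborhood search.**  For each vehicle, each return bit is
  flipped in turn (a bit forced by a full vehicle is skipped) and all
  later bits of that vehicle are regenerated by the loading-rate
  heuristic; the best neighbor replaces the direction vector only if
  strictly better.  Members are re-refined only after something changed
  them — a refined member's direction vector is at a fixed point, and
  re-deriving it every generation would spend the evaluation budget
  without information gain.
* **Balancing.**  Accepted propagation candidates get the completion-time
  balancing pass (relocate areas from the busiest to the most idle
  vehicle, best single move per round, monotone), the same pass applied to
  every member at initialization.
* **Stall restarts.**  When no member changes for three consecutive
  generations, every operator's neighborhood around the population is
  exhausted (measured directly: on plateaued members, no single reversal
  and no intra-route swap improves), so further sampling spends the
  budget on information-free rejections.  The population is then
  reinitialized around the incumbent, which keeps the incumbent monotone
  while re-investing the remaining budget in fresh basins.

### Direction bits under route mutations

How the direction vector survives a route mutation is not determined by
the operator definitions, and it matters: regenerating all bits from the
heuristic would discard refined decisions and bias candidate evaluation
against good route moves.  The package keeps bits positionally on
unchanged route prefixes, carries them by *area identity* where an area
stays in the same vehicle's route, and fills the rest deterministically
with the loading-rate threshold (return iff load $\ge$ half capacity);
accepted candidates are then refined stochastically by the neighborhood
search.

### Keeping the sharing distribution stationary

A slice reversal can land both copies of a shared area in one route;
duplicate removal then deletes one, and no operator re-adds copies — left
alone, multi-vehicle sharing would decay monotonically over a long run,
pushing the search away from exactly the schedules that large areas need.
`repair_solution()` therefore gives every area that lost a copy to
duplicate removal a fresh draw of the probabilistic extra-vehicle
assignment used at construction (probability = uncovered demand fraction,
uniformly chosen eligible vehicle).  Feasible inputs pass through repair
with routes untouched.

### Construction

Initial members are random permutations split by $m-1$ separators chosen
without replacement among the $n+1$ gaps; areas whose demand exceeds their
assigned capacity are assigned to additional vehicles, each draw accepted
with probability equal to the uncovered demand fraction, and the recursion
runs until the demand is covered, the vehicle cap binds, or no eligible
vehicle remains — residual demand is absorbed by shuttling (the printed
selection condition has an inverted sign — taken literally the probability
is nonpositive, so the demand-exceeds-capacity reading is used).  Direction bits come from
the loading-rate heuristic: vehicles are simulated in index order against
a shared pool of untaken individuals; a sole server takes its whole area
(shuttling), and the return probability after each area is the loading
rate, with certainty at full load.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pop_init` / `pop_min` | 8 / 3 | population size, shrinking linearly over the budget |
| `alpha` | 0.25 | breaking intensity: swaps per route = $\lceil \alpha n_i \rceil$ |
| `max_evals` | 50000 | evaluation-count budget (every full-solution evaluation counts, including repair and balancing bookkeeping); deterministic for a fixed seed |
| `time_limit` | off | optional wall-clock budget in seconds |
| `seed` | 1 | RNG seed; identical seed + evaluation budget gives identical output |

## The greedy baseline

`greedy_solve()` models the dispatch practice the optimization replaces:
whenever a vehicle is free it is sent to the closest area (by its own
travel time from where it stands) that still has individuals not covered
by other vehicles' claims, subject to R1/R3 on the set of claimants.  A
dispatched vehicle claims up to its free capacity, so vehicles do not pile
onto demand that is already covered; simultaneous conflicting claims go to
the vehicle that would arrive earlier.  Full vehicles unload at the
region; a vehicle that leaves individuals behind keeps shuttling back
until its area is empty or another claim covers the rest.  The realized
trajectory is encoded as a route-and-direction schedule and scored by the
event evaluator, so both algorithms are compared under identical
semantics.

## The synthetic generator

No real deployment data are published, so `generate_instance()` emulates
the printed summary characteristics of the seven reported deployments
(`deployment_presets()`): areas, vehicles, mean individuals per area $\bar b$,
number of vehicle types $K_V$, mean capacity $\bar c$, mean travel time
$\bar t$.  Its model:

* individual counts: $1 + \mathrm{Poisson}(\bar b - 1)$, so every area is
  nonempty and the mean is $\bar b$;
* geometry: areas, vehicle origins and the region placed uniformly in a
  square; per-vehicle travel time = Euclidean distance × type speed
  factor, the whole time scale chosen so the fleet-wide mean between-area
  time equals $\bar t$ exactly;
* capacities: $K_V$ integer capacities spaced one apart and centred on
  $\bar c$, assigned round-robin; speed factors evenly spaced in
  $[1 - d, 1 + d]$ with `travel_dispersion` $d = 0.4$;
* loading intervals: uniform per area in 0.1–5 minutes, shared across
  vehicles.

What this does *not* emulate: road-network structure (clustered demand,
asymmetric or congested links), correlated counts, and the time-varying
conditions of a real outbreak.  Passing tests therefore show that the
method behaves as designed under the reported summary statistics, not that
the specific published performance numbers transfer.

## Numerical and design choices

* Durations are real-valued minutes; nothing assumes integral times (the
  worked example uses 0.5-minute loading intervals).
* Frontier ties break to the lower vehicle index; greedy claim ties to the
  earlier arrival then lower index; all operators accept strictly better
  candidates only, so the incumbent objective is non-increasing (asserted
  every generation).
* Degenerate inputs: empty routes are legal and contribute nothing;
  a vehicle arriving with zero free capacity makes a pure reload trip;
  identity reversals (length-1 slices) are recognized and not
  re-evaluated.
* Instance JSON round-trips numerics at 17 significant digits, so
  save/load is exact.
* Test problem sizes: evaluator equivalence uses 5-area/2-vehicle
  schedules (hundreds of seeds) plus the exhaustive small-domain check;
  solver optimality uses 3-area/2-vehicle instances where full enumeration
  of every feasible assignment, order and direction vector is tractable
  (counts around 8, capacities 10/15, so splitting is legal but not
  forced); the dominance comparison runs the 27-area preset with a 50,000
  evaluation budget, the scale at which a single run stays in tens of
  seconds.

## Known limitations

* The closed-form evaluator is kept for fidelity and transparency; its
  exactness domain excludes partially-loaded multi-round visits, which the
  event evaluator handles as the reference.
* The solver's operator set cannot represent a vehicle revisiting an area
  non-consecutively except through shuttling; schedules of that shape are
  outside the search space (and outside the encoding).
* Search quality at fixed evaluation budgets depends on the instance
  geometry; on some synthetic draws the claim-based greedy dispatcher is
  within a percent of the best schedule found, and exceeding it reliably
  needs larger budgets.
* Driver scheduling, mixed electric/fuel fleets, stochastic travel times
  and mid-execution re-planning are out of scope.
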