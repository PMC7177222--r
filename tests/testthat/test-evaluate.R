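# Low-level recursion pieces first (anchored and enumeration-derived
# values), then the two full evaluators and their agreement.

test_that("shuttle round counts follow the floor rules", {
  expect_identical(round_trips_first(10, 15), 0L)
  expect_identical(round_trips_first(25, 10), 2L)
  expect_identical(round_trips_first(20, 10), 2L)

  expect_equal(round_trips_next(25, 7, 10, 0L), 2)
  expect_equal(round_trips_next(5, 5, 10, 0L), 0)
  expect_equal(round_trips_next(25, 3, 10, 1L), 2)
  expect_error(round_trips_next(5, 12, 10, 0L), "exceeds")

  # reduces to the first-area rule when arriving at full capacity and the
  # load actually overflows (below that no shuttling happens at all)
  for (cc in c(5, 8)) for (b in (cc + 1):40) {
    expect_equal(round_trips_next(b, cc, cc, 0L), round_trips_first(b, cc))
  }
})

test_that("leave times match the recursion and the per-individual oracle", {
  expect_equal(leave_time(5, 10, 15, 0L, 6, 0.5), 9.5)
  expect_equal(leave_time(19.5, 5, 5, 0L, 5, 0.5), 21.5)
  # multi-round case against enumeration (exact when not a whole multiple)
  expect_equal(leave_time(0, 25, 10, 2L, 5, 0), 20)
  for (b in c(7, 13, 25, 41)) {
    for (dt in c(0, 0.5)) {
      orc <- enumerate_single_visit(b, 10, 10, 2, dt, 5)
      expect_equal(leave_time(2, b, 10, orc$trips, 5, dt), orc$leave)
    }
  }
})

test_that("next arrival and residual capacity follow the transition rules", {
  expect_equal(next_arrival(9.5, 0L, 10, 6, 5), 19.5)
  expect_equal(next_arrival(21.5, 1L, 8, 5, 10), 36.5)
  expect_equal(next_arrival(42, 0L, 0, 3, 3), 42)

  expect_equal(next_capacity(10, 25, 10, 0L), 5)
  expect_equal(next_capacity(15, 10, 15, 0L), 5)
  expect_equal(next_capacity(4, 25, 10, 1L), 10)
  # explicit-round semantics where the printed recursion would go negative
  expect_equal(next_capacity(7, 25, 10, 0L), 2)
  # an exactly-full final round leaves the vehicle freshly unloaded
  expect_equal(next_capacity(10, 20, 10, 0L), 10)
  # agreement with enumeration at full arrival capacity: the residual room
  # is what the final loading round left over
  for (b in c(3, 12, 20, 27)) {
    final_round <- if (b <= 10) b else b - 10 * enumerate_single_visit(b, 10, 10, 0, 0.3, 4)$trips
    free <- if (final_round == 10) 10 else 10 - final_round
    expect_equal(next_capacity(10, b, 10, 0L), free)
  }
})

test_that("area exposure closed form equals per-individual enumeration", {
  expect_equal(area_exposure(10, 15, 5, 0.5, 0L, 6), 72.5)
  expect_equal(area_exposure(1, 9, 7, 123, 0L, 1), 7)
  # shuttle case: both the closed form and the oracle give 80
  orc <- enumerate_single_visit(20, 10, 10, 0, 0, 4)
  expect_equal(orc$exposure, 80)
  expect_equal(area_exposure(20, 10, 0, 0, 2L, 4), 80)

  # exhaustive small-domain agreement at full arrival capacity
  for (cc in 1:20) {
    for (b in 1:60) {
      k <- round_trips_first(b, cc)
      expect_equal(area_exposure(b, cc, 3, 0.25, k, 2.5),
                   enumerate_single_visit(b, cc, cc, 3, 0.25, 2.5)$exposure)
    }
  }
})

test_that("shared-area round helpers match their printed and derived values", {
  expect_equal(first_round_exposure(10, 5, 0.5), 72.5)
  expect_equal(first_round_exposure(1, 0, 3), 0)
  # 5 individuals at 19.5, 20, 20.5, 21, 21.5
  expect_equal(first_round_exposure(5, 19.5, 0.5), sum(19.5 + 0:4 * 0.5))

  expect_equal(shuttle_arrival_update(10, 15, 0.5, 5), 27)
  expect_equal(shuttle_arrival_update(0, 1, 9, 3), 6)
  expect_equal(shuttle_arrival_update(42, 1, 0.5, 0), 42)
})

test_that("both evaluators reproduce the worked example exactly", {
  inst <- worked_example_instance()
  sol <- worked_example_solution()
  for (evaluate in list(evaluate_events, evaluate_formula)) {
    ev <- evaluate(inst, sol)
    tl <- ev$timelines[[1]]
    expect_equal(ev$area_exposure[1], 72.5)
    expect_equal(tl$arrival, c(5, 19.5, 36.5))
    expect_equal(tl$leave[1], 9.5)
    expect_equal(tl$leave[2], 21.5)
    expect_equal(ev$objective, sum(ev$area_exposure))
  }
  # the two evaluators agree on the whole schedule
  ee <- evaluate_events(inst, sol)
  ff <- evaluate_formula(inst, sol)
  expect_equal(ee$objective, ff$objective)
  expect_equal(ee$completion, ff$completion)
  expect_true(ee$meta$formula_consistent)
})

test_that("degenerate solutions evaluate to the expected closed forms", {
  # one vehicle, one area, load fits: objective = b * arrival when dt = 0
  inst <- one_area_instance(7, 10, t_origin = 4, dt = 0)
  sol <- qv_solution(list(1L), list(integer(0)))
  for (evaluate in list(evaluate_events, evaluate_formula)) {
    ev <- evaluate(inst, sol)
    expect_equal(ev$objective, 7 * 4)
    expect_equal(ev$completion, 4 + 5)
  }
  # empty route contributes nothing
  inst2 <- small_instance(3, n = 4, m = 2)
  sol2 <- qv_solution(list(c(1L, 2L, 3L, 4L), integer(0)),
                      list(c(0L, 1L, 0L), integer(0)))
  if (is_feasible(inst2, sol2)) {
    ev <- evaluate_events(inst2, sol2)
    expect_equal(nrow(ev$timelines[[2]]), 0L)
    expect_equal(ev$completion[2], 0)
  }
  # single vehicle shuttling a big area: oracle equality
  inst3 <- one_area_instance(23, 10, t_origin = 2, t_region = 6, dt = 0.4)
  ev <- evaluate_events(inst3, qv_solution(list(1L), list(integer(0))))
  orc <- enumerate_single_visit(23, 10, 10, 2, 0.4, 6)
  expect_equal(ev$objective, orc$exposure)
  expect_equal(ev$timelines[[1]]$rounds, orc$trips)
})

test_that("rule-infeasible solutions are rejected with the rule named", {
  inst <- worked_example_instance()
  bad <- qv_solution(list(c(1L, 2L), integer(0)), list(0L, integer(0)))
  expect_error(evaluate_events(inst, bad), "coverage")
  expect_error(evaluate_formula(inst, bad), "coverage")
})

test_that("individuals are conserved across seeded instance/solution pairs", {
  set.seed(11)
  for (k in 1:40) {
    inst <- small_instance(200 + k, n = 6, m = 3)
    sol <- init_population(inst, 1, balance_rounds = 0)[[1]]
    ev <- evaluate_events(inst, sol)
    loaded <- sum(vapply(ev$timelines, function(tl) sum(tl$loaded), numeric(1)))
    expect_equal(loaded, sum(inst$areas$individuals))
    expect_equal(ev$objective, sum(ev$area_exposure))
  }
})

test_that("objective respects the earliest-arrival lower bound", {
  set.seed(21)
  for (k in 1:20) {
    inst <- small_instance(300 + k, n = 6, m = 3)
    sol <- init_population(inst, 1, balance_rounds = 0)[[1]]
    ev <- evaluate_events(inst, sol)
    b <- inst$areas$individuals
    # no individual can board before the fastest possible direct arrival of
    # any vehicle assigned to its area
    lb <- vapply(seq_len(n_areas(inst)), function(a) {
      assigned <- which(vapply(sol$routes, function(r) a %in% r, logical(1)))
      b[a] * min(inst$times$origin_to_area[assigned, a])
    }, numeric(1))
    expect_true(all(ev$area_exposure >= lb - 1e-9))
    expect_gte(ev$objective, sum(lb) - 1e-9)
  }
})

test_that("inflating every travel time never helps a fixed solution", {
  set.seed(31)
  for (k in 1:10) {
    inst <- small_instance(400 + k, n = 5, m = 2)
    sol <- init_population(inst, 1, balance_rounds = 0)[[1]]
    base <- evaluate_events(inst, sol)$objective
    inst2 <- inst
    delta <- 3
    inst2$times$origin_to_area <- inst2$times$origin_to_area + delta
    inst2$times$area_to_region <- inst2$times$area_to_region + delta
    inst2$times$between_areas <- inst2$times$between_areas + delta
    # keep the zero diagonal
    for (i in seq_len(n_vehicles(inst2)))
      inst2$times$between_areas[cbind(i, seq_len(n_areas(inst2)), seq_len(n_areas(inst2)))] <- 0
    expect_gte(evaluate_events(inst2, sol)$objective, base - 1e-9)
  }
})

test_that("formula and event evaluators agree on their consistent domain", {
  set.seed(41)
  checked <- 0
  for (k in 1:120) {
    inst <- generate_instance(generator_config(
      n = 5, m = 2, mean_individuals = 9, capacities = c(8L, 12L),
      mean_travel = 15, seed = 5000 + k))
    sol <- init_population(inst, 1, balance_rounds = 0)[[1]]
    ev <- evaluate_events(inst, sol)
    if (!ev$meta$formula_consistent) next
    checked <- checked + 1
    ff <- evaluate_formula(inst, sol)
    expect_equal(ev$objective, ff$objective, tolerance = 1e-12)
    for (i in 1:2) {
      expect_equal(ev$timelines[[i]]$arrival, ff$timelines[[i]]$arrival)
      expect_equal(ev$timelines[[i]]$leave, ff$timelines[[i]]$leave)
    }
  }
  expect_gte(checked, 20)
})

test_that("completion times are the final region returns", {
  inst <- worked_example_instance()
  ev <- evaluate_events(inst, worked_example_solution())
  # v1 ends at area 3 (leave 38.5) + region travel 10; v2 restored leave 39 + 10
  expect_equal(completion_times(ev), c(48.5, 49))
  # single area: arrival + loading + region travel
  inst2 <- one_area_instance(1, 5, t_origin = 7, t_region = 3)
  ev2 <- evaluate_events(inst2, qv_solution(list(1L), list(integer(0))))
  expect_equal(completion_times(ev2), 7 + 3)
})
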