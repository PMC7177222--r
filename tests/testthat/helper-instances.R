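# Shared fixtures and independent oracles used across the test files.

# tiny enumerable instance family: 3 areas, 2 vehicles of capacity 10/15,
# counts around 8 so some areas exceed c_min and may be split
tiny_config <- function(seed) {
  generator_config(n = 3, m = 2, mean_individuals = 8,
                   capacities = c(10L, 15L), mean_travel = 20, seed = seed)
}

# mid-sized feasibility workhorse
small_instance <- function(seed, n = 8, m = 3) {
  generate_instance(generator_config(n = n, m = m, mean_individuals = 10,
                                     mean_capacity = 10, seed = seed))
}

# single-area single-vehicle instance with hand-set times
one_area_instance <- function(b, cap, t_origin = 4, t_region = 5, dt = 0.5) {
  qv_instance(
    areas = data.frame(id = 1L, individuals = as.integer(b)),
    vehicles = data.frame(id = 1L, capacity = as.integer(cap)),
    times = list(origin_to_area = matrix(t_origin, 1, 1),
                 between_areas = array(0, c(1, 1, 1)),
                 area_to_region = matrix(t_region, 1, 1),
                 loading_interval = matrix(dt, 1, 1)))
}

# ---- independent oracles ----------------------------------------------------

# per-individual enumeration of one vehicle serving one area alone, under
# the model's loading clock: the i-th individual boards at
# arrival + (i-1)*dt + 2*t_region*(round trips completed before them).
# Round 1 holds min(b, c_on) individuals, later rounds hold c_i.  Returns
# the summed load times, the final leave time (last individual's load
# time), and the number of completed round trips.
enumerate_single_visit <- function(b, c_on, c_i, arrival, dt, t_region) {
  stopifnot(c_on <= c_i, b >= 1)
  i <- seq_len(b)
  round_of <- ifelse(i <= c_on, 1L, 1L + ceiling((i - c_on) / c_i))
  load_times <- arrival + (i - 1) * dt + 2 * t_region * (round_of - 1L)
  list(exposure = sum(load_times), leave = load_times[b],
       trips = round_of[b] - 1L)
}

# all permutations of an integer vector (small n only)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# exhaustive optimum over every feasible (routes, directions) pair of a
# 2-vehicle instance: each area is assigned to vehicle 1, vehicle 2, or
# (when the rules allow) both; all route orders and direction-bit vectors
# are enumerated and evaluated with the event evaluator.
enumerate_optimum <- function(instance) {
  n <- n_areas(instance)
  m <- n_vehicles(instance)
  stopifnot(m == 2L)
  b <- instance$areas$individuals
  cmin <- min_capacity(instance)
  kcap <- max_vehicles_for_area(b, cmin)
  choices <- lapply(seq_len(n), function(a) {
    ch <- list(1L, 2L)
    if (b[a] > cmin && kcap[a] >= 2L) ch <- c(ch, list(c(1L, 2L)))
    ch
  })
  best <- Inf
  best_sol <- NULL
  grid <- expand.grid(lapply(choices, seq_along))
  for (g in seq_len(nrow(grid))) {
    assign <- lapply(seq_len(n), function(a) choices[[a]][[grid[g, a]]])
    set1 <- which(vapply(assign, function(x) 1L %in% x, logical(1)))
    set2 <- which(vapply(assign, function(x) 2L %in% x, logical(1)))
    for (p1 in perms(set1)) {
      for (p2 in perms(set2)) {
        nb1 <- max(length(p1) - 1L, 0L)
        nb2 <- max(length(p2) - 1L, 0L)
        ygrid <- expand.grid(rep(list(0:1), nb1 + nb2))
        if (nb1 + nb2 == 0L) ygrid <- data.frame(row.names = 1)
        for (yg in seq_len(nrow(ygrid))) {
          yy <- as.integer(unlist(ygrid[yg, , drop = TRUE]))
          sol <- qv_solution(list(p1, p2),
                             list(head(yy, nb1), tail(yy, nb2)))
          o <- evaluate_events(instance, sol, check = FALSE,
                               detail = FALSE)$objective
          if (o < best) {
            best <- o
            best_sol <- sol
          }
        }
      }
    }
  }
  list(objective = best, solution = best_sol)
}
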