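# Construction and repair of feasible solutions: random separator-encoded
# sequences, probabilistic assignment of big areas to additional vehicles,
# the loading-rate direction heuristic, and completion-time balancing.

#' Random route sequences
#'
#' Draws a uniformly random permutation of all areas and splits it into m
#' routes by choosing m - 1 distinct separator positions among the n + 1
#' gaps of the permutation (so at most the first and last route can be
#' empty).  Every area appears in exactly one route.
#'
#' @param instance a `qv_instance`.
#' @return A list of m integer route vectors.
#' @export
random_sequences <- function(instance) {
  n <- n_areas(instance)
  m <- n_vehicles(instance)
  if (m - 1L > n + 1L)
    stop("more vehicles than the separator encoding can accommodate (m > n + 2)")
  perm <- sample.int(n)
  if (m == 1L) return(list(perm))
  cuts <- sort(sample.int(n + 1L, m - 1L) - 1L)  # gap positions in 0..n
  bounds <- c(0L, cuts, n)
  lapply(seq_len(m), function(i) {
    lo <- bounds[i] + 1L
    hi <- bounds[i + 1L]
    if (lo > hi) integer(0) else perm[lo:hi]
  })
}

# number of routes containing each area
route_counts <- function(routes, n) {
  cnt <- integer(n)
  for (r in routes) for (a in unique(r)) cnt[a] <- cnt[a] + 1L
  cnt
}

#' Assign under-capacitated areas to additional vehicles
#'
#' For each area whose individual count exceeds the total capacity of the
#' vehicles currently assigned to it, the area is appended to the route of
#' another eligible vehicle with probability `(b_j - c(j)) / b_j` (the
#' uncovered demand fraction); the draw is repeated until the demand is
#' covered, the vehicle cap binds, or no eligible vehicle remains -- any
#' residual demand is absorbed by shuttling.  Eligible vehicles are those
#' not already assigned the area and
#' whose addition keeps the area within its vehicle cap; areas no larger
#' than the minimum fleet capacity are never split.  The additional vehicle
#' is chosen uniformly at random among the eligible ones and the area is
#' appended at the end of its route.
#'
#' @param routes list of m route vectors covering every area once.
#' @param instance a `qv_instance`.
#' @return The augmented route list; always rule-feasible.
#' @export
assign_additional_vehicles <- function(routes, instance) {
  b <- instance$areas$individuals
  cvec <- instance$vehicles$capacity
  n <- n_areas(instance)
  m <- n_vehicles(instance)
  cmin <- min_capacity(instance)
  kcap <- max_vehicles_for_area(b, cmin)
  cnt <- route_counts(routes, n)
  cap_assigned <- numeric(n)
  for (i in seq_len(m)) for (a in routes[[i]]) cap_assigned[a] <- cap_assigned[a] + cvec[i]
  has <- matrix(FALSE, m, n)
  for (i in seq_len(m)) has[i, routes[[i]]] <- TRUE

  for (a in seq_len(n)) {
    routes <- draw_extra_vehicles(routes, a, instance, cmin, kcap,
                                  cnt, cap_assigned, has)
    upd <- attr(routes, "state")
    cnt <- upd$cnt; cap_assigned <- upd$cap_assigned; has <- upd$has
    attr(routes, "state") <- NULL
  }
  routes
}

# probabilistic extra-vehicle loop for one area: each iteration assigns the
# area to another eligible vehicle with probability equal to the uncovered
# demand fraction; the recursion runs until the demand is covered, the
# vehicle cap binds, or no eligible vehicle remains (a failed draw retries,
# so the probability paces the race between areas for scarce vehicles
# rather than cutting assignment short).
draw_extra_vehicles <- function(routes, a, instance, cmin, kcap,
                                cnt, cap_assigned, has) {
  b <- instance$areas$individuals
  cvec <- instance$vehicles$capacity
  if (b[a] > cmin) {  # R1: never split small areas
    tries <- 0L
    while (cap_assigned[a] < b[a] && cnt[a] < kcap[a] && tries < 1000L) {
      tries <- tries + 1L
      p <- (b[a] - cap_assigned[a]) / b[a]
      if (stats::runif(1) >= p) next
      eligible <- which(!has[, a])
      if (length(eligible) == 0L) break
      pick <- if (length(eligible) == 1L) eligible else
        eligible[sample.int(length(eligible), 1L)]
      routes[[pick]] <- c(routes[[pick]], a)
      has[pick, a] <- TRUE
      cnt[a] <- cnt[a] + 1L
      cap_assigned[a] <- cap_assigned[a] + cvec[pick]
    }
  }
  attr(routes, "state") <- list(cnt = cnt, cap_assigned = cap_assigned, has = has)
  routes
}

#' Generate direction bits by the loading-rate heuristic
#'
#' Simulates each vehicle's load along its route (vehicles in index order,
#' sharing a running count of untaken individuals per area) and, after each
#' non-final area, sets the return-to-region bit to 1 with probability
#' equal to the vehicle's loading rate `load / c_i`; a full vehicle returns
#' with certainty.  An area assigned to this vehicle alone is taken in
#' full (the vehicle shuttles), leaving the vehicle with the final-round
#' remainder on board.
#'
#' @param routes list of m route vectors.
#' @param instance a `qv_instance`.
#' @param deterministic if TRUE, no random draws: the bit is 1 iff the
#'   loading rate is at least 0.5 (used inside [balance_solution()] so its
#'   improvement contract is deterministic).
#' @param prev optional previous direction bits (list of m vectors).
#' @param keep_prefix integer vector (length m): how many leading bits of
#'   each vehicle to copy from `prev` instead of regenerating (used to
#'   preserve decisions on unchanged route prefixes).
#' @param area_bits optional list of m integer vectors of length n
#'   (NA where absent): a direction decision previously made by the same
#'   vehicle after the same area, reused outside the kept prefix (a full
#'   vehicle still returns with certainty).  Used by the search operators
#'   so refined decisions survive route rearrangements.
#' @return A list of m 0/1 integer vectors.
#' @export
generate_directions <- function(routes, instance, deterministic = FALSE,
                                prev = NULL, keep_prefix = NULL,
                                area_bits = NULL) {
  b <- as.integer(instance$areas$individuals)
  cvec <- as.integer(instance$vehicles$capacity)
  n <- length(b)
  m <- length(routes)
  if (is.null(keep_prefix)) keep_prefix <- integer(m)
  cnt <- route_counts(routes, n)
  remaining <- b
  dirs <- vector("list", m)
  for (i in seq_len(m)) {
    r <- routes[[i]]
    ci <- cvec[i]
    load <- 0L
    nb <- max(length(r) - 1L, 0L)
    y <- integer(nb)
    for (t in seq_along(r)) {
      a <- r[t]
      room <- ci - load
      if (cnt[a] == 1L && remaining[a] > room) {
        # sole server: shuttles until empty; final-round remainder on board
        lr <- (remaining[a] - room) %% ci
        load <- if (lr == 0L) ci else lr
        remaining[a] <- 0L
      } else {
        take <- min(room, remaining[a])
        remaining[a] <- remaining[a] - take
        load <- load + take
      }
      if (t <= nb) {
        if (t <= keep_prefix[i] && !is.null(prev) && t <= length(prev[[i]])) {
          y[t] <- prev[[i]][t]
        } else if (load == ci) {
          y[t] <- 1L
        } else if (!is.null(area_bits) && !is.na(area_bits[[i]][a])) {
          y[t] <- area_bits[[i]][a]
        } else {
          p <- load / ci
          y[t] <- if (deterministic) as.integer(p >= 0.5) else
            as.integer(stats::runif(1) < p)
        }
        if (y[t] == 1L) load <- 0L
      }
    }
    dirs[[i]] <- y
  }
  dirs
}

# longest common prefix of two integer vectors
common_prefix <- function(a, b) {
  k <- min(length(a), length(b))
  if (k == 0L) return(0L)
  neq <- which(a[seq_len(k)] != b[seq_len(k)])
  if (length(neq) == 0L) k else neq[1L] - 1L
}

#' Repair a solution to rule feasibility
#'
#' Applied to routes that may contain within-route duplicates, oversharing,
#' or coverage gaps (e.g. after a sequence reversal that crosses route
#' separators).  Removes duplicates keeping the first occurrence; enforces
#' the one-vehicle rule for small areas and the vehicle cap by deleting
#' surplus copies, keeping the copies on the vehicles with the most spare
#' capacity (capacity minus the vehicle's expected share of its assigned
#' demand; ties broken by lower vehicle index); restores coverage by
#' appending each missing area to the vehicle with the minimum completion
#' time; gives areas that lost a copy to duplicate removal (relative to
#' `ref_routes`) a fresh probabilistic extra-vehicle draw, so route
#' rearrangements do not steadily erode multi-vehicle sharing; and
#' regenerates direction bits for every changed route suffix by the
#' loading-rate heuristic.  A rule-feasible input passes through with its
#' routes unchanged.  The result always passes [check_rules()].
#'
#' @param solution a `qv_solution` (or bare list with `routes` and
#'   `directions`), possibly rule-infeasible.
#' @param instance a `qv_instance`.
#' @param deterministic passed to [generate_directions()] for regenerated
#'   bits.
#' @param ref_routes the routes that `solution$directions` belong to
#'   (defaults to `solution$routes`); direction bits are retained only on
#'   unchanged prefixes relative to these.
#' @return A feasible `qv_solution`.
#' @export
repair_solution <- function(solution, instance, deterministic = FALSE,
                            ref_routes = solution$routes) {
  b <- instance$areas$individuals
  cvec <- instance$vehicles$capacity
  n <- n_areas(instance)
  m <- n_vehicles(instance)
  cmin <- min_capacity(instance)
  allowed <- ifelse(b <= cmin, 1L, max_vehicles_for_area(b, cmin))

  routes <- lapply(solution$routes, function(r) r[!duplicated(r)])
  cnt <- route_counts(routes, n)

  over <- which(cnt > allowed)
  if (length(over) > 0L) {
    share <- vapply(seq_len(m), function(i) {
      r <- routes[[i]]
      if (length(r) == 0L) 0 else sum(b[r] / cnt[r])
    }, numeric(1))
    spare <- cvec - share
    for (a in over) {
      holders <- which(vapply(routes, function(r) a %in% r, logical(1)))
      keep <- holders[order(-spare[holders], holders)][seq_len(allowed[a])]
      drop <- setdiff(holders, keep)
      for (i in drop) {
        routes[[i]] <- routes[[i]][routes[[i]] != a]
        spare[i] <- spare[i] + b[a] / cnt[a]
      }
      cnt[a] <- allowed[a]
    }
  }

  missing <- which(cnt == 0L)
  for (a in missing) {
    tmp <- qv_solution(routes, generate_directions(routes, instance,
                                                   deterministic = TRUE))
    comp <- eval_events_core(instance, tmp, detail = FALSE, partial = TRUE)$completion
    pick <- which.min(comp)
    routes[[pick]] <- c(routes[[pick]], a)
    cnt[a] <- 1L
  }

  # areas that lost a copy to duplicate removal (relative to the reference
  # routes) get the probabilistic extra-vehicle draw again, so rearranging
  # moves do not steadily erode multi-vehicle sharing
  lost <- which(cnt < route_counts(ref_routes, n) &
                  b > cmin & cnt < max_vehicles_for_area(b, cmin))
  if (length(lost) > 0L) {
    kj <- max_vehicles_for_area(b, cmin)
    cap_assigned <- numeric(n)
    has <- matrix(FALSE, m, n)
    for (i in seq_len(m)) {
      for (a2 in routes[[i]]) cap_assigned[a2] <- cap_assigned[a2] + cvec[i]
      has[i, routes[[i]]] <- TRUE
    }
    for (a2 in lost) {
      routes <- draw_extra_vehicles(routes, a2, instance, cmin, kj,
                                    cnt, cap_assigned, has)
      upd <- attr(routes, "state")
      cnt <- upd$cnt; cap_assigned <- upd$cap_assigned; has <- upd$has
      attr(routes, "state") <- NULL
    }
  }

  keep_prefix <- vapply(seq_len(m), function(i)
    max(common_prefix(routes[[i]], ref_routes[[i]]) - 1L, 0L), integer(1))
  area_bits <- lapply(seq_len(m), function(i) {
    ab <- rep(NA_integer_, n)
    r0 <- ref_routes[[i]]
    y0 <- solution$directions[[i]]
    k <- min(length(r0) - 1L, length(y0))
    if (k >= 1L) ab[r0[seq_len(k)]] <- y0[seq_len(k)]
    ab
  })
  dirs <- generate_directions(routes, instance, deterministic = deterministic,
                              prev = solution$directions,
                              keep_prefix = keep_prefix,
                              area_bits = area_bits)
  qv_solution(routes, dirs)
}

#' Balance routes by completion time
#'
#' Greedy improvement pass: repeatedly identify the vehicles with the
#' maximum and minimum completion times and try to relocate each area of
#' the busiest route into every position of the most idle route (skipping
#' relocations that would duplicate an area within the target route);
#' direction bits of the two changed routes are regenerated
#' deterministically by the loading-rate heuristic.  The single relocation
#' that most reduces the objective is applied; the pass stops when no
#' relocation improves or after `max_rounds` rounds.  The returned
#' objective never exceeds the input's.
#'
#' @param solution a feasible `qv_solution`.
#' @param instance a `qv_instance`.
#' @param max_rounds maximum relocation rounds (default: the number of
#'   areas).
#' @return A feasible `qv_solution` with objective <= the input's; the
#'   attribute `"objective"` carries its evaluated objective.
#' @export
balance_solution <- function(solution, instance, max_rounds = n_areas(instance)) {
  if (max_rounds <= 0L) return(solution)
  ev <- eval_events_core(instance, solution, detail = FALSE)
  cur_obj <- ev$objective
  input_obj <- cur_obj
  m <- n_vehicles(instance)
  for (round in seq_len(max_rounds)) {
    comp <- ev$completion
    vmax <- which.max(comp)
    vmin <- which.min(comp)
    if (vmax == vmin || length(solution$routes[[vmax]]) == 0L) break
    rmax <- solution$routes[[vmax]]
    rmin <- solution$routes[[vmin]]
    best <- NULL
    best_obj <- cur_obj
    for (a in rmax) {
      if (a %in% rmin) next
      src <- rmax[rmax != a]
      for (p in 0:length(rmin)) {
        dst <- append(rmin, a, after = p)
        routes2 <- solution$routes
        routes2[[vmax]] <- src
        routes2[[vmin]] <- dst
        keep_prefix <- vapply(seq_len(m), function(i)
          if (i == vmax || i == vmin)
            max(common_prefix(routes2[[i]], solution$routes[[i]]) - 1L, 0L)
          else length(solution$directions[[i]]), integer(1))
        dirs2 <- generate_directions(routes2, instance, deterministic = TRUE,
                                     prev = solution$directions,
                                     keep_prefix = keep_prefix)
        cand <- qv_solution(routes2, dirs2)
        ev2 <- eval_events_core(instance, cand, detail = FALSE)
        if (ev2$objective < best_obj) {
          best <- cand
          best_obj <- ev2$objective
          best_ev <- ev2
        }
      }
    }
    if (is.null(best)) break
    solution <- best
    cur_obj <- best_obj
    ev <- best_ev
  }
  stopifnot(cur_obj <= input_obj)
  attr(solution, "objective") <- cur_obj
  solution
}

#' Build a random initial population
#'
#' Each member is constructed by drawing random route sequences, assigning
#' big areas to additional vehicles, generating direction bits by the
#' loading-rate heuristic, and applying one balancing pass.  All members
#' are rule-feasible.
#'
#' @param instance a `qv_instance`.
#' @param size population size (>= 1).
#' @param balance_rounds balancing rounds applied to each member.
#' @return List of `qv_solution` objects.
#' @export
init_population <- function(instance, size, balance_rounds = n_areas(instance)) {
  stopifnot(size >= 1)
  lapply(seq_len(size), function(k) {
    routes <- random_sequences(instance)
    routes <- assign_additional_vehicles(routes, instance)
    dirs <- generate_directions(routes, instance)
    balance_solution(qv_solution(routes, dirs), instance,
                     max_rounds = balance_rounds)
  })
}
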