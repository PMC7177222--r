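# Closed-form pieces of the exposure-time recursion, plus the two full
# evaluators.  `evaluate_formula()` implements the recursive closed forms
# with the multi-vehicle coordination procedure; `evaluate_events()` is an
# independent discrete-event simulation that loads individuals one by one
# and sums their load times.  The two agree (objective and all arrival /
# leave times) whenever every single-vehicle visit either fits in the
# vehicle's residual capacity or starts from a freshly reloaded vehicle
# with a non-exact final round; see the methods vignette.

#' Round trips at a vehicle's first area
#'
#' Number of times a vehicle shuttles between its first area and the
#' isolated region when it arrives empty with capacity `c_i`:
#' `floor(b / c_i)`.
#'
#' @param b individuals in the area (>= 1).
#' @param c_i vehicle capacity (>= 1).
#' @return Nonnegative integer (vectorized).
#' @export
round_trips_first <- function(b, c_i) {
  stopifnot(all(b >= 1), all(c_i >= 1))
  as.integer(b %/% c_i)
}

#' Round trips at a subsequent area
#'
#' Shuttle count for an area visited with residual capacity `c_remaining`
#' after the previous direction decision `y_prev`: zero when the load fits,
#' `1 + floor((b - c_remaining) / c_i)` when it does not, and
#' `floor(b / c_i)` when the vehicle unloaded at the region on the way
#' (so it arrives with full capacity).
#'
#' @param b individuals in the area.
#' @param c_remaining residual capacity on arrival (0..c_i).
#' @param c_i full vehicle capacity.
#' @param y_prev previous direction bit (1 = came via the region).
#' @return Nonnegative integer.
#' @export
round_trips_next <- function(b, c_remaining, c_i, y_prev) {
  if (any(c_remaining > c_i)) stop("c_remaining exceeds vehicle capacity")
  if (any(c_remaining < 0)) stop("c_remaining must be nonnegative")
  ifelse(y_prev == 1L, b %/% c_i,
         ifelse(b <= c_remaining, 0L, 1L + (b - c_remaining) %/% c_i))
}

#' Final leave time at an area
#'
#' If the whole area fits in the arriving capacity the vehicle leaves after
#' loading all `b` individuals at `dt` intervals; otherwise `k` round trips
#' to the region (each of duration `2 * t_region`) are added.
#'
#' @param arrival first arrival time at the area.
#' @param b individuals in the area (>= 1).
#' @param c_on_arrival residual capacity on arrival.
#' @param k shuttle count (see [round_trips_next()]).
#' @param t_region one-way travel time area <-> region.
#' @param dt loading interval at the area.
#' @return Leave time.
#' @export
leave_time <- function(arrival, b, c_on_arrival, k, t_region, dt) {
  stopifnot(all(b >= 1))
  ifelse(b <= c_on_arrival,
         arrival + (b - 1) * dt,
         arrival + 2 * k * t_region + (b - 1) * dt)
}

#' Arrival time at the next area
#'
#' Direct travel when the direction bit is 0; via the region (unload, then
#' drive out) when it is 1.
#'
#' @param leave leave time at the current area.
#' @param y_prev direction bit after the current area.
#' @param t_between direct travel time to the next area.
#' @param t_region_cur current area to region.
#' @param t_region_next region to next area.
#' @return Arrival time at the next area.
#' @export
next_arrival <- function(leave, y_prev, t_between, t_region_cur, t_region_next) {
  ifelse(y_prev == 1L, leave + t_region_cur + t_region_next, leave + t_between)
}

#' Residual capacity on arrival at the next area
#'
#' After unloading at the region (bit 1) the vehicle is at full capacity.
#' Travelling directly (bit 0) it keeps its load: the residual is
#' `c_on_arrival - b` when the area fitted, and otherwise
#' `c_i - ((b - c_on_arrival) mod c_i)` -- the spare room after the final
#' shuttle round, with an exact final round mapping to full capacity
#' `c_i` (the vehicle has unloaded everything at the region).
#'
#' @inheritParams leave_time
#' @param c_i full vehicle capacity.
#' @param y_prev direction bit after the area.
#' @return Residual capacity in `[0, c_i]`.
#' @export
next_capacity <- function(c_on_arrival, b, c_i, y_prev) {
  res <- ifelse(y_prev == 1L, c_i,
                ifelse(b <= c_on_arrival, c_on_arrival - b,
                       c_i - (b - c_on_arrival) %% c_i))
  if (any(res < 0 | res > c_i)) stop("internal error: capacity out of range")
  res
}

#' Exposure total of an area served by a single vehicle
#'
#' Sum of exposure durations of the area's individuals when one vehicle
#' loads all of them, possibly over `k` shuttle rounds: the first-round term
#' `b * arrival + b * (b - 1) / 2 * dt` plus, when shuttling is needed,
#' `k * t_region * (2 * b - (k + 1) * c_on_arrival)` for the round-trip
#' waiting of later rounds.  The shuttle term is exact when the vehicle
#' arrives at full capacity (`c_on_arrival == c_i`).
#'
#' @inheritParams leave_time
#' @return Exposure in minutes x persons.
#' @export
area_exposure <- function(b, c_on_arrival, arrival, dt, k, t_region) {
  stopifnot(all(b >= 1))
  base <- b * arrival + b * (b - 1) / 2 * dt
  ifelse(b <= c_on_arrival, base,
         base + k * t_region * (2 * b - (k + 1) * c_on_arrival))
}

#' Exposure increment of one loading round at a shared area
#'
#' When several vehicles serve one area, each round of `b_loaded`
#' individuals boarding from time `arrival` at `dt` intervals contributes
#' `b_loaded * arrival + b_loaded * (b_loaded - 1) / 2 * dt`.
#'
#' @param b_loaded individuals loaded this round (>= 1).
#' @param arrival round start time.
#' @param dt loading interval.
#' @return Exposure increment.
#' @export
first_round_exposure <- function(b_loaded, arrival, dt) {
  stopifnot(all(b_loaded >= 1))
  b_loaded * arrival + b_loaded * (b_loaded - 1) / 2 * dt
}

#' Provisional re-arrival after a shuttle round at a shared area
#'
#' A vehicle that fills up at a shared area departs when its last
#' individual boards, unloads at the region, and is provisionally scheduled
#' back at the same area: `arrival + (b_loaded - 1) * dt + 2 * t_region`.
#'
#' @param arrival round start time.
#' @param b_loaded individuals loaded this round (>= 1).
#' @param dt loading interval.
#' @param t_region one-way area <-> region travel time for this vehicle.
#' @return Provisional next arrival at the same area.
#' @export
shuttle_arrival_update <- function(arrival, b_loaded, dt, t_region) {
  stopifnot(all(b_loaded >= 1))
  arrival + (b_loaded - 1) * dt + 2 * t_region
}

# ---- shared helpers ---------------------------------------------------------

# package-internal counter of full-solution evaluations (used by the solver's
# evaluation-count budget; every core invocation counts, including the
# bookkeeping evaluations done inside repair and balance)
.qv_state <- new.env(parent = emptyenv())
.qv_state$evals <- 0

evaluation_count <- function() .qv_state$evals

assert_evaluable <- function(instance, solution) {
  rep <- check_rules(instance, solution)
  if (nrow(rep) > 0L)
    stop(sprintf("solution violates rule %s: %s", rep$rule[1], rep$message[1]))
}

empty_result <- function(mode, n, m) {
  structure(list(objective = 0, area_exposure = numeric(n),
                 timelines = rep(list(NULL), m), completion = numeric(m),
                 meta = list(evaluator = mode, formula_consistent = TRUE)),
            class = "qv_evaluation")
}

#' @export
print.qv_evaluation <- function(x, ...) {
  total_b <- sum(vapply(x$timelines, function(tl)
    if (is.null(tl)) 0 else sum(tl$loaded), numeric(1)))
  cat(sprintf("qv_evaluation (%s): objective %.4g minutes x persons", x$meta$evaluator,
              x$objective))
  if (total_b > 0)
    cat(sprintf(" (%.4g min / individual)", x$objective / total_b))
  cat("\n")
  invisible(x)
}

#' Per-vehicle completion times
#'
#' The time each vehicle finally returns to the isolated region after its
#' last actually visited area (leave time at the last visit plus that
#' area's region travel time); 0 for vehicles that never load anyone.
#'
#' @param result a `qv_evaluation` from [evaluate_events()] or
#'   [evaluate_formula()].
#' @return Numeric vector, one entry per vehicle.
#' @export
completion_times <- function(result) {
  stopifnot(inherits(result, "qv_evaluation"))
  result$completion
}

# ---- event-simulation evaluator --------------------------------------------

# Core of the discrete-event evaluator.  detail = FALSE skips timeline
# bookkeeping (used in solver hot loops); partial = TRUE permits solutions
# that do not cover every area (used to compute completion times of
# intermediate solutions during repair).
eval_events_core <- function(instance, solution, detail = TRUE, partial = FALSE) {
  .qv_state$evals <- .qv_state$evals + 1
  b <- as.integer(instance$areas$individuals)
  cvec <- as.integer(instance$vehicles$capacity)
  tor <- instance$times$origin_to_area
  tb <- instance$times$between_areas
  tr <- instance$times$area_to_region
  dtm <- instance$times$loading_interval
  n <- length(b); m <- length(cvec)
  routes <- solution$routes
  dirs <- solution$directions

  cnt <- integer(n)
  for (r in routes) for (a in unique(r)) cnt[a] <- cnt[a] + 1L
  shared <- cnt >= 2L

  rem <- b
  Tj <- numeric(n)
  active <- logical(m); pos <- integer(m); arr <- numeric(m); cap <- integer(m)
  last_area <- integer(m); last_leave <- numeric(m); last_bit <- integer(m)
  hist_area <- integer(m); hist_arr <- numeric(m); hist_q <- integer(m)
  completion <- numeric(m)
  consistent <- TRUE
  rows <- if (detail) vector("list", 4L * (n + m) + 8L) else NULL
  nrow_used <- 0L

  rec <- function(i, a, arrival, leave, cap0, rounds, loaded) {
    nrow_used <<- nrow_used + 1L
    if (nrow_used > length(rows)) rows[[2L * nrow_used]] <<- NULL
    rows[[nrow_used]] <<- c(i, a, arrival, leave, cap0, rounds, loaded)
  }

  advance_from <- function(i, a_from, leave, free_cap, y_eff) {
    r <- routes[[i]]
    j2 <- pos[i] + 1L
    while (j2 <= length(r) && rem[r[j2]] == 0L) j2 <- j2 + 1L
    if (j2 > length(r)) {
      active[i] <<- FALSE
      completion[i] <<- if (a_from == 0L) 0 else leave + tr[i, a_from]
    } else {
      nxt <- r[j2]
      pos[i] <<- j2
      if (a_from == 0L) {
        arr[i] <<- tor[i, nxt]; cap[i] <<- cvec[i]
      } else if (y_eff == 1L) {
        arr[i] <<- leave + tr[i, a_from] + tr[i, nxt]; cap[i] <<- cvec[i]
      } else {
        arr[i] <<- leave + tb[i, a_from, nxt]; cap[i] <<- free_cap
      }
      last_area[i] <<- a_from; last_leave[i] <<- leave; last_bit[i] <<- y_eff
      hist_area[i] <<- 0L
    }
  }

  for (i in seq_len(m)) {
    if (length(routes[[i]]) >= 1L) {
      active[i] <- TRUE; pos[i] <- 1L
      arr[i] <- tor[i, routes[[i]][1L]]; cap[i] <- cvec[i]
      last_area[i] <- 0L
    }
  }

  guard <- 0L
  guard_max <- 10L * (sum(ceiling(b / min(cvec))) + n * m + m + 10L)
  while (any(active)) {
    guard <- guard + 1L
    if (guard > guard_max) stop("internal error: evaluation did not terminate")
    a2 <- arr; a2[!active] <- Inf
    i <- which.min(a2)
    a <- routes[[i]][pos[i]]
    ci <- cvec[i]

    if (rem[a] == 0L) {
      # pending visit to an area emptied by others: cancel it
      if (detail) rec(i, a, arr[i], arr[i], cap[i], 0L, 0L)
      advance_from(i, last_area[i], last_leave[i], cap[i], last_bit[i])
      next
    }

    if (!shared[a]) {
      # single-assigned area: the vehicle shuttles until the area is empty.
      # The i-th individual boards at arrival + (i-1)*dt plus 2*t_region
      # for every completed round trip before them (the model's loading
      # clock keeps running across shuttle rounds).
      a0 <- arr[i]; cap0 <- cap[i]; dt <- dtm[i, a]; trg <- tr[i, a]
      ba <- rem[a]
      if (cap0 == 0L) {                 # degenerate: pure reload trip first
        consistent <- FALSE
        arr[i] <- a0 + 2 * trg; cap[i] <- ci
        next
      }
      idx <- seq_len(ba)
      round_of <- ifelse(idx <= cap0, 1L, 1L + ceiling((idx - cap0) / ci))
      Tj[a] <- Tj[a] + sum(a0 + (idx - 1L) * dt + 2 * trg * (round_of - 1L))
      rounds <- round_of[ba] - 1L
      leave <- a0 + (ba - 1L) * dt + 2 * trg * rounds
      onboard <- if (rounds == 0L) (ci - cap0) + ba else
        ba - cap0 - (rounds - 1L) * ci  # size of the final round
      if (ba > cap0 && !(cap0 == ci && ba %% ci != 0L)) consistent <- FALSE
      rem[a] <- 0L
      if (detail) rec(i, a, a0, leave, cap0, rounds, ba)
      yb <- if (pos[i] < length(routes[[i]])) dirs[[i]][pos[i]] else 1L
      y_eff <- if (onboard == ci) 1L else yb
      if (onboard == ci && yb == 0L) consistent <- FALSE
      advance_from(i, a, leave, ci - onboard, y_eff)
    } else {
      # shared area: one loading round per frontier pick
      dt <- dtm[i, a]; trg <- tr[i, a]
      q <- min(rem[a], cap[i])
      if (q == 0L) {
        consistent <- FALSE
        arr[i] <- arr[i] + 2 * trg; cap[i] <- ci
        next
      }
      a0 <- arr[i]; cap0 <- cap[i]
      Tj[a] <- Tj[a] + sum(a0 + (seq_len(q) - 1L) * dt)
      rem[a] <- rem[a] - q
      onboard <- (ci - cap0) + q
      if (detail) rec(i, a, a0, a0 + (q - 1L) * dt, cap0, 0L, q)
      if (rem[a] > 0L) {
        # vehicle is full: unload at the region and come back provisionally
        hist_area[i] <- a; hist_arr[i] <- a0; hist_q[i] <- q
        arr[i] <- a0 + (q - 1L) * dt + 2 * trg
        cap[i] <- ci
      } else {
        leave <- a0 + (q - 1L) * dt
        yb <- if (pos[i] < length(routes[[i]])) dirs[[i]][pos[i]] else 1L
        y_eff <- if (onboard == ci) 1L else yb
        if (onboard == ci && yb == 0L) consistent <- FALSE
        advance_from(i, a, leave, ci - onboard, y_eff)
        # resolve every other vehicle still headed for the emptied area
        for (i2 in seq_len(m)) {
          if (i2 != i && active[i2] && routes[[i2]][pos[i2]] == a) {
            if (hist_area[i2] == a) {
              leave2 <- hist_arr[i2] + (hist_q[i2] - 1L) * dtm[i2, a]
              advance_from(i2, a, leave2, cvec[i2], 1L)
            } else {
              if (detail) rec(i2, a, arr[i2], arr[i2], cap[i2], 0L, 0L)
              advance_from(i2, last_area[i2], last_leave[i2], cap[i2], last_bit[i2])
            }
          }
        }
      }
    }
  }

  if (!partial && any(rem != 0L)) stop("internal error: unvisited-area deadlock")
  out <- empty_result("events", n, m)
  out$objective <- sum(Tj)
  out$area_exposure <- Tj
  out$completion <- completion
  out$meta$formula_consistent <- consistent
  if (detail) {
    mat <- do.call(rbind, rows[seq_len(nrow_used)])
    out$timelines <- lapply(seq_len(m), function(i) {
      sel <- mat[, 1L] == i
      data.frame(area = as.integer(mat[sel, 2L]), arrival = mat[sel, 3L],
                 leave = mat[sel, 4L],
                 capacity_on_arrival = as.integer(mat[sel, 5L]),
                 rounds = as.integer(mat[sel, 6L]),
                 loaded = as.integer(mat[sel, 7L]))
    })
    total <- sum(vapply(out$timelines, function(tl) sum(tl$loaded), numeric(1)))
    if (!partial && total != sum(b))
      stop("internal error: individuals loaded != total individuals")
  }
  out
}

#' Evaluate a solution by discrete-event simulation
#'
#' Walks every vehicle along its route in a single event-driven timeline:
#' visits are processed in order of arrival time (ties: lower vehicle
#' index); at an area the vehicle loads `min(remaining, residual capacity)`
#' individuals one by one at the area's loading interval (the loading
#' clock keeps running across shuttle rounds, with each completed round
#' trip adding its travel time); a vehicle alone at
#' an area shuttles to the region and back until the area is empty; at an
#' area assigned to several vehicles the earliest arriver loads as much as
#' possible first, later vehicles load what remains, and vehicles headed for
#' an area that empties in the meantime skip it.  A vehicle that fills up
#' must unload at the region before continuing, overriding its direction
#' bit.  Each individual's exposure is the time at which they board; the
#' objective is the sum over all individuals.
#'
#' @param instance a `qv_instance`.
#' @param solution a `qv_solution`; must pass [check_rules()] when
#'   `check = TRUE`.
#' @param check verify rule feasibility first (default TRUE).
#' @param detail build per-vehicle visit timelines (default TRUE); with
#'   `FALSE` only the objective, per-area exposures and completion times
#'   are returned.
#' @return A `qv_evaluation`: list with `objective` (minutes x persons),
#'   `area_exposure` (per area), `timelines` (per vehicle: area, arrival,
#'   leave, capacity_on_arrival, rounds, loaded; cancelled visits appear
#'   with `loaded = 0`), `completion` (per vehicle) and `meta`
#'   (`formula_consistent` flags whether the run stayed in the domain where
#'   the closed-form evaluator is exact).
#' @seealso [evaluate_formula()]
#' @export
#' @examples
#' ev <- evaluate_events(worked_example_instance(), worked_example_solution())
#' ev$area_exposure[1]          # 72.5
#' ev$timelines[[1]]$arrival    # 5, 19.5, 36.5
evaluate_events <- function(instance, solution, check = TRUE, detail = TRUE) {
  if (check) assert_evaluable(instance, solution)
  eval_events_core(instance, solution, detail = detail)
}

# objective-only fast path used by the search modules
objective_events <- function(instance, solution) {
  eval_events_core(instance, solution, detail = FALSE)$objective
}

# ---- closed-form evaluator --------------------------------------------------

eval_formula_core <- function(instance, solution, detail = TRUE, partial = FALSE) {
  .qv_state$evals <- .qv_state$evals + 1
  b <- as.integer(instance$areas$individuals)
  cvec <- as.integer(instance$vehicles$capacity)
  tor <- instance$times$origin_to_area
  tb <- instance$times$between_areas
  tr <- instance$times$area_to_region
  dtm <- instance$times$loading_interval
  n <- length(b); m <- length(cvec)
  routes <- solution$routes
  dirs <- solution$directions

  cnt <- integer(n)
  for (r in routes) for (a in unique(r)) cnt[a] <- cnt[a] + 1L
  shared <- cnt >= 2L

  rem <- b
  Tj <- numeric(n)
  active <- logical(m); pos <- integer(m); arr <- numeric(m); cap <- integer(m)
  last_area <- integer(m); last_leave <- numeric(m); last_bit <- integer(m)
  hist_area <- integer(m); hist_arr <- numeric(m); hist_q <- integer(m)
  completion <- numeric(m)
  rows <- if (detail) vector("list", 4L * (n + m) + 8L) else NULL
  nrow_used <- 0L

  rec <- function(i, a, arrival, leave, cap0, rounds, loaded) {
    nrow_used <<- nrow_used + 1L
    if (nrow_used > length(rows)) rows[[2L * nrow_used]] <<- NULL
    rows[[nrow_used]] <<- c(i, a, arrival, leave, cap0, rounds, loaded)
  }

  advance_from <- function(i, a_from, leave, free_cap, y_eff) {
    r <- routes[[i]]
    j2 <- pos[i] + 1L
    while (j2 <= length(r) && rem[r[j2]] == 0L) j2 <- j2 + 1L
    if (j2 > length(r)) {
      active[i] <<- FALSE
      completion[i] <<- if (a_from == 0L) 0 else leave + tr[i, a_from]
    } else {
      nxt <- r[j2]
      pos[i] <<- j2
      if (a_from == 0L) {
        arr[i] <<- tor[i, nxt]; cap[i] <<- cvec[i]
      } else {
        arr[i] <<- next_arrival(leave, y_eff, tb[i, a_from, nxt],
                                tr[i, a_from], tr[i, nxt])
        cap[i] <<- if (y_eff == 1L) cvec[i] else free_cap
      }
      last_area[i] <<- a_from; last_leave[i] <<- leave; last_bit[i] <<- y_eff
      hist_area[i] <<- 0L
    }
  }

  for (i in seq_len(m)) {
    if (length(routes[[i]]) >= 1L) {
      active[i] <- TRUE; pos[i] <- 1L
      arr[i] <- tor[i, routes[[i]][1L]]; cap[i] <- cvec[i]
      last_area[i] <- 0L
    }
  }

  guard <- 0L
  guard_max <- 10L * (sum(ceiling(b / min(cvec))) + n * m + m + 10L)
  while (any(active)) {
    guard <- guard + 1L
    if (guard > guard_max) stop("internal error: evaluation did not terminate")
    a2 <- arr; a2[!active] <- Inf
    i <- which.min(a2)
    a <- routes[[i]][pos[i]]
    ci <- cvec[i]

    if (rem[a] == 0L) {
      if (detail) rec(i, a, arr[i], arr[i], cap[i], 0L, 0L)
      advance_from(i, last_area[i], last_leave[i], cap[i], last_bit[i])
      next
    }

    if (!shared[a]) {
      # single-assigned area: closed forms for shuttling, leave time, exposure
      a0 <- arr[i]; cap0 <- cap[i]; dt <- dtm[i, a]; trg <- tr[i, a]
      ba <- rem[a]
      if (cap0 == 0L) {                 # degenerate: pure reload trip first
        arr[i] <- a0 + 2 * trg; cap[i] <- ci
        next
      }
      k <- round_trips_next(ba, cap0, ci, 0L)
      leave <- leave_time(a0, ba, cap0, k, trg, dt)
      Tj[a] <- Tj[a] + area_exposure(ba, cap0, a0, dt, k, trg)
      rem[a] <- 0L
      if (detail) rec(i, a, a0, leave, cap0, k, ba)
      yb <- if (pos[i] < length(routes[[i]])) dirs[[i]][pos[i]] else 1L
      free_after <- next_capacity(cap0, ba, ci, 0L)
      advance_from(i, a, leave, free_after, yb)
    } else {
      dt <- dtm[i, a]; trg <- tr[i, a]
      q <- min(rem[a], cap[i])
      if (q == 0L) {
        arr[i] <- arr[i] + 2 * trg; cap[i] <- ci
        next
      }
      a0 <- arr[i]; cap0 <- cap[i]
      Tj[a] <- Tj[a] + first_round_exposure(q, a0, dt)
      rem[a] <- rem[a] - q
      if (detail) rec(i, a, a0, a0 + (q - 1L) * dt, cap0, 0L, q)
      if (rem[a] > 0L) {
        hist_area[i] <- a; hist_arr[i] <- a0; hist_q[i] <- q
        arr[i] <- shuttle_arrival_update(a0, q, dt, trg)
        cap[i] <- ci
      } else {
        leave <- a0 + (q - 1L) * dt
        yb <- if (pos[i] < length(routes[[i]])) dirs[[i]][pos[i]] else 1L
        free_after <- next_capacity(cap0, q, ci, 0L)
        advance_from(i, a, leave, free_after, yb)
        for (i2 in seq_len(m)) {
          if (i2 != i && active[i2] && routes[[i2]][pos[i2]] == a) {
            if (hist_area[i2] == a) {
              leave2 <- hist_arr[i2] + (hist_q[i2] - 1L) * dtm[i2, a]
              advance_from(i2, a, leave2, cvec[i2], 1L)
            } else {
              if (detail) rec(i2, a, arr[i2], arr[i2], cap[i2], 0L, 0L)
              advance_from(i2, last_area[i2], last_leave[i2], cap[i2], last_bit[i2])
            }
          }
        }
      }
    }
  }

  if (!partial && any(rem != 0L)) stop("internal error: unvisited-area deadlock")
  out <- empty_result("formula", n, m)
  out$objective <- sum(Tj)
  out$area_exposure <- Tj
  out$completion <- completion
  if (detail) {
    mat <- do.call(rbind, rows[seq_len(nrow_used)])
    out$timelines <- lapply(seq_len(m), function(i) {
      sel <- mat[, 1L] == i
      data.frame(area = as.integer(mat[sel, 2L]), arrival = mat[sel, 3L],
                 leave = mat[sel, 4L],
                 capacity_on_arrival = as.integer(mat[sel, 5L]),
                 rounds = as.integer(mat[sel, 6L]),
                 loaded = as.integer(mat[sel, 7L]))
    })
  }
  out
}

#' Evaluate a solution by the closed-form recursion
#'
#' Implements the recursive closed forms for arrival times, leave times,
#' residual capacities, shuttle counts and per-area exposure totals,
#' coordinated across vehicles by the frontier procedure: visits are
#' processed in order of arrival time; areas assigned to a single vehicle
#' are served in one step via the closed forms; areas assigned to several
#' vehicles are served in rounds in which the earliest arriver loads up to
#' its residual capacity, provisionally shuttles back if individuals
#' remain, and -- once the area empties -- every other vehicle headed there
#' has its arrival restored to its last actual loading round (or skips the
#' area entirely if it never loaded there).
#'
#' The closed forms for multi-round service are exact when the vehicle
#' starts the area at full capacity and the final round is not exactly
#' full; outside that domain [evaluate_events()] is the reference
#' semantics, and its `meta$formula_consistent` flag reports whether the
#' two are guaranteed to agree on a given solution.
#'
#' @inheritParams evaluate_events
#' @return A `qv_evaluation` (see [evaluate_events()]).
#' @export
#' @examples
#' ev <- evaluate_formula(worked_example_instance(), worked_example_solution())
#' ev$area_exposure[1]   # 72.5
evaluate_formula <- function(instance, solution, check = TRUE, detail = TRUE) {
  if (check) assert_evaluable(instance, solution)
  eval_formula_core(instance, solution, detail = detail)
}
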