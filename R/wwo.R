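# The hybrid water wave optimization + gradual neighborhood search solver.
# A small population of solutions evolves by wavelength-controlled
# subsequence reversals (propagation), best-of-k random swaps on each new
# incumbent (breaking), and a direction-vector refinement that flips one
# return decision and regenerates the later ones (gradual neighborhood
# search).  The population shrinks linearly over the budget.

#' Search configuration for the hybrid solver
#'
#' @param pop_init initial population size (the solver is designed around a
#'   small population, typically 5-10).
#' @param pop_min final population size after linear reduction.
#' @param alpha breaking intensity in (0, 1): each route of a new incumbent
#'   receives `ceiling(alpha * route length)` candidate swaps.
#' @param max_evals evaluation-count budget: the solver stops once this many
#'   full-solution evaluations have been spent (counting construction,
#'   repair and balancing bookkeeping; the running phase completes, so the
#'   total may overshoot slightly, and initialization always completes even
#'   under a smaller budget).  The evaluation-count mode is deterministic
#'   for a fixed seed.
#' @param time_limit optional wall-clock budget in seconds; when both
#'   budgets are given, whichever is exhausted first stops the search.
#' @param seed integer RNG seed.
#' @param debug_invariants if TRUE, every intermediate solution is checked
#'   against the scheduling rules (slow; for development).
#' @return A list of class `qv_search_config`.
#' @export
search_config <- function(pop_init = 8L, pop_min = 3L, alpha = 0.25,
                          max_evals = 50000L, time_limit = NULL, seed = 1L,
                          debug_invariants = FALSE) {
  stopifnot(pop_min >= 1, pop_init >= pop_min, alpha > 0, alpha < 1)
  if (is.null(max_evals) && is.null(time_limit))
    stop("at least one of max_evals and time_limit is required")
  structure(list(pop_init = as.integer(pop_init),
                 pop_min = as.integer(pop_min), alpha = alpha,
                 max_evals = max_evals, time_limit = time_limit,
                 seed = as.integer(seed),
                 debug_invariants = isTRUE(debug_invariants)),
            class = "qv_search_config")
}

#' Wavelengths of a population
#'
#' Each solution's wavelength is its objective value divided by the
#' population's total objective, so wavelengths sum to 1 and worse (larger
#' objective) solutions get larger wavelengths, i.e. mutate more widely.
#'
#' @param objectives vector of positive objective values.
#' @return Numeric vector of the same length summing to 1.
#' @export
wavelengths <- function(objectives) {
  if (any(objectives <= 0)) stop("objectives must be positive")
  objectives / sum(objectives)
}

# encode routes as one string with 0 separators; decode back to m routes
encode_routes <- function(routes) {
  m <- length(routes)
  out <- routes[[1L]]
  if (m > 1L) for (i in 2:m) out <- c(out, 0L, routes[[i]])
  out
}

decode_routes <- function(s, m) {
  seps <- which(s == 0L)
  bounds <- c(0L, seps, length(s) + 1L)
  lapply(seq_len(m), function(i) {
    lo <- bounds[i] + 1L
    hi <- bounds[i + 1L] - 1L
    if (lo > hi) integer(0) else s[lo:hi]
  })
}

#' Propagation: wavelength-controlled subsequence reversals
#'
#' The solution's routes are laid out as a single string with separators
#' between vehicles.  Scanning the string left to right, each area position
#' triggers with probability `lam` a reversal of a slice of random length
#' starting there (so the expected number of reversals is `lam` times the
#' number of area entries).  Each triggered reversal produces its own
#' candidate solution; slices may span separators, which reassigns areas
#' between vehicles, so every candidate is repaired to rule feasibility.
#' Direction bits are kept on unchanged route prefixes, carried along by
#' area identity where an area stays in the same vehicle's route, and
#' regenerated (deterministically) elsewhere.  The best resulting
#' candidate is returned; the caller replaces the original only if the
#' candidate is strictly better.
#'
#' @param solution a feasible `qv_solution`.
#' @param lam wavelength in (0, 1].
#' @param instance a `qv_instance`.
#' @return The best candidate `qv_solution`, with attributes
#'   `"objective"` (its evaluated objective, absent when no reversal
#'   triggered and the input is returned unchanged) and `"reversals"`
#'   (the number of triggered reversals).
#' @export
propagate <- function(solution, lam, instance) {
  stopifnot(lam > 0, lam <= 1)
  s <- encode_routes(solution$routes)
  L <- length(s)
  m <- length(solution$routes)
  nrev <- 0L
  best <- NULL
  best_obj <- Inf
  eval_string <- function(s2) {
    cand <- repair_solution(
      list(routes = decode_routes(s2, m),
           directions = solution$directions),
      instance, deterministic = TRUE, ref_routes = solution$routes)
    o <- objective_events(instance, cand)
    if (o < best_obj) {
      best <<- cand
      best_obj <<- o
    }
  }
  s_all <- s
  for (d in seq_len(L)) {
    if (s[d] != 0L && stats::runif(1) < lam) {
      nrev <- nrev + 1L
      len <- sample.int(L - d + 1L, 1L)
      if (len == 1L) next  # identity reversal: candidate equals the parent
      s2 <- s
      idx <- d:(d + len - 1L)
      s2[idx] <- s2[rev(idx)]
      s_all[idx] <- s_all[rev(idx)]
      eval_string(s2)
    }
  }
  # the joint application of all triggered reversals explores a larger
  # jump of the same expected extent, giving stuck solutions an escape
  if (nrev > 1L && !identical(s_all, s)) eval_string(s_all)
  if (is.null(best)) {
    best <- solution
  } else {
    attr(best, "objective") <- best_obj
  }
  attr(best, "reversals") <- nrev
  best
}

#' Breaking: local swap search on a new incumbent
#'
#' For each route of at least two areas, `ceiling(alpha * route length)`
#' candidate solutions are generated, each swapping two randomly chosen
#' positions of the route (direction bits unchanged -- a swap preserves all
#' route lengths).  The best candidate is adopted only if it strictly
#' decreases the objective; routes are processed in index order with
#' improvements accumulating.
#'
#' @param solution the incumbent `qv_solution`.
#' @param alpha breaking intensity in (0, 1).
#' @param instance a `qv_instance`.
#' @return A feasible `qv_solution` with attribute `"objective"`; its
#'   objective never exceeds the input's.
#' @export
breaking <- function(solution, alpha, instance) {
  stopifnot(alpha > 0, alpha < 1)
  obj <- objective_events(instance, solution)
  for (i in seq_along(solution$routes)) {
    r <- solution$routes[[i]]
    ni <- length(r)
    if (ni < 2L) next
    ns <- ceiling(alpha * ni)
    best_cand <- NULL
    best_obj <- obj
    for (s in seq_len(ns)) {
      pq <- sample.int(ni, 2L)
      r2 <- r
      r2[pq] <- r2[rev(pq)]
      cand <- solution
      cand$routes[[i]] <- r2
      o <- objective_events(instance, cand)
      if (o < best_obj) {
        best_cand <- cand
        best_obj <- o
      }
    }
    if (!is.null(best_cand)) {
      solution <- best_cand
      obj <- best_obj
    }
  }
  attr(solution, "objective") <- obj
  solution
}

# heuristic on-board load after each visited area (same load model as
# generate_directions, with the current direction bits applied)
heuristic_loads <- function(routes, dirs, instance) {
  b <- as.integer(instance$areas$individuals)
  cvec <- as.integer(instance$vehicles$capacity)
  cnt <- route_counts(routes, length(b))
  remaining <- b
  out <- vector("list", length(routes))
  for (i in seq_along(routes)) {
    r <- routes[[i]]
    ci <- cvec[i]
    load <- 0L
    loads <- integer(length(r))
    for (t in seq_along(r)) {
      a <- r[t]
      room <- ci - load
      if (cnt[a] == 1L && remaining[a] > room) {
        lr <- (remaining[a] - room) %% ci
        load <- if (lr == 0L) ci else lr
        remaining[a] <- 0L
      } else {
        take <- min(room, remaining[a])
        remaining[a] <- remaining[a] - take
        load <- load + take
      }
      loads[t] <- load
      if (t < length(r) && dirs[[i]][t] == 1L) load <- 0L
    }
    out[[i]] <- loads
  }
  out
}

#' Gradual neighborhood search on the direction vector
#'
#' For each vehicle in turn, builds one neighbor per route position by
#' flipping that position's return-to-region bit (a bit forced to 1 by a
#' full vehicle is not flipped) and regenerating all later bits of that
#' vehicle by the loading-rate heuristic.  The best neighbor replaces the
#' vehicle's direction vector only if it strictly improves the objective,
#' so the returned objective never exceeds the input's.
#'
#' @param solution a feasible `qv_solution`.
#' @param instance a `qv_instance`.
#' @return A feasible `qv_solution` with attribute `"objective"`.
#' @export
gradual_neighborhood_search <- function(solution, instance) {
  obj <- objective_events(instance, solution)
  cvec <- instance$vehicles$capacity
  m <- length(solution$routes)
  kp_full <- vapply(solution$directions, length, integer(1))
  for (i in seq_len(m)) {
    ni <- length(solution$routes[[i]])
    if (ni < 2L) next
    loads <- heuristic_loads(solution$routes, solution$directions, instance)
    best_cand <- NULL
    best_obj <- obj
    for (j in seq_len(ni - 1L)) {
      cur <- solution$directions[[i]][j]
      if (cur == 1L && loads[[i]][j] == cvec[i]) next  # full: must unload
      prev2 <- solution$directions
      prev2[[i]][j] <- 1L - cur
      kp <- kp_full
      kp[i] <- j
      dirs2 <- generate_directions(solution$routes, instance,
                                   prev = prev2, keep_prefix = kp)
      cand <- qv_solution(solution$routes, dirs2)
      o <- objective_events(instance, cand)
      if (o < best_obj) {
        best_cand <- cand
        best_obj <- o
      }
    }
    if (!is.null(best_cand)) {
      solution <- best_cand
      obj <- best_obj
    }
  }
  attr(solution, "objective") <- obj
  solution
}

#' Linear population reduction
#'
#' Shrinks the population from `pop_init` members at progress 0 to
#' `pop_min` members at progress 1: the target size is
#' `round(pop_init - (pop_init - pop_min) * progress)` and the worst
#' members are dropped first, so the incumbent best member is never
#' removed.
#'
#' @param population list with `members` (solutions) and `objectives`.
#' @param progress fraction of the budget spent, in `[0, 1]`.
#' @param config a `qv_search_config`.
#' @return The (possibly shrunk) population, same structure.
#' @export
reduce_population <- function(population, progress, config) {
  stopifnot(length(population$members) >= 1)
  progress <- min(max(progress, 0), 1)
  target <- max(round(config$pop_init -
                        (config$pop_init - config$pop_min) * progress),
                config$pop_min)
  keep <- seq_along(population$members)
  if (length(population$members) > target) {
    keep <- sort(order(population$objectives)[seq_len(target)])
    population$members <- population$members[keep]
    population$objectives <- population$objectives[keep]
  }
  attr(population, "kept") <- keep
  population
}

#' Solve an instance with the hybrid WWO + neighborhood search algorithm
#'
#' Initializes a small random population and iterates generations of:
#' wavelength computation; propagation of every member (a candidate
#' replaces its parent only if strictly better); gradual neighborhood
#' search on every member; breaking applied to the incumbent whenever a
#' generation produces a new global best; and linear population reduction
#' by budget progress.  When every operator has gone quiet for three
#' consecutive generations the population is reinitialized around the
#' incumbent, re-investing budget that would otherwise be spent
#' re-sampling exhausted neighborhoods.  The incumbent objective is
#' non-increasing across generations, and identical seeds with an
#' evaluation-count budget give identical results.
#'
#' @param instance a `qv_instance`.
#' @param config a `qv_search_config`.
#' @return A list of class `qv_search_result`: `solution` (best found),
#'   `objective`, `evaluation` (full [evaluate_events()] result),
#'   `log` (data frame: generation, evaluations, best_objective,
#'   population_size), `evaluations` (total spent), and `config`.
#' @export
#' @examples
#' inst <- worked_example_instance()
#' res <- wwo_solve(inst, search_config(max_evals = 2000, seed = 1))
#' res$objective
wwo_solve <- function(instance, config = search_config()) {
  validate_instance(instance)
  stopifnot(inherits(config, "qv_search_config"))
  set.seed(config$seed)
  start_evals <- evaluation_count()
  t0 <- proc.time()[[3]]
  used <- function() evaluation_count() - start_evals
  budget_left <- function() {
    ok <- TRUE
    if (!is.null(config$max_evals)) ok <- ok && used() < config$max_evals
    if (!is.null(config$time_limit))
      ok <- ok && (proc.time()[[3]] - t0) < config$time_limit
    ok
  }
  progress_frac <- function() {
    p <- 0
    if (!is.null(config$max_evals)) p <- max(p, used() / config$max_evals)
    if (!is.null(config$time_limit))
      p <- max(p, (proc.time()[[3]] - t0) / config$time_limit)
    min(p, 1)
  }
  check_dbg <- function(sol) {
    if (config$debug_invariants && !is_feasible(instance, sol))
      stop("internal error: intermediate solution violates scheduling rules")
    sol
  }

  members <- lapply(init_population(instance, config$pop_init), check_dbg)
  objs <- vapply(members, function(s) objective_events(instance, s), numeric(1))
  changed <- rep(TRUE, length(members))  # member altered since its last GNS pass
  bi <- which.min(objs)
  best <- members[[bi]]
  best_obj <- objs[bi]

  log_rows <- list(data.frame(generation = 0L, evaluations = used(),
                              best_objective = best_obj,
                              population_size = length(members)))
  gen <- 0L
  stalled <- 0L
  while (budget_left()) {
    gen <- gen + 1L
    any_change <- FALSE
    lam <- wavelengths(objs)
    for (k in seq_along(members)) {
      if (!budget_left()) break
      cand <- check_dbg(propagate(members[[k]], lam[k], instance))
      o <- attr(cand, "objective")
      if (!is.null(o) && o < objs[k]) {
        attr(cand, "objective") <- NULL
        attr(cand, "reversals") <- NULL
        cand <- check_dbg(balance_solution(cand, instance))
        members[[k]] <- cand
        objs[k] <- attr(cand, "objective")
        attr(members[[k]], "objective") <- NULL
        changed[k] <- TRUE
        any_change <- TRUE
      }
    }
    for (k in seq_along(members)) {
      if (!budget_left()) break
      if (!changed[k]) next  # direction vector already refined to a fixed point
      res <- check_dbg(gradual_neighborhood_search(members[[k]], instance))
      o <- attr(res, "objective")
      changed[k] <- o < objs[k]
      if (o < objs[k]) {
        members[[k]] <- res
        objs[k] <- o
        any_change <- TRUE
      }
    }
    mi <- which.min(objs)
    if (objs[mi] < best_obj) {
      best <- members[[mi]]
      best_obj <- objs[mi]
      if (budget_left()) {
        br <- check_dbg(breaking(best, config$alpha, instance))
        bo <- attr(br, "objective")
        if (bo < best_obj) {
          best <- br
          best_obj <- bo
          members[[mi]] <- br
          objs[mi] <- bo
        }
      }
    }
    pop <- reduce_population(list(members = members, objectives = objs),
                             progress_frac(), config)
    members <- pop$members
    objs <- pop$objectives
    changed <- changed[attr(pop, "kept")]

    # stall handling: when every operator has gone quiet for several
    # generations the population sits in exhausted neighborhoods, so the
    # remaining budget is re-invested in fresh waves around the incumbent
    stalled <- if (any_change) 0L else stalled + 1L
    if (stalled >= 3L && budget_left()) {
      stalled <- 0L
      size <- length(members)
      fresh <- lapply(init_population(instance, size), check_dbg)
      fresh[[1L]] <- best
      members <- fresh
      objs <- vapply(seq_len(size), function(k)
        if (k == 1L) best_obj else objective_events(instance, members[[k]]),
        numeric(1))
      changed <- rep(TRUE, size)
    }
    prev_best <- log_rows[[length(log_rows)]]$best_objective
    if (best_obj > prev_best + 1e-9)
      stop("internal error: incumbent objective increased")
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(generation = gen, evaluations = used(),
                 best_objective = best_obj,
                 population_size = length(members))
  }
  attributes(best) <- attributes(best)[c("names", "class")]
  structure(list(solution = best, objective = best_obj,
                 evaluation = evaluate_events(instance, best),
                 log = do.call(rbind, log_rows),
                 evaluations = used(), config = config),
            class = "qv_search_result")
}

#' @export
print.qv_search_result <- function(x, ...) {
  cat(sprintf(
    "qv_search_result: objective %.4g after %d evaluations (%d generations)\n",
    x$objective, x$evaluations, max(x$log$generation)))
  invisible(x)
}
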