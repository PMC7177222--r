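# The greedy dispatcher historically used in practice: every vehicle,
# whenever free, is dispatched to the closest area that still has
# unclaimed untransferred individuals it is allowed to serve, claiming
# capacity-worth of them at dispatch time; it loads up to its remaining
# capacity on arrival, returns to the region when full, and keeps going
# until nothing is left.

#' Greedy nearest-area dispatch
#'
#' Event-driven deterministic baseline.  All vehicles start free at their
#' origins at time 0.  A free vehicle targets the area minimizing its
#' travel time from its current position (origin, area, or region; ties by
#' lower area id) among areas that still hold individuals not yet claimed
#' by dispatched vehicles and that it may serve under the splitting rules:
#' an area no larger than the minimum fleet capacity is served by a single
#' vehicle, and an area may be claimed by at most `ceiling(b / c_min)`
#' distinct vehicles.  A dispatched vehicle claims up to its free capacity
#' of the area's unclaimed individuals, so vehicles do not pile onto
#' demand that is already covered; when several vehicles become free
#' simultaneously, conflicting claims resolve in favor of the vehicle that
#' would arrive earlier (ties by lower vehicle index).  On arrival a
#' vehicle loads its claim plus whatever is still unclaimed, up to its
#' free capacity; a full vehicle unloads at the region; a vehicle that
#' leaves individuals behind keeps the area as its next target
#' (shuttling) until the area is empty or its remainder is claimed by
#' another vehicle.  The realized trajectories are encoded as a
#' route-and-direction solution and evaluated with the event evaluator.
#'
#' @param instance a `qv_instance`.
#' @return A list with `solution` (a feasible `qv_solution`), `evaluation`
#'   (its [evaluate_events()] result) and `objective`.
#' @export
#' @examples
#' res <- greedy_solve(worked_example_instance())
#' res$objective
greedy_solve <- function(instance) {
  validate_instance(instance)
  b <- as.integer(instance$areas$individuals)
  cvec <- as.integer(instance$vehicles$capacity)
  tor <- instance$times$origin_to_area
  tb <- instance$times$between_areas
  tr <- instance$times$area_to_region
  dtm <- instance$times$loading_interval
  n <- length(b)
  m <- length(cvec)
  cmin <- min(cvec)
  kcap <- max_vehicles_for_area(b, cmin)

  rem <- b                       # individuals still waiting at the area
  unclm <- b                     # individuals not covered by any claim
  claimants <- matrix(FALSE, m, n)
  nclaim <- integer(n)           # distinct vehicles that ever claimed the area
  phase <- rep("decide", m)      # decide | arrive | done
  vtime <- numeric(m)            # time of the vehicle's next event
  ptype <- rep("origin", m)      # current position: origin | area | region
  parea <- integer(m)
  load <- integer(m)
  target <- integer(m)
  claim_q <- integer(m)
  sticky <- integer(m)
  went_region <- rep(FALSE, m)
  routes <- rep(list(integer(0)), m)
  bits <- rep(list(integer(0)), m)

  travel <- function(i, a) {
    switch(ptype[i],
           origin = tor[i, a],
           area = tb[i, parea[i], a],
           region = tr[i, a])
  }
  eligible_areas <- function(i) {
    ok <- unclm > 0L & (claimants[i, ] |
                          (nclaim < kcap & (b > cmin | nclaim == 0L)))
    which(ok)
  }
  preferred <- function(i) {
    if (sticky[i] != 0L) return(sticky[i])
    el <- eligible_areas(i)
    if (length(el) == 0L) return(0L)
    tt <- vapply(el, function(x) travel(i, x), numeric(1))
    el[which.min(tt)]
  }
  retire <- function(i) {
    if (load[i] > 0L && ptype[i] == "area") {
      vtime[i] <<- vtime[i] + tr[i, parea[i]]
      went_region[i] <<- TRUE
      load[i] <<- 0L
      ptype[i] <<- "region"
    }
    phase[i] <<- "done"
  }

  repeat {
    dec <- which(phase == "decide")
    arrs <- which(phase == "arrive")
    if (length(dec) == 0L && length(arrs) == 0L) break
    t_dec <- if (length(dec)) min(vtime[dec]) else Inf
    t_arr <- if (length(arrs)) min(vtime[arrs]) else Inf

    if (t_dec <= t_arr + 1e-12) {
      # dispatch all vehicles freed at this instant; conflicting claims go
      # to the vehicle arriving earlier (ties: lower index)
      batch <- dec[vtime[dec] <= t_dec + 1e-12]
      repeat {
        best_i <- 0L; best_a <- 0L; best_arr <- Inf
        for (i in batch) {
          if (phase[i] != "decide") next
          if (sticky[i] != 0L &&
              (rem[sticky[i]] == 0L || unclm[sticky[i]] == 0L))
            sticky[i] <- 0L   # remainder gone or covered by another claim
          a <- preferred(i)
          if (a == 0L) { retire(i); next }
          arr <- vtime[i] + travel(i, a)
          if (arr < best_arr - 1e-12) { best_i <- i; best_a <- a; best_arr <- arr }
        }
        if (best_i == 0L) break
        i <- best_i; a <- best_a
        q <- min(cvec[i] - load[i], unclm[a])
        stopifnot(q >= 1L)
        unclm[a] <- unclm[a] - q
        claim_q[i] <- q
        if (!claimants[i, a]) {
          claimants[i, a] <- TRUE
          nclaim[a] <- nclaim[a] + 1L
        }
        sticky[i] <- 0L
        target[i] <- a
        phase[i] <- "arrive"
        vtime[i] <- best_arr
      }
    } else {
      # commit the earliest arrival (ties: lower index via which.min)
      i <- arrs[which.min(vtime[arrs])]
      a <- target[i]
      arr <- vtime[i]
      # the vehicle takes its claim plus any still-unclaimed individuals,
      # up to its free capacity; claimed individuals of later-arriving
      # vehicles are left for them
      q <- min(cvec[i] - load[i], claim_q[i] + unclm[a])
      stopifnot(q >= 1L, q <= rem[a])
      unclm[a] <- unclm[a] - (q - claim_q[i])
      claim_q[i] <- 0L
      rem[a] <- rem[a] - q
      if (length(routes[[i]]) == 0L || routes[[i]][length(routes[[i]])] != a) {
        if (length(routes[[i]]) > 0L)
          bits[[i]] <- c(bits[[i]], as.integer(went_region[i]))
        routes[[i]] <- c(routes[[i]], a)
      }
      went_region[i] <- FALSE
      load[i] <- load[i] + q
      leave <- arr + (q - 1L) * dtm[i, a]
      ptype[i] <- "area"
      parea[i] <- a
      phase[i] <- "decide"
      if (load[i] == cvec[i]) {
        vtime[i] <- leave + tr[i, a]
        went_region[i] <- TRUE
        load[i] <- 0L
        ptype[i] <- "region"
        # individuals left behind: keep shuttling back unless another
        # vehicle's claim now covers them
        sticky[i] <- if (rem[a] > 0L && unclm[a] > 0L) a else 0L
      } else {
        vtime[i] <- leave
        sticky[i] <- 0L
      }
    }
  }

  if (any(rem != 0L))
    stop("internal error: greedy left individuals untransferred")
  solution <- qv_solution(routes, bits)
  rep <- check_rules(instance, solution)
  if (nrow(rep) > 0L)
    stop(sprintf("internal error: greedy produced an infeasible solution (%s)",
                 rep$message[1]))
  ev <- evaluate_events(instance, solution, check = FALSE)
  list(solution = solution, evaluation = ev, objective = ev$objective)
}
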