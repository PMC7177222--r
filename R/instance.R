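#' Construct a quarantine routing problem instance
#'
#' An instance describes a set of areas holding high-risk individuals, a
#' heterogeneous fleet of quarantine vehicles, and per-vehicle travel times
#' between every pair of locations plus the single isolated region that all
#' vehicles unload at.  Vehicles are canonicalized to nondecreasing capacity
#' order on construction (the scheduling rules are stated relative to the
#' minimum residual capacity, so the sorted order is the natural working
#' order); the original input order is preserved in the `meta` field so that
#' results can be reported against the order of the source file.
#'
#' @param areas data frame with columns `id` (contiguous 1..n) and
#'   `individuals` (positive integer counts, one per area).
#' @param vehicles data frame with columns `id` and `capacity`
#'   (positive integers).
#' @param times list with elements `origin_to_area` (m x n matrix, minutes
#'   from each vehicle's start location to each area), `between_areas`
#'   (m x n x n array, per-vehicle area-to-area times with zero diagonal),
#'   `area_to_region` (m x n matrix, times from each area to the isolated
#'   region) and `loading_interval` (m x n matrix, mean minutes between
#'   loading two successive individuals in an area).
#' @param name optional label for the instance.
#'
#' @return An object of class `qv_instance`: a list with fields `name`,
#'   `areas`, `vehicles` (sorted by nondecreasing capacity), `times`, and
#'   `meta` (with `original_order`, the position of each sorted vehicle in
#'   the input order).
#' @seealso [load_instance()], [save_instance()], [check_rules()]
#' @export
#' @examples
#' inst <- worked_example_instance()
#' inst$areas$individuals
#' min_capacity(inst)
qv_instance <- function(areas, vehicles, times, name = "instance") {
  areas <- as.data.frame(areas)
  vehicles <- as.data.frame(vehicles)
  ord <- order(vehicles$capacity)
  vehicles_sorted <- vehicles[ord, , drop = FALSE]
  rownames(vehicles_sorted) <- NULL
  times <- list(
    origin_to_area = as.matrix(times$origin_to_area)[ord, , drop = FALSE],
    between_areas = times$between_areas[ord, , , drop = FALSE],
    area_to_region = as.matrix(times$area_to_region)[ord, , drop = FALSE],
    loading_interval = as.matrix(times$loading_interval)[ord, , drop = FALSE]
  )
  inst <- structure(
    list(name = name, areas = areas, vehicles = vehicles_sorted,
         times = times, meta = list(original_order = ord)),
    class = "qv_instance"
  )
  validate_instance(inst)
  inst
}

#' Validate a problem instance
#'
#' Checks all structural invariants of a `qv_instance`: contiguous area ids,
#' positive individual counts and capacities, matching matrix dimensions,
#' nonnegative finite travel times, and a zero diagonal in the area-to-area
#' tensor.  Called by the constructor and by [load_instance()].
#'
#' @param instance object to validate.
#' @return The instance, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_instance <- function(instance) {
  if (!inherits(instance, "qv_instance")) stop("not a qv_instance")
  a <- instance$areas
  v <- instance$vehicles
  tt <- instance$times
  n <- nrow(a)
  m <- nrow(v)
  if (n < 1L) stop("instance field 'areas': at least one area required")
  if (m < 1L) stop("instance field 'vehicles': at least one vehicle required")
  if (!identical(as.integer(a$id), seq_len(n)))
    stop("instance field 'areas$id': ids must be contiguous 1..n")
  if (any(a$individuals < 1) || any(a$individuals != round(a$individuals)))
    stop("instance field 'areas$individuals': counts must be positive integers")
  if (any(v$capacity < 1) || any(v$capacity != round(v$capacity)))
    stop("instance field 'vehicles$capacity': capacities must be positive integers")
  if (is.unsorted(v$capacity))
    stop("instance field 'vehicles': must be in nondecreasing capacity order")
  dims <- list(origin_to_area = c(m, n), area_to_region = c(m, n),
               loading_interval = c(m, n), between_areas = c(m, n, n))
  for (nm in names(dims)) {
    x <- tt[[nm]]
    if (!identical(dim(x), as.integer(dims[[nm]])))
      stop(sprintf("instance field 'times$%s': expected shape %s, found %s",
                   nm, paste(dims[[nm]], collapse = "x"),
                   paste(dim(x), collapse = "x")))
    if (any(!is.finite(x)) || any(x < 0))
      stop(sprintf("instance field 'times$%s': entries must be finite and >= 0", nm))
  }
  for (i in seq_len(m)) {
    if (any(tt$between_areas[cbind(i, seq_len(n), seq_len(n))] != 0))
      stop("instance field 'times$between_areas': diagonal entries must be 0")
  }
  invisible(instance)
}

#' @export
print.qv_instance <- function(x, ...) {
  cat(sprintf("qv_instance '%s': %d areas (%d individuals), %d vehicles (capacities %s)\n",
              x$name, nrow(x$areas), sum(x$areas$individuals), nrow(x$vehicles),
              paste(x$vehicles$capacity, collapse = ",")))
  invisible(x)
}

#' Number of areas / vehicles in an instance
#'
#' @param instance a `qv_instance`.
#' @return Integer count.
#' @export
n_areas <- function(instance) nrow(instance$areas)

#' @rdname n_areas
#' @export
n_vehicles <- function(instance) nrow(instance$vehicles)

#' Minimum vehicle capacity
#'
#' The smallest capacity in the fleet, written c_min.  The splitting rules
#' are stated relative to this quantity: an area whose count does not exceed
#' c_min may be served by a single vehicle only.
#'
#' @param instance a `qv_instance` with at least one vehicle.
#' @return The minimum capacity, a positive integer.
#' @export
min_capacity <- function(instance) {
  if (nrow(instance$vehicles) < 1L) stop("instance has no vehicles")
  min(instance$vehicles$capacity)
}

#' Maximum number of vehicles allowed for an area
#'
#' Returns the unique positive integer k satisfying
#' (k - 1) * c_min < b <= k * c_min, i.e. `ceiling(b / c_min)`: the cap on
#' how many vehicles may share the b individuals of one area.
#'
#' @param b positive integer count of individuals in the area.
#' @param c_min positive integer minimum fleet capacity.
#' @return The cap k, a positive integer (vectorized over `b`).
#' @export
max_vehicles_for_area <- function(b, c_min) {
  stopifnot(all(b >= 1), c_min >= 1)
  as.integer(ceiling(b / c_min))
}

#' Construct a solution
#'
#' A solution assigns each vehicle an ordered sequence of areas to visit and,
#' after every non-final area, a direction bit: 1 means the vehicle returns
#' to the isolated region to unload before heading to its next area, 0 means
#' it drives there directly with its current load.
#'
#' @param routes list of m integer vectors of area ids (possibly empty).
#' @param directions list of m 0/1 vectors, each of length
#'   `max(length(route) - 1, 0)`.
#' @return Object of class `qv_solution`.
#' @export
qv_solution <- function(routes, directions) {
  if (length(routes) != length(directions))
    stop("routes and directions must have the same length")
  routes <- lapply(routes, as.integer)
  directions <- lapply(directions, as.integer)
  for (i in seq_along(routes)) {
    want <- max(length(routes[[i]]) - 1L, 0L)
    if (length(directions[[i]]) != want)
      stop(sprintf("vehicle %d: expected %d direction bits, found %d",
                   i, want, length(directions[[i]])))
  }
  structure(list(routes = routes, directions = directions),
            class = "qv_solution")
}

#' @export
print.qv_solution <- function(x, ...) {
  for (i in seq_along(x$routes)) {
    r <- x$routes[[i]]
    if (length(r) == 0L) {
      cat(sprintf("v%d: (idle)\n", i))
    } else {
      y <- x$directions[[i]]
      parts <- as.character(r[1])
      if (length(r) > 1L) {
        for (j in 2:length(r)) {
          parts <- c(parts, if (y[j - 1L] == 1L) "->R->" else "->", r[j])
        }
      }
      cat(sprintf("v%d: %s\n", i, paste(parts, collapse = " ")))
    }
  }
  invisible(x)
}

#' Check a solution against the scheduling rules
#'
#' Verifies the static feasibility rules of the problem:
#' * `R1` -- an area whose count is at most c_min may appear in only one
#'   route;
#' * `R3` -- an area may appear in at most `ceiling(b / c_min)` routes;
#' * `coverage` -- every area appears in at least one route;
#' * `bounds` -- area ids lie in 1..n, direction bits are 0/1, direction
#'   lengths match route lengths, and no route repeats an area.
#'
#' The shuttling rule (a vehicle alone at an area keeps shuttling until the
#' area is empty) and the first-arriver-loads-most rule are enforced by the
#' evaluators by construction, so they are not checked here.  Rules are
#' checked against the global fleet minimum capacity; the sequential greedy
#' dispatcher, which schedules vehicles one at a time, applies the same
#' rules with the residual fleet internally.
#'
#' @param instance a `qv_instance`.
#' @param solution a `qv_solution` (or a bare list with `routes` and
#'   `directions`).
#' @return A data frame of class `qv_rule_report` with columns `rule`,
#'   `vehicle`, `area`, `message`; zero rows iff the solution is feasible.
#' @export
#' @examples
#' inst <- worked_example_instance()
#' sol <- qv_solution(list(c(1, 2, 3), c(2, 3)), list(c(0, 1), c(1)))
#' check_rules(inst, sol)   # zero rows: feasible
check_rules <- function(instance, solution) {
  n <- n_areas(instance)
  m <- n_vehicles(instance)
  b <- instance$areas$individuals
  cmin <- min_capacity(instance)
  kcap <- max_vehicles_for_area(b, cmin)
  viol <- list()
  add <- function(rule, vehicle, area, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, vehicle = vehicle, area = area, message = message,
      stringsAsFactors = FALSE)
  }
  routes <- solution$routes
  dirs <- solution$directions
  if (length(routes) != m) {
    add("bounds", NA_integer_, NA_integer_,
        sprintf("expected %d routes, found %d", m, length(routes)))
  }
  count <- integer(n)
  for (i in seq_along(routes)) {
    r <- routes[[i]]
    y <- if (i <= length(dirs)) dirs[[i]] else integer(0)
    if (length(y) != max(length(r) - 1L, 0L))
      add("bounds", i, NA_integer_, "direction length does not match route length")
    if (any(!(y %in% c(0L, 1L))))
      add("bounds", i, NA_integer_, "direction bits must be 0 or 1")
    bad <- r[r < 1L | r > n]
    for (a in bad) add("bounds", i, a, "area id out of range")
    r <- r[r >= 1L & r <= n]
    dup <- unique(r[duplicated(r)])
    for (a in dup) add("bounds", i, a, "area repeated within one route")
    for (a in unique(r)) count[a] <- count[a] + 1L
  }
  for (a in seq_len(n)) {
    if (count[a] == 0L)
      add("coverage", NA_integer_, a, "area not assigned to any vehicle")
    if (b[a] <= cmin && count[a] > 1L)
      add("R1", NA_integer_, a,
          sprintf("area with %d <= c_min = %d individuals assigned to %d vehicles",
                  b[a], cmin, count[a]))
    if (count[a] > kcap[a])
      add("R3", NA_integer_, a,
          sprintf("area assigned to %d vehicles, cap is %d", count[a], kcap[a]))
  }
  report <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(0), vehicle = integer(0),
               area = integer(0), message = character(0),
               stringsAsFactors = FALSE)
  class(report) <- c("qv_rule_report", "data.frame")
  report
}

#' Is a solution rule-feasible?
#'
#' @param instance a `qv_instance`.
#' @param solution a `qv_solution`.
#' @return TRUE iff [check_rules()] reports no violations.
#' @export
is_feasible <- function(instance, solution) {
  nrow(check_rules(instance, solution)) == 0L
}

# ---- file I/O ---------------------------------------------------------------

#' Read a problem instance from a JSON file
#'
#' The on-disk schema is
#' `{"name", "areas": [{"id", "individuals"}], "vehicles": [{"id",
#' "capacity"}], "times": {"origin_to_area", "between_areas",
#' "area_to_region", "loading_interval"}}` where each `times` entry is a
#' (nested) array with row index = vehicle (file order) and column index =
#' area id.  On load, vehicles are re-sorted to nondecreasing capacity; the
#' original file order is recorded in the returned instance's metadata.
#'
#' @param path path to a JSON instance file.
#' @return A validated `qv_instance`.
#' @export
load_instance <- function(path) {
  if (!file.exists(path)) stop(sprintf("instance file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("areas", "vehicles", "times"))
    if (is.null(raw[[field]]))
      stop(sprintf("instance file missing required field '%s'", field))
  areas <- as.data.frame(raw$areas)
  vehicles <- as.data.frame(raw$vehicles)
  if (is.null(areas$id) || is.null(areas$individuals))
    stop("instance field 'areas': entries need 'id' and 'individuals'")
  if (is.null(vehicles$id) || is.null(vehicles$capacity))
    stop("instance field 'vehicles': entries need 'id' and 'capacity'")
  tt <- raw$times
  for (nm in c("origin_to_area", "between_areas", "area_to_region", "loading_interval"))
    if (is.null(tt[[nm]]))
      stop(sprintf("instance field 'times$%s' missing", nm))
  m <- nrow(vehicles)
  n <- nrow(areas)
  shape_matrix <- function(x, nm) {
    x <- as.matrix(x)
    if (m == 1L && nrow(x) != 1L) x <- matrix(as.numeric(x), nrow = 1L)
    if (!identical(dim(x), c(m, n)))
      stop(sprintf("instance field 'times$%s': expected shape %dx%d, found %s",
                   nm, m, n, paste(dim(x), collapse = "x")))
    x
  }
  ba <- tt$between_areas
  if (!is.array(ba) || length(dim(ba)) != 3L) {
    ba <- array(as.numeric(unlist(ba)), dim = c(n, n, m))
    ba <- aperm(ba, c(3L, 1L, 2L))
  }
  times <- list(
    origin_to_area = shape_matrix(tt$origin_to_area, "origin_to_area"),
    between_areas = ba,
    area_to_region = shape_matrix(tt$area_to_region, "area_to_region"),
    loading_interval = shape_matrix(tt$loading_interval, "loading_interval")
  )
  qv_instance(areas = areas, vehicles = vehicles, times = times,
              name = if (!is.null(raw$name)) raw$name else basename(path))
}

#' Write a problem instance to a JSON file
#'
#' Inverse of [load_instance()]: the written file re-loads to an instance
#' equal to the input (numeric values round-trip at full precision).
#' Vehicles are written in the instance's canonical (sorted) order.
#'
#' @param instance a valid `qv_instance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_instance <- function(instance, path) {
  validate_instance(instance)
  obj <- list(
    name = instance$name,
    areas = instance$areas,
    vehicles = instance$vehicles[, c("id", "capacity")],
    times = list(
      origin_to_area = instance$times$origin_to_area,
      between_areas = instance$times$between_areas,
      area_to_region = instance$times$area_to_region,
      loading_interval = instance$times$loading_interval
    )
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}

#' Read / write a solution JSON file
#'
#' Schema: `{"routes": [{"vehicle": i, "areas": [...], "return_flags":
#' [...]}], "objective": f}`.  The objective entry is informational and
#' optional on read.
#'
#' @param path file path.
#' @return For `load_solution`, a `qv_solution` (with the stored objective,
#'   if any, in attribute `"objective"`).
#' @export
load_solution <- function(path) {
  if (!file.exists(path)) stop(sprintf("solution file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- raw$routes
  mx <- max(vapply(entries, function(e) as.integer(e$vehicle), integer(1)))
  routes <- rep(list(integer(0)), mx)
  dirs <- rep(list(integer(0)), mx)
  for (e in entries) {
    i <- as.integer(e$vehicle)
    routes[[i]] <- as.integer(unlist(e$areas))
    dirs[[i]] <- as.integer(unlist(e$return_flags))
  }
  sol <- qv_solution(routes, dirs)
  if (!is.null(raw$objective)) attr(sol, "objective") <- as.numeric(raw$objective)
  sol
}

#' @rdname load_solution
#' @param solution a `qv_solution`.
#' @param objective optional objective value to store alongside the routes.
#' @export
save_solution <- function(solution, path, objective = NULL) {
  entries <- lapply(seq_along(solution$routes), function(i) {
    list(vehicle = i, areas = solution$routes[[i]],
         return_flags = solution$directions[[i]])
  })
  obj <- list(routes = entries)
  if (!is.null(objective)) obj$objective <- objective
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}
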