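# Stage 2: the greedy bi-objective selection loop. Each round scores every
# remaining candidate by the demand population inside its service radius
# (maximal-coverage objective), restricts to the argmax set, breaks the tie
# by minimum demand-weighted distance (p-median objective), commits the
# winner, removes the demand it covers, and repeats. Facilities are then
# sized from the population they cover.

#' Siting configuration
#'
#' @param service_radius clinic service radius in meters (default 300).
#' @param area_index floor area per 1000 covered persons, m^2; the planning
#'   standard allows 15-30 and the default is the upper value 30. Values
#'   outside the standard range require `allow_any_index = TRUE`.
#' @param min_covered_population stop selecting once the best remaining
#'   candidate covers fewer persons than this (default 10000, the
#'   resident count at which a clinic is warranted; set 0 to cover all
#'   reachable demand).
#' @param max_sites maximum number of sites to select (default unlimited).
#' @param allow_any_index permit `area_index` outside 15-30.
#' @return a `siting_config` list.
#' @export
siting_config <- function(service_radius = 300, area_index = 30,
                          min_covered_population = 10000, max_sites = Inf,
                          allow_any_index = FALSE) {
  if (!is.numeric(service_radius) || service_radius <= 0) {
    stop("service_radius must be positive", call. = FALSE)
  }
  if ((area_index < 15 || area_index > 30) && !allow_any_index) {
    stop("area_index outside the 15-30 m^2 per 1000 persons planning standard; ",
         "set allow_any_index = TRUE to override", call. = FALSE)
  }
  stopifnot(min_covered_population >= 0, max_sites >= 0)
  structure(list(service_radius = service_radius, area_index = area_index,
                 min_covered_population = min_covered_population,
                 max_sites = max_sites),
            class = "siting_config")
}

#' Demand covered by a candidate site
#'
#' A demand point is covered when its straight-line distance to the
#' candidate is less than or equal to the service radius (the boundary
#' counts as covered).
#'
#' @param candidate numeric `c(x, y)` or a one-row data frame with `x`, `y`.
#' @param demand data frame with columns `id`, `x`, `y`, `pop`.
#' @param radius service radius, meters.
#' @return list with `ids` (covered demand ids) and `population`
#'   (their summed weight).
#' @export
coverage <- function(candidate, demand, radius) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive", call. = FALSE)
  if (is.data.frame(candidate)) candidate <- c(candidate$x[1], candidate$y[1])
  d <- sqrt((demand$x - candidate[1])^2 + (demand$y - candidate[2])^2)
  hit <- d <= radius
  list(ids = demand$id[hit], population = sum(demand$pop[hit]))
}

#' Demand-weighted distance from a candidate to its covered demand
#'
#' `sum_k pop_k * dist_k` over the covered set only, in person-meters; the
#' p-median score used to break coverage ties. An empty covered set scores 0.
#'
#' @param candidate numeric `c(x, y)` or a one-row data frame.
#' @param covered data frame of covered demand points (`x`, `y`, `pop`).
#' @return weighted distance in person-meters.
#' @export
weighted_distance <- function(candidate, covered) {
  if (is.null(covered) || nrow(covered) == 0) return(0)
  if (is.data.frame(candidate)) candidate <- c(candidate$x[1], candidate$y[1])
  d <- sqrt((covered$x - candidate[1])^2 + (covered$y - candidate[2])^2)
  sum(covered$pop * d)
}

#' Greedy bi-objective site selection
#'
#' Iterates until demand or candidates are exhausted, the best coverage
#' falls below `min_covered_population`, or `max_sites` is reached. Per
#' round: (a) every remaining candidate is scored by the remaining demand
#' population within the service radius; (b) the candidates attaining the
#' maximum form the max-coverage set Q; (c) the member of Q with minimal
#' demand-weighted distance to the demand it covers wins, residual ties
#' going to the earliest candidate in input order; (d) the winner is
#' committed, and both it and the demand it covers are removed, so every
#' demand point is assigned to at most one site and per-round coverage is
#' non-increasing.
#'
#' @param candidates data frame of candidate sites (`x`, `y`), e.g. from
#'   [extract_candidates()].
#' @param demand data frame with `id`, `x`, `y`, `pop` (the coverage /
#'   tie-break weight, e.g. elderly headcount) and optionally `sizing_pop`,
#'   a second weight summed per round for facility sizing (e.g. total
#'   residents); without it `pop` is used for sizing too.
#' @param config a [siting_config()].
#' @return a `siting_plan`: `rounds` (one row per selected site: `round`,
#'   `x`, `y`, `covered_population`, `sizing_population`,
#'   `weighted_distance`, `q_set_size`, `floor_area`), `covered_ids` (list
#'   of demand ids per round), `assignments` (named integer vector, demand
#'   id to round), `uncovered_demand_ids`, and the echoed `config`.
#' @export
greedy_select <- function(candidates, demand, config = siting_config()) {
  stopifnot(inherits(config, "siting_config"))
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("empty candidate set: nothing to select from", call. = FALSE)
  }
  radius <- config$service_radius
  sizing <- if (is.null(demand$sizing_pop)) demand$pop else demand$sizing_pop
  nd <- nrow(demand); ncand <- nrow(candidates)

  # candidate x demand coverage incidence, computed once
  if (nd > 0) {
    d2 <- outer(candidates$x, demand$x, "-")^2 + outer(candidates$y, demand$y, "-")^2
    covmat <- d2 <= radius^2
    dmat <- sqrt(d2)
  } else {
    covmat <- matrix(FALSE, ncand, 0); dmat <- matrix(0, ncand, 0)
  }

  cand_left <- rep(TRUE, ncand)
  dem_left <- rep(TRUE, nd)
  rounds <- list(); covered_ids <- list()
  assignments <- integer(0)

  while (any(dem_left) && any(cand_left) && length(rounds) < config$max_sites) {
    ci <- which(cand_left); di <- which(dem_left)
    pops <- as.numeric(covmat[ci, di, drop = FALSE] %*% demand$pop[di])
    best <- max(pops)
    if (best <= 0) break                       # no candidate reaches residual demand
    if (best < config$min_covered_population) break
    q <- ci[pops == best]                      # max-coverage set Q for this round
    wd <- vapply(q, function(i) {
      hit <- di[covmat[i, di]]
      sum(demand$pop[hit] * dmat[i, hit])
    }, numeric(1))
    chosen <- q[which.min(wd)]                 # earliest candidate wins residual ties
    hit <- di[covmat[chosen, di]]
    r <- length(rounds) + 1L
    rounds[[r]] <- data.frame(
      round = r, x = candidates$x[chosen], y = candidates$y[chosen],
      covered_population = sum(demand$pop[hit]),
      sizing_population = sum(sizing[hit]),
      weighted_distance = sum(demand$pop[hit] * dmat[chosen, hit]),
      q_set_size = length(q))
    covered_ids[[r]] <- demand$id[hit]
    a <- rep(r, length(hit)); names(a) <- as.character(demand$id[hit])
    assignments <- c(assignments, a)
    cand_left[chosen] <- FALSE
    dem_left[hit] <- FALSE
  }

  rounds <- if (length(rounds)) do.call(rbind, rounds) else
    data.frame(round = integer(), x = numeric(), y = numeric(),
               covered_population = numeric(), sizing_population = numeric(),
               weighted_distance = numeric(), q_set_size = integer())
  rounds$floor_area <- size_facility(rounds$sizing_population, config$area_index,
                                     allow_any_index = TRUE)
  structure(list(rounds = rounds, covered_ids = covered_ids,
                 assignments = assignments,
                 uncovered_demand_ids = demand$id[dem_left],
                 config = config),
            class = "siting_plan")
}

#' @export
print.siting_plan <- function(x, ...) {
  cat(sprintf("siting_plan: %d site(s), %d demand point(s) left uncovered\n",
              nrow(x$rounds), length(x$uncovered_demand_ids)))
  if (nrow(x$rounds)) {
    print(x$rounds, row.names = FALSE)
  }
  invisible(x)
}

#' Size a facility from the population it covers
#'
#' Applies the planning standard of `area_index` square meters of clinic
#' floor area per 1000 covered persons, rounded up:
#' `ceil(population * area_index / 1000)`. Covering 12,430 persons at the
#' 30 m^2 index yields 373 m^2.
#'
#' @param covered_population persons covered (>= 0); vectorised.
#' @param area_index m^2 per 1000 persons, 15-30 under the standard.
#' @param allow_any_index permit an index outside 15-30.
#' @return floor area in whole square meters.
#' @export
#' @examples
#' size_facility(12430, 30)  # 373
size_facility <- function(covered_population, area_index = 30, allow_any_index = FALSE) {
  if (any(covered_population < 0)) stop("covered_population must be >= 0", call. = FALSE)
  if ((area_index < 15 || area_index > 30) && !allow_any_index) {
    stop("area_index outside the 15-30 m^2 per 1000 persons planning standard; ",
         "set allow_any_index = TRUE to override", call. = FALSE)
  }
  ceiling(covered_population * area_index / 1000)
}

#' Coverage report for a plan plus the existing facilities
#'
#' Tabulates, per facility (existing first, then planned), the demand
#' population within its service radius — existing facilities use their own
#' `service_radius`, planned sites the given radius — and computes the
#' overall fraction of the demand population within reach of at least one
#' facility.
#'
#' @param plan a `siting_plan` (may have zero rounds).
#' @param existing data frame of existing facilities (`id`, `kind`, `x`,
#'   `y`, `service_radius`), or `NULL`/empty.
#' @param demand data frame with `id`, `x`, `y`, `pop` — the full demand
#'   set the report is judged against.
#' @param radius service radius for planned sites, meters.
#' @return list with `table` (facility, kind, covered population) and
#'   `fraction_covered` of total demand population (0 when there is none).
#' @export
coverage_report <- function(plan, existing, demand, radius = 300) {
  sites <- data.frame(id = character(), kind = character(),
                      x = numeric(), y = numeric(), r = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(existing) && nrow(existing)) {
    sites <- rbind(sites, data.frame(id = as.character(existing$id),
                                     kind = existing$kind,
                                     x = existing$x, y = existing$y,
                                     r = existing$service_radius,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(plan$rounds)) {
    sites <- rbind(sites, data.frame(id = paste0("planned_", plan$rounds$round),
                                     kind = "planned_clinic",
                                     x = plan$rounds$x, y = plan$rounds$y,
                                     r = radius, stringsAsFactors = FALSE))
  }
  served <- rep(FALSE, nrow(demand))
  covered <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- sqrt((demand$x - sites$x[i])^2 + (demand$y - sites$y[i])^2) <= sites$r[i]
    covered[i] <- sum(demand$pop[hit])
    served <- served | hit
  }
  total <- sum(demand$pop)
  list(table = data.frame(facility = sites$id, kind = sites$kind,
                          covered_population = covered, stringsAsFactors = FALSE),
       fraction_covered = if (total > 0) sum(demand$pop[served]) / total else 0)
}
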