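# Stage-0 demand computations: spreading the community's elderly population
# over building centroids in proportion to floor area, summarising the
# accessibility survey, turning accepted walk times into service radii, and
# the finite-population sample-size check for the survey itself.

#' Community demographic profile
#'
#' @param households number of households in the community (P).
#' @param persons_per_household average household size (N), > 0.
#' @param elderly_ratio share of residents aged 60+ (R), in `[0, 1]`.
#' @return a `community_profile` with the derived `total_population = P * N`.
#' @export
#' @examples
#' community_profile(40000, 2.5, 0.30)
community_profile <- function(households, persons_per_household, elderly_ratio) {
  stopifnot(is.numeric(households), households >= 0,
            is.numeric(persons_per_household), persons_per_household > 0)
  if (!is.numeric(elderly_ratio) || elderly_ratio < 0 || elderly_ratio > 1) {
    stop("elderly_ratio must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(list(households = households,
                 persons_per_household = persons_per_household,
                 elderly_ratio = elderly_ratio,
                 total_population = households * persons_per_household),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf(
    "community_profile: %g households x %g persons = %g residents, elderly ratio %.2f (%g elderly)\n",
    x$households, x$persons_per_household, x$total_population,
    x$elderly_ratio, x$total_population * x$elderly_ratio))
  invisible(x)
}

#' Allocate the elderly population to building centroids
#'
#' Each building receives an elderly headcount proportional to its share of
#' the community's total floor area:
#' `EP_i = (a_i / A) * P * N * R`, with `A = sum(a_i)`. Full occupancy of
#' every building is assumed, so the allocation conserves the community
#' total: `sum(EP_i) = P * N * R`.
#'
#' @param buildings data frame with columns `x`, `y`, `floor_area` (and
#'   optionally `id`), as returned by [read_vector_layer()].
#' @param profile a [community_profile()].
#' @return `buildings` with `elderly_pop` filled (and `resident_pop`, the
#'   analogous total-resident allocation `(a_i / A) * P * N`, used for
#'   facility sizing against resident-based planning standards).
#' @export
allocate_elderly_population <- function(buildings, profile) {
  stopifnot(inherits(profile, "community_profile"))
  if (nrow(buildings) == 0) stop("no buildings to allocate to", call. = FALSE)
  a <- buildings$floor_area
  if (any(!is.finite(a)) || any(a < 0)) stop("floor areas must be finite and >= 0", call. = FALSE)
  A <- sum(a)
  if (A <= 0) {
    stop("undefined share: total floor area is zero, cannot allocate population", call. = FALSE)
  }
  residents <- (a / A) * profile$total_population
  buildings$resident_pop <- residents
  buildings$elderly_pop <- residents * profile$elderly_ratio
  buildings
}

#' Round half away from zero
#' @param x numeric vector; @param digits decimal places.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# canonical category orderings for the questionnaire codes
.survey_levels <- list(
  gender = c("male", "female"),
  age_band = c("a60_64", "a65_69", "a70_74", "a75_79", "a80p"),
  health = c("good", "fair", "poor"),
  income_band = c("lt1000", "i1000_1500", "i1500_2000", "i2000_2500", "gt2500"),
  accessibility_choice = c("lt5", "m5_10", "m10_15", "m15_20", "gt20")
)

#' Summarise the accessibility questionnaire
#'
#' Tabulates each respondent characteristic (gender, age band, health,
#' income band, accepted walk time) into counts and percentages of the valid
#' responses. Percentages are `100 * count / n_valid`, rounded half-up to
#' two decimals; the response rate is `100 * n_valid / n_distributed` on the
#' same rounding.
#'
#' @param responses data frame, one row per respondent; any subset of the
#'   columns `gender`, `age_band`, `health`, `income_band`,
#'   `accessibility_choice`. The walk-time column must use the codes
#'   `lt5`, `m5_10`, `m10_15`, `m15_20`, `gt20`.
#' @param n_distributed number of questionnaires handed out (>= n_valid).
#' @return a `survey_summary`: `table` (characteristic, level, n, pct),
#'   `n_valid`, `n_distributed`, `response_rate`.
#' @export
summarize_survey <- function(responses, n_distributed = nrow(responses)) {
  n_valid <- nrow(responses)
  if (is.null(n_valid) || n_valid == 0) {
    stop("empty summary: no valid survey responses", call. = FALSE)
  }
  if (n_distributed < n_valid) {
    stop("n_distributed must be at least the number of valid responses", call. = FALSE)
  }
  cols <- intersect(names(.survey_levels), names(responses))
  if (!length(cols)) stop("no recognised survey columns present", call. = FALSE)
  if ("accessibility_choice" %in% cols) {
    bad <- setdiff(unique(as.character(responses$accessibility_choice)),
                   .survey_levels$accessibility_choice)
    if (length(bad)) {
      stop("invalid accessibility_choice code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  tabs <- lapply(cols, function(col) {
    obs <- as.character(responses[[col]])
    lev <- union(.survey_levels[[col]], unique(obs))
    n <- as.integer(table(factor(obs, levels = lev)))
    data.frame(characteristic = col, level = lev, n = n,
               pct = round_half_up(100 * n / n_valid, 2),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, tabs),
                 n_valid = n_valid,
                 n_distributed = n_distributed,
                 response_rate = round_half_up(100 * n_valid / n_distributed, 2)),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("survey_summary: %d valid of %d distributed (response rate %.2f%%)\n",
              x$n_valid, x$n_distributed, x$response_rate))
  for (ch in unique(x$table$characteristic)) {
    cat(" ", ch, "\n")
    sub <- x$table[x$table$characteristic == ch, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-12s %5d  %6.2f%%\n", sub$level[i], sub$n[i], sub$pct[i]))
    }
  }
  invisible(x)
}

#' Elderly walking model
#'
#' @param accepted_minutes walk time the elderly accept, minutes, > 0.
#' @param speed_min,speed_max elderly walking speed range in m/min
#'   (default 50-60).
#' @return a `walk_model` list.
#' @export
walk_model <- function(accepted_minutes, speed_min = 50, speed_max = 60) {
  if (!is.numeric(accepted_minutes) || accepted_minutes <= 0) {
    stop("accepted_minutes must be positive", call. = FALSE)
  }
  if (!(speed_min > 0 && speed_min <= speed_max)) {
    stop("need 0 < speed_min <= speed_max", call. = FALSE)
  }
  structure(list(accepted_minutes = accepted_minutes,
                 speed_min = speed_min, speed_max = speed_max),
            class = "walk_model")
}

#' Convert accepted walk time to a service-radius interval
#'
#' Walkable distance is walk time times walking speed, so an accepted
#' 5-minute walk at 50-60 m/min yields a 250-300 m clinic radius (and a
#' 10-minute walk the 500-600 m center radius). The pipeline adopts the
#' upper end of the interval as the working radius.
#'
#' @param walk a [walk_model()].
#' @return named numeric `c(lower, upper)` in meters.
#' @export
#' @examples
#' derive_service_radius(walk_model(5))   # 250 300
derive_service_radius <- function(walk) {
  stopifnot(inherits(walk, "walk_model"))
  c(lower = walk$accepted_minutes * walk$speed_min,
    upper = walk$accepted_minutes * walk$speed_max)
}

#' Required survey sample size (finite population)
#'
#' Cochran's formula at maximum variance, `n0 = z^2 * 0.25 / margin^2`, with
#' the finite-population correction `n = n0 / (1 + (n0 - 1) / population)`,
#' rounded up.
#'
#' @param population community population size (>= 1).
#' @param confidence confidence level, in (0, 1); default 0.95.
#' @param margin margin of error as a fraction, in (0, 1); default 0.05.
#' @return required number of respondents (integer).
#' @export
#' @examples
#' sample_size(100000)  # 383
sample_size <- function(population, confidence = 0.95, margin = 0.05) {
  if (!is.numeric(population) || population < 1) {
    stop("population must be at least 1", call. = FALSE)
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(margin) || margin <= 0 || margin >= 1) {
    stop("margin must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * 0.25 / margin^2
  as.integer(ceiling(n0 / (1 + (n0 - 1) / population)))
}

#' Read / write a survey response CSV
#'
#' One row per respondent with the enumerated questionnaire codes.
#' @param path CSV path.
#' @return data frame of responses.
#' @export
read_survey <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_survey
#' @param responses data frame of responses.
#' @export
write_survey <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
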