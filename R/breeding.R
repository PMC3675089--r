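#' @title Egg development, nestling growth, predation and the annual cycle
#' @name breeding
NULL

#' Degree-day requirement for hatching
#'
#' `D_req = MINDAYSTOHATCH * (EGGTEMP - MD_THRESHOLD)` in degC-days: a clutch
#' incubated continuously at the incubation temperature hatches after exactly
#' `MINDAYSTOHATCH` days.
#'
#' @param params a `skylark_params` object.
#' @return required accumulated development (degC-days).
#' @export
egg_dev_requirement <- function(params = skylark_params()) {
  params$MINDAYSTOHATCH * (params$EGGTEMP - params$MD_THRESHOLD)
}

#' Create a clutch
#' @param eggs number of eggs.
#' @param params a `skylark_params` object.
#' @return a `clutch` list: `eggs`, `t_egg`, `dev` (degC-days), `days`,
#'   `alive`, `hatched`.
#' @export
new_clutch <- function(eggs, params = skylark_params()) {
  list(eggs = eggs, t_egg = params$EGGTEMP, dev = 0, days = 0L,
       alive = TRUE, hatched = FALSE)
}

## development (degC-hours) accrued during one off-bout of tau hours,
## egg cooling exponentially from EGGTEMP towards ambient
trip_development <- function(tau_hours, ambient, params) {
  egg <- params$EGGTEMP; md <- params$MD_THRESHOLD
  k <- params$COOLING_RATE_EGGS
  if (tau_hours <= 0) return(0)
  if (k <= 0) return(max(0, egg - md) * tau_hours)
  A <- ambient - md          # asymptotic excess over the threshold
  B <- egg - ambient         # initial gradient to ambient
  if (A >= 0) {
    t_m <- tau_hours
  } else {
    if (B <= -A) return(0)   # egg starts at or below the threshold
    t_m <- min(tau_hours, log(B / (-A)) / k)
  }
  A * t_m + B * (1 - exp(-k * t_m)) / k
}

#' One day of incubation
#'
#' The day is partitioned into incubated time (egg at `EGGTEMP`) and
#' `n_trips` off-bouts of `TRIPLENGTH` minutes during which the egg cools
#' exponentially towards ambient at rate `COOLING_RATE_EGGS` per hour
#' (closed form within each bout; rewarming on return is instantaneous).
#' Development accrues as the time integral of the temperature excess over
#' `MD_THRESHOLD`, in degC-days; the clutch hatches when accumulated
#' development reaches [egg_dev_requirement()].
#'
#' @param clutch a [new_clutch()].
#' @param n_trips number of foraging trips today.
#' @param ambient ambient temperature (degC).
#' @param params a `skylark_params` object.
#' @return the updated clutch (`dev`, `days`, `hatched`).
#' @export
incubation_step <- function(clutch, n_trips, ambient,
                            params = skylark_params()) {
  stopifnot(clutch$alive, !clutch$hatched)
  tau <- params$TRIPLENGTH / 60
  off <- min(24, n_trips * tau)
  on_dev <- max(0, params$EGGTEMP - params$MD_THRESHOLD) * (24 - off)
  off_dev <- n_trips * trip_development(tau, ambient, params)
  clutch$dev <- clutch$dev + (on_dev + off_dev) / 24
  clutch$days <- clutch$days + 1L
  if (clutch$dev >= egg_dev_requirement(params)) clutch$hatched <- TRUE
  clutch
}

#' Incubation length under a fixed daily trip schedule
#'
#' Runs [incubation_step()] day by day and returns the fractional day on
#' which the degree-day requirement is met (linear interpolation within the
#' final day). With zero trips this equals `MINDAYSTOHATCH` for any ambient
#' temperature.
#'
#' @param n_trips trips per day.
#' @param ambient ambient temperature (degC).
#' @param params a `skylark_params` object.
#' @param max_days give up after this many days (returns `Inf`).
#' @return fractional days to hatching.
#' @export
incubation_days <- function(n_trips = 0, ambient = 15,
                            params = skylark_params(), max_days = 100) {
  cl <- new_clutch(4, params)
  req <- egg_dev_requirement(params)
  prev <- 0
  for (d in seq_len(max_days)) {
    cl <- incubation_step(cl, n_trips, ambient, params)
    if (cl$hatched) {
      inc <- cl$dev - prev
      return(d - 1 + (req - prev) / inc)
    }
    if (cl$dev <= prev) return(Inf)  # no progress: will never hatch
    prev <- cl$dev
  }
  Inf
}

#' Daily nest predation draw
#'
#' Destruction with daily probability `CLUTCH_MORT_PROB * MORT_PROB_SCALE`
#' (clutches) or `NEST_MORT_PROB * MORT_PROB_SCALE` (nestling broods),
#' independent across days. Uses the current RNG stream.
#'
#' @param stage `"clutch"` or `"nestling"`.
#' @param params a `skylark_params` object.
#' @return `TRUE` if the nest survives today.
#' @export
daily_predation_survives <- function(stage = c("clutch", "nestling"),
                                     params = skylark_params()) {
  stage <- match.arg(stage)
  p <- switch(stage,
              clutch = params$CLUTCH_MORT_PROB,
              nestling = params$NEST_MORT_PROB) * params$MORT_PROB_SCALE
  stats::runif(1) >= p
}

#' Create a brood of nestlings
#' @param n brood size.
#' @return a `brood` list: `n`, `age` (days), `mass` (g, per nestling),
#'   `starve_days`, `alive`, `left` (nest-leaving flag).
#' @export
new_brood <- function(n) {
  list(n = n, age = 0L, mass = 2.0, starve_days = 0L, alive = TRUE,
       left = FALSE)
}

#' One day of nestling growth and nest-leaving
#'
#' Per-nestling growth is `min(PEMAX, ASSIMILATION * food_delivered / n)`.
#' Growth below `STARVE_FRACTION * PEMAX` on `STARVE_DAYS` consecutive days
#' kills the brood ("other" mortality). From `MIN_LEAVE_AGE` the brood leaves
#' the nest with probability `NESTLEAVECHANCE` percent per day, and is forced
#' out at `MAX_LEAVE_AGE`. Uses the current RNG stream for the leaving draw.
#'
#' @param brood a [new_brood()].
#' @param food_delivered total food units delivered to the brood today.
#' @param params a `skylark_params` object.
#' @return updated brood; on leaving, `left = TRUE` and `age` is the nestling
#'   period (days from hatching to leaving).
#' @export
nestling_daily_step <- function(brood, food_delivered,
                                params = skylark_params()) {
  stopifnot(brood$alive, !brood$left)
  growth <- min(params$PEMAX,
                params$ASSIMILATION * food_delivered / brood$n)
  brood$mass <- brood$mass + growth
  if (growth < params$STARVE_FRACTION * params$PEMAX) {
    brood$starve_days <- brood$starve_days + 1L
  } else {
    brood$starve_days <- 0L
  }
  brood$age <- brood$age + 1L
  if (brood$starve_days >= params$STARVE_DAYS) {
    brood$alive <- FALSE
    return(brood)
  }
  if (brood$age >= params$MIN_LEAVE_AGE) {
    if (brood$age >= params$MAX_LEAVE_AGE ||
        stats::runif(1) < params$NESTLEAVECHANCE * params$PERCENT_SCALE) {
      brood$left <- TRUE
    }
  }
  brood
}

#' A female's daily foraging decision
#'
#' The daily requirement (maintenance plus thermoregulation surcharge plus
#' any brood share) is met by repeated trips of `TRIPLENGTH` minutes to the
#' best cell of the territory; trips taken are
#' `ceil(requirement / intake_per_trip)`, capped by the daylight budget
#' `MAX_TRIPS_PER_DAY`. A day on which the requirement cannot be met is a
#' deficit day.
#'
#' @param requirement food units needed today.
#' @param insect_food,accessibility per-cell vectors over the territory.
#' @param precipitation mm/day.
#' @param params a `skylark_params` object.
#' @return list: `trips`, `intake_per_trip`, `gained`, `deficit` (logical).
#' @export
female_daily_step <- function(requirement, insect_food, accessibility,
                              precipitation, params = skylark_params()) {
  per_trip <- foraging_intake(insect_food, accessibility, precipitation,
                              params$TRIPLENGTH, params)
  if (per_trip <= 0) {
    return(list(trips = 0L, intake_per_trip = 0, gained = 0,
                deficit = requirement > 0))
  }
  trips <- min(params$MAX_TRIPS_PER_DAY, ceiling(requirement / per_trip))
  gained <- trips * per_trip
  list(trips = as.integer(trips), intake_per_trip = per_trip, gained = gained,
       deficit = gained < requirement - 1e-9)
}

#' Daily adult food requirement
#'
#' Maintenance plus a cold-weather thermoregulation surcharge
#' `max(0, THERMO_THRESHOLD - mean_temp) * THERMO_SLOPE`, plus any brood
#' provisioning share.
#'
#' @param mean_temp daily mean temperature (degC).
#' @param brood_share food units of brood demand assigned to this adult.
#' @param params a `skylark_params` object.
#' @return food units.
#' @export
adult_requirement <- function(mean_temp, brood_share = 0,
                              params = skylark_params()) {
  params$ADULT_MAINTENANCE +
    max(0, params$THERMO_THRESHOLD - mean_temp) * params$THERMO_SLOPE +
    brood_share
}

#' Overwinter return survival between seasons
#'
#' Each adult returns next spring with probability
#' `1 - ADULTRETURNMORT/100`, each independent juvenile with
#' `1 - JUVRETURNMORT/100` (binomial draws from the current RNG stream).
#'
#' @param n_adults,n_juveniles counts at the end of the season.
#' @param params a `skylark_params` object.
#' @return list `adults`, `juveniles`: numbers returning.
#' @export
season_cycle <- function(n_adults, n_juveniles, params = skylark_params()) {
  pa <- 1 - params$ADULTRETURNMORT * params$PERCENT_SCALE
  pj <- 1 - params$JUVRETURNMORT * params$PERCENT_SCALE
  list(adults = stats::rbinom(1, n_adults, max(0, min(1, pa))),
       juveniles = stats::rbinom(1, n_juveniles, max(0, min(1, pj))))
}
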