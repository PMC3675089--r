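p <- skylark_params()

test_that("uninterrupted incubation hatches at exactly the minimum time", {
  for (amb in c(-5, 5, 15, 25, 36.1)) {
    expect_equal(incubation_days(n_trips = 0, ambient = amb, params = p),
                 10.2, tolerance = 1e-9)
  }
  ## ambient at egg temperature: trips cause no development loss
  expect_equal(incubation_days(n_trips = 30, ambient = p$EGGTEMP, params = p),
               10.2, tolerance = 1e-9)
})

test_that("per-trip egg cooling matches a fine-step integration of the ODE", {
  tau <- p$TRIPLENGTH / 60
  for (amb in c(0, 10, 20, 25.8, 30)) {
    closed <- skylarksim:::trip_development(tau, amb, p)
    euler <- euler_trip_development(tau, amb, p)
    expect_equal(closed, euler, tolerance = 1e-3)
  }
  ## zero cooling rate: development continues at the full rate off nest
  p0 <- override_params(p, list(COOLING_RATE_EGGS = 0))
  expect_equal(skylarksim:::trip_development(tau, 5, p0),
               (p$EGGTEMP - p$MD_THRESHOLD) * tau)
})

test_that("trip-interrupted incubation is delayed but bounded", {
  d <- incubation_days(n_trips = 30, ambient = 10, params = p)
  expect_gt(d, 10.2)
  expect_lte(d, 17)
  ## more trips, longer incubation (monotone)
  dd <- vapply(c(0, 10, 20, 40), function(n)
    incubation_days(n, ambient = 10, params = p), numeric(1))
  expect_true(all(diff(dd) > 0))
  ## the integer hatch day (both first and last day included) is >= 11
  cl <- new_clutch(4, p)
  while (!cl$hatched) cl <- incubation_step(cl, 0, 15, p)
  expect_equal(cl$days, 11)
})

test_that("daily predation matches the binomial closed form", {
  p0 <- override_params(p, list(CLUTCH_MORT_PROB = 0))
  set.seed(5)
  expect_true(all(vapply(1:200, function(i)
    daily_predation_survives("clutch", p0), logical(1))))
  ## survival over 11 days at 0.035/day: (1 - 0.035)^11 ~ 0.676
  n <- 20000
  set.seed(7)
  surv <- vapply(seq_len(n), function(i)
    all(vapply(1:11, function(d) daily_predation_survives("clutch", p),
               logical(1))), logical(1))
  p_true <- (1 - 0.035)^11
  expect_lt(abs(mean(surv) - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  ## same seed, same fate sequence
  set.seed(11); a <- vapply(1:50, function(i)
    daily_predation_survives("nestling", p), logical(1))
  set.seed(11); b <- vapply(1:50, function(i)
    daily_predation_survives("nestling", p), logical(1))
  expect_identical(a, b)
})

test_that("nestling growth, starvation and nest leaving", {
  ## unlimited food: growth at PEMAX
  b <- new_brood(4)
  b2 <- nestling_daily_step(b, food_delivered = 1000, p)
  expect_equal(b2$mass - b$mass, 4.54)
  ## zero food for the consecutive-day limit kills the brood
  b <- new_brood(4)
  for (i in seq_len(p$STARVE_DAYS)) b <- nestling_daily_step(b, 0, p)
  expect_false(b$alive)
  ## leaving probability at the minimum age matches the binomial oracle
  n <- 10000
  set.seed(13)
  left <- 0L
  for (i in seq_len(n)) {
    b <- new_brood(3)
    b$age <- p$MIN_LEAVE_AGE - 1L
    b <- nestling_daily_step(b, 1000, p)
    if (b$left) left <- left + 1L
  }
  expect_lt(abs(left / n - 0.23), 3 * sqrt(0.23 * 0.77 / n))
  ## forced leaving at the maximum age
  b <- new_brood(3); b$age <- p$MAX_LEAVE_AGE - 1L
  set.seed(17)
  b <- nestling_daily_step(b, 1000, p)
  expect_true(b$left)
})

test_that("female foraging decision arithmetic", {
  ## requirement of exactly one trip's intake: one trip
  per_trip <- 100 * p$EXTRACTION_RATE * p$TRIPLENGTH
  fs <- female_daily_step(per_trip, 100, 1, 0, p)
  expect_equal(fs$trips, 1L)
  expect_false(fs$deficit)
  ## rain at the gate: zero intake, full deficit day
  fs2 <- female_daily_step(5, 100, 1, p$MAXFEEDRAIN, p)
  expect_equal(fs2$trips, 0L)
  expect_true(fs2$deficit)
  ## fixed scenario: food 100, accessibility 1, requirement 2.65,
  ## 10-minute trips -> ceil(2.65 / 0.53) = 5 trips
  p10 <- override_params(p, list(TRIPLENGTH = 10))
  fs3 <- female_daily_step(2.65, 100, 1, 0, p10)
  expect_equal(fs3$trips, 5L)
  ## thermoregulation surcharge below the threshold
  expect_equal(adult_requirement(5, 0, p),
               p$ADULT_MAINTENANCE + 5 * p$THERMO_SLOPE)
  expect_equal(adult_requirement(20, 3, p), p$ADULT_MAINTENANCE + 3)
})

test_that("overwinter return mortality matches the binomial closed form", {
  p100 <- override_params(p, list(ADULTRETURNMORT = 100))
  set.seed(19)
  expect_equal(season_cycle(500, 0, p100)$adults, 0)
  set.seed(23)
  back <- season_cycle(1000, 0, p)$adults
  expect_lt(abs(back - 650), 3 * sqrt(1000 * 0.65 * 0.35))
  ## juveniles independent of adults
  set.seed(29)
  r <- season_cycle(0, 2000, p)
  expect_equal(r$adults, 0)
  expect_lt(abs(r$juveniles - 1300), 3 * sqrt(2000 * 0.65 * 0.35))
})

test_that("higher clutch predation weakly increases the predated share", {
  ## Monte-Carlo over 11-day exposures under two predation levels
  sim_share <- function(prob, n = 4000, seed = 41) {
    pp <- override_params(p, list(CLUTCH_MORT_PROB = prob))
    set.seed(seed)
    pred <- 0L
    for (i in seq_len(n)) {
      ok <- TRUE
      for (d in 1:11) if (!daily_predation_survives("clutch", pp)) {
        ok <- FALSE; break
      }
      if (!ok) pred <- pred + 1L
    }
    pred / n
  }
  expect_lte(sim_share(100), sim_share(350))
  expect_lte(sim_share(350), sim_share(800))
})
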