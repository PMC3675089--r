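test_that("operations fire inside their window subject to the weather gate", {
  plans <- list(test_crop = list(
    crop = "test_crop", curve = "spring_barley",
    operations = list(farm_operation("sow", c(100, 101), prob = 1,
                                     max_precip = 2, reset = "sow"))))
  fm <- farm(1L, "arable", fields = 10L, rotation = "test_crop")
  done <- matrix(FALSE, 1, 1)
  ## certain event on the first eligible dry day
  set.seed(1)
  res <- step_farm_day(fm, "test_crop", done, doy = 100, precipitation = 0,
                       plans = plans)
  expect_equal(res$executed$kind, "sow")
  ## deferred above the weather gate
  res2 <- step_farm_day(fm, "test_crop", done, doy = 100, precipitation = 5,
                        plans = plans)
  expect_equal(nrow(res2$executed), 0)
  ## outside the window nothing happens
  res3 <- step_farm_day(fm, "test_crop", done, doy = 99, precipitation = 0,
                        plans = plans)
  expect_equal(nrow(res3$executed), 0)
})

test_that("daily attempt probability matches the binomial closed form", {
  plans <- list(tc = list(crop = "tc", curve = "spring_barley",
                          operations = list(farm_operation(
                            "mow", c(1, 2), prob = 0.5, max_precip = 10))))
  fm <- farm(1L, "arable", fields = 1L, rotation = "tc")
  n <- 10000
  set.seed(99)
  fired_day1 <- 0L
  for (i in seq_len(n)) {
    res <- step_farm_day(fm, "tc", matrix(FALSE, 1, 1), doy = 1,
                         precipitation = 0, plans = plans)
    if (nrow(res$executed)) fired_day1 <- fired_day1 + 1L
  }
  phat <- fired_day1 / n
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("operation effects: tramline clock, vegetation reset, idempotence", {
  p <- skylark_params()
  curve <- default_growth_curves()$spring_barley
  spray <- farm_operation("spray_other", c(140, 160), 0.4,
                          opens_tramlines = TRUE)
  veg <- list(height = 50, density = 15, biomass = 300, is_patchy = FALSE,
              crop = "spring_barley")
  up <- apply_operation(spray, veg, curve, day = 1000, tram_until = -Inf,
                        params = p)
  expect_equal(up$tram_until, 1000 + 21)   # TRAMLINE_DECAYTIME
  expect_equal(up$veg, veg)                # sprays do not reset vegetation
  ## harvest resets, and is idempotent on an already-reset polygon
  harv <- farm_operation("harvest", c(225, 250), 0.4,
                         reset = list(height = 10, density = 5, biomass = 40))
  v1 <- apply_operation(harv, veg, curve, 1, -Inf, p)$veg
  v2 <- apply_operation(harv, v1, curve, 2, -Inf, p)$veg
  expect_equal(v1[c("height", "density", "biomass")],
               list(height = 10, density = 5, biomass = 40))
  expect_equal(v2, v1)
  ## sowing re-initialises the growth curve
  sow <- farm_operation("sow", c(95, 115), 0.5, reset = "sow")
  vs <- apply_operation(sow, veg, curve, 1, -Inf, p)$veg
  expect_equal(vs$biomass, curve$b0)
})

test_that("organic plans never contain spray operations", {
  for (pl in default_crop_plans(organic = TRUE)) {
    kinds <- vapply(pl$operations, `[[`, "", "kind")
    expect_false(any(grepl("spray", kinds)))
    ## and operations stay ordered by window start
    starts <- vapply(pl$operations, function(o) o$window[1], numeric(1))
    expect_true(!is.unsorted(starts))
  }
})

test_that("phased rotations hit long-run crop area targets", {
  ## one crop: grown every year everywhere
  r1 <- assign_rotations(1:3, c(spring_barley = 1))
  expect_true(all(r1$rotation == "spring_barley"))
  ## two crops 50/50 over 2 equal fields: each year each crop on one field
  r2 <- assign_rotations(1:2, c(a = 0.5, b = 0.5))
  fm <- farm(1L, "arable", 1:2, r2$rotation, r2$phases)
  for (yr in 0:5) {
    crops <- farm_year_crops(fm, yr)
    expect_setequal(crops, c("a", "b"))
  }
  ## 3 crops over 7 unequal fields: 21-year mean areas match targets within
  ## the largest single-field area (exhaustive check of the phase assignment)
  areas <- c(2, 3, 4, 5, 6, 7, 8) * 1e4
  targets <- c(a = 0.5, b = 0.3, cc = 0.2)
  r3 <- assign_rotations(1:7, targets)
  fm3 <- farm(1L, "arable", 1:7, r3$rotation, r3$phases)
  tot <- stats::setNames(numeric(3), names(targets))
  for (yr in 0:20) {
    crops <- farm_year_crops(fm3, yr)
    for (i in 1:7) tot[crops[i]] <- tot[crops[i]] + areas[i]
  }
  mean_area <- tot / 21
  target_area <- targets / sum(targets) * sum(areas)
  expect_true(all(abs(mean_area - target_area) <= max(areas)))
  expect_error(assign_rotations(1:3, c(a = -1, b = 2)), "negative")
})
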