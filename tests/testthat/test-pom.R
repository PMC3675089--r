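test_that("regression through the origin matches brute-force least squares", {
  r <- regression_origin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  r2 <- regression_origin(1:3, 1:3)
  expect_equal(r2$slope, 1)
  expect_equal(r2$r2, 1)
  ## worked case: b = sum(xy)/sum(x^2) = 29/14, R2 from the stated formula
  x <- c(1, 2, 3); y <- c(2, 3, 7)
  r3 <- regression_origin(x, y)
  expect_equal(r3$slope, 29 / 14)
  expect_equal(r3$slope, brute_origin_slope(x, y), tolerance = 1e-6)
  expect_equal(r3$r2, 1 - sum((y - 29 / 14 * x)^2) / sum((y - mean(y))^2))
  ## random instances against the brute-force minimiser
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- stats::runif(n, 0.1, 5)
    y <- 1.5 * x + stats::rnorm(n)
    rr <- regression_origin(x, y)
    expect_equal(rr$slope, brute_origin_slope(x, y), tolerance = 1e-6)
  }
  expect_error(regression_origin(c(0, 0), c(1, 2)), "all-zero")
})

test_that("R2 can be negative for a poor origin fit", {
  r <- regression_origin(c(1, 2, 3), c(10, 2, -4))
  expect_lt(r$r2, 0)
})

test_that("distribution SSD: zero at equality, max 2 at disjoint masses", {
  v <- c(`9` = 0.25, `10` = 0.5, `11` = 0.25, predated = 0, other = 0)
  expect_equal(ssd_distribution_fit(v, v)$ssd, 0)
  a <- c(`9` = 1, `17` = 0, predated = 0)
  b <- c(`9` = 0, `17` = 1, predated = 0)
  fit <- ssd_distribution_fit(a, b)
  expect_equal(fit$ssd, 2)
  expect_equal(fit$scaled, 1)
  ## moving 0.1 of mass between two bins costs 0.02
  c1 <- c(`9` = 0.5, `10` = 0.5)
  c2 <- c(`9` = 0.4, `10` = 0.6)
  expect_equal(ssd_distribution_fit(c1, c2)$ssd, 0.02)
  ## symmetric in its arguments
  expect_equal(ssd_distribution_fit(c1, c2)$ssd,
               ssd_distribution_fit(c2, c1)$ssd)
  expect_error(ssd_distribution_fit(a, c1), "mismatch")
})

test_that("density-series scaling: perfect 0, extinct 1", {
  obs <- c(5, 5)
  expect_equal(density_series_fit(obs, obs), 0)
  expect_equal(density_series_fit(obs, c(0, 0)), 1)
  expect_equal(density_series_fit(obs, c(4, 6)), 2 / 50)
  expect_equal(density_series_fit(obs, c(20, 20)), 1)  # clamped overshoot
  expect_error(density_series_fit(obs, c(1, 2, 3)), "dates mismatch")
  expect_error(density_series_fit(c(0, 0), c(1, 1)), "all zero")
})

test_that("scaled slope and R2 statistics", {
  expect_equal(scaled_slope_fit(1, 0.5), 0)
  expect_equal(scaled_slope_fit(0.5, 1), 0.5)
  expect_equal(scaled_slope_fit(-3, 1), 1)     # clamped
  expect_equal(scaled_r2_fit(0.8, 0.8), 0)
  expect_equal(scaled_r2_fit(0.4, 0.8), 0.5)
  expect_equal(scaled_r2_fit(-2, 0.8), 1)      # clamped
  expect_error(scaled_slope_fit(1, 0), "positive")
})

test_that("overall fit respects the (2,2,1) weighting identities", {
  nm <- c("bjerringbro_slope", "bjerringbro_r2", "hatch_fit",
          "nest_leaving_fit", "density_no_scrapes", "density_with_scrapes")
  ## constant statistics are weight-invariant
  s <- stats::setNames(rep(0.37, 6), nm)
  expect_equal(overall_fit(s), 0.37)
  ## set means (0, 0, 1) -> (2*0 + 2*0 + 1*1)/5
  s2 <- stats::setNames(c(0, 0, 0, 0, 1, 1), nm)
  expect_equal(overall_fit(s2), 0.2)
  ## unweighted fallback is the plain mean of set means
  expect_equal(overall_fit(s2, weights = c(1, 1, 1)), 1 / 3)
  ## zero iff all six are zero
  expect_equal(overall_fit(stats::setNames(rep(0, 6), nm)), 0)
  s3 <- stats::setNames(c(0.01, rep(0, 5)), nm)
  expect_gt(overall_fit(s3), 0)
  expect_error(overall_fit(stats::setNames(c(2, rep(0, 5)), nm)), "\\[0,1\\]")
  expect_error(overall_fit(s[1:5]), "missing statistic")
})

test_that("perturbation grids: percent steps and integer steps", {
  v <- perturbation_values(100, integer = FALSE)
  expect_equal(unname(v), c(60, 80, 90, 95, 105, 110, 120, 140))
  ## an integer parameter at 23 is tested at 15,19,21,22,24,25,27,31
  vi <- perturbation_values(23, integer = TRUE)
  expect_equal(unname(vi), c(15, 19, 21, 22, 24, 25, 27, 31))
})

test_that("sensitivity scan classifies runner-ignored parameters insensitive", {
  runner <- analytic_runner()
  scan <- sensitivity_scan(runner, parameters = c("HQHEDGE", "PEMAX",
                                                  "MINDAYSTOHATCH"))
  s <- scan$summary
  ## HQHEDGE does not enter the analytic runner at all
  expect_equal(s$max_deviation[s$parameter == "HQHEDGE"], 0)
  expect_true(s$insensitive[s$parameter == "HQHEDGE"])
  ## a 40% change in PEMAX moves its statistic by 0.4 -> sensitive
  expect_gt(s$max_deviation[s$parameter == "PEMAX"], 0.1)
  expect_false(s$insensitive[s$parameter == "PEMAX"])
  ## 8 perturbations per parameter, all statistics within [0,1]
  expect_equal(nrow(scan$table), 3 * 8)
  expect_true(all(scan$table$overall >= 0 & scan$table$overall <= 1))
  ## runner failures name the offending parameter
  bad <- function(p) if (p$PEMAX != 4.54) stop("boom") else analytic_runner()(p)
  expect_error(sensitivity_scan(bad, parameters = "PEMAX"), "PEMAX")
})

test_that("guided scan ranks candidates by overall fit", {
  runner <- analytic_runner()
  g <- guided_scan(runner, skylark_params(),
                   list(list(PEMAX = 4.54), list(PEMAX = 6), list(PEMAX = 9)))
  expect_equal(g$overall, sort(g$overall))
  expect_equal(g$candidate[1], 1)  # the fitted value wins
})

test_that("pattern files load and validate", {
  f <- system.file("extdata", "kalo_scrape_pairs.csv", package = "skylarksim")
  x <- load_pattern_pairs(f)
  expect_equal(x$pairs, c(8, 17, 17, 13))
  expect_equal(mean(x$pairs), 13.75)
  d <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(bin = c("9", "10", "predated", "other"),
                              proportion = c(0.5, 0.3, 0.1, 0.1)),
                   d, row.names = FALSE)
  v <- load_pattern_distribution(d)
  expect_equal(sum(v), 1)
  utils::write.csv(data.frame(bin = "9", proportion = 0.5), d,
                   row.names = FALSE)
  expect_error(load_pattern_distribution(d), "sum to 1")
})
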