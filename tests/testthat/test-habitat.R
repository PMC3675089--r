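p <- skylark_params()

test_that("habitat score bands and premiums", {
  ## bare earth below 3 cm
  expect_equal(habitat_score_cell(2, 0, "field", params = p), 3)
  ## hedgerows and tall vegetation
  expect_equal(habitat_score_cell(400, 80, "hedgerow", params = p), -250)
  expect_equal(habitat_score_cell(30, 5, "hedgerow", params = p), -250)
  expect_equal(habitat_score_cell(350, 40, "field", params = p), -250)
  expect_equal(habitat_score_cell(250, 40, "field", params = p), -10)
  expect_equal(habitat_score_cell(150, 40, "field", params = p), -2)
  ## at both thresholds the power-law factors are 1: score = q0
  expect_equal(habitat_score_cell(p$HEIGHTCONST_C, p$DENSITYCONST_C, "field",
                                  params = p), p$Q0_CROP_SCORE)
  ## numeric oracle for the power law: 40 * (76/38)^(-0.22)
  expect_equal(habitat_score_cell(76, 10, "field", params = p),
               40 * (76 / 38)^(-0.22), tolerance = 1e-12)
  expect_equal(40 * (76 / 38)^(-0.22), 34.34, tolerance = 1e-2)
  ## premiums are additive
  expect_equal(habitat_score_cell(50, 10, "field", is_patchy = TRUE,
                                  tramlines_open = TRUE, has_scrapes = TRUE,
                                  params = p),
               40 * (50 / 38)^(-0.22) + 47 + 6 + 0.24)
})

test_that("vectorised polygon scoring matches the per-cell function", {
  set.seed(2)
  n <- 300
  h <- stats::runif(n, 0, 350)
  d <- stats::runif(n, 0, 80)
  elem <- sample(element_types(), n, replace = TRUE)
  patchy <- stats::runif(n) < 0.3
  tram <- stats::runif(n) < 0.3
  scrape <- stats::runif(n) < 0.2
  vec <- skylarksim:::score_polys(h, d, elem, patchy, tram, scrape, p)
  scal <- vapply(seq_len(n), function(i)
    habitat_score_cell(h[i], d[i], elem[i], patchy[i], tram[i], scrape[i], p),
    numeric(1))
  expect_equal(vec, scal, tolerance = 1e-12)
})

test_that("foraging accessibility: thresholds, slopes, tramline relief", {
  ## at the height threshold accessibility is full
  expect_equal(foraging_accessibility(38, 5, FALSE, p), 1)
  ## linear decline: h = 78 -> a_h = 1 - 0.025*40 = 0
  expect_equal(foraging_accessibility(78, 5, FALSE, p), 0)
  ## with tramlines the hindrance is reduced by TRAMLINE_FORAGING
  expect_equal(foraging_accessibility(78, 5, TRUE, p), 0.45)
  ## always within [0, 1]
  hh <- seq(0, 400, by = 10); dd <- seq(0, 100, by = 10)
  gridv <- expand.grid(h = hh, d = dd)
  acc <- foraging_accessibility(gridv$h, gridv$d, FALSE, p)
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("rain hindrance follows the stated power curve", {
  expect_equal(rain_hindrance(0, p), 0)
  expect_equal(rain_hindrance(4.7, p), 1)
  expect_equal(rain_hindrance(10, p), 1)
  expect_equal(rain_hindrance(2.35, p), 0.5^4)
})

test_that("foraging intake arithmetic", {
  expect_equal(foraging_intake(100, 1, 0, 0, p), 0)
  expect_equal(foraging_intake(100, 1, 0, 10, p), 100 * 0.00053 * 10)
  ## rain at or above the gate stops foraging entirely
  expect_equal(foraging_intake(100, 1, 4.7, 600, p), 0)
  ## the best cell is used first
  expect_equal(foraging_intake(c(50, 100, 80), c(1, 0.5, 1), 0, 10, p),
               80 * 0.00053 * 10)
})

test_that("territory evaluation against arithmetic oracles", {
  ## uniform bare earth: 10,000 m2 at 3/m2 = 30,000 < 300,000 -> rejected
  cells <- matrix(1L, 150, 150)
  g <- landscape_grid(cells, data.frame(id = 1L, elem_type = "field"))
  sc_bare <- polygon_scores(g, height = 0, density = 0, is_patchy = FALSE,
                            tramlines_open = FALSE, has_scrapes = FALSE, p)
  ev <- evaluate_territory(g, sc_bare, c(75L, 75L), p)
  expect_equal(ev$total, 30000)
  expect_false(ev$acceptable)
  ## all hedge: negative total, rejected
  g2 <- landscape_grid(cells, data.frame(id = 1L, elem_type = "hedgerow"))
  sc_hedge <- polygon_scores(g2, 400, 80, FALSE, FALSE, FALSE, p)
  ev2 <- evaluate_territory(g2, sc_hedge, c(75L, 75L), p)
  expect_lt(ev2$total, 0)
  expect_false(ev2$acceptable)
  ## q0 + patchy premium = 50/m2 over 10,000 m2 = 500,000 -> accepted
  p50 <- override_params(p, list(PATCHYPREMIUM = 10))
  sc_good <- polygon_scores(g, 38, 10, TRUE, FALSE, FALSE, p50)
  expect_equal(sc_good, 50)
  ev3 <- evaluate_territory(g, sc_good, c(75L, 75L), p50)
  expect_equal(ev3$total, 500000)
  expect_true(ev3$acceptable)
})

test_that("territory acquisition is exclusive, best-first, and splits", {
  cells <- matrix(1L, 100, 100)  # exactly one 100x100 block at 1 m cells
  g <- landscape_grid(cells, data.frame(id = 1L, elem_type = "field"))
  ## zero acceptable candidates: all floaters
  sc_bad <- polygon_scores(g, 0, 0, FALSE, FALSE, FALSE, p)
  res <- acquire_territories(g, sc_bad, n_males = 3, params = p)
  expect_equal(length(res$territories), 0)
  expect_equal(res$n_floaters, 3)
  ## one acceptable block below the split threshold: exactly one territory
  sc_ok <- rep(40, 1)  # 400,000 < 2 x 300,000
  res2 <- acquire_territories(g, sc_ok, n_males = 2, params = p)
  expect_equal(length(res2$territories), 1)
  expect_equal(res2$n_floaters, 1)
  ## scoring >= 2x threshold with split multiplier 2: two territories
  sc_rich <- rep(65, 1)  # 650,000 >= 600,000; halves at 325,000 each
  res3 <- acquire_territories(g, sc_rich, n_males = 2, params = p)
  expect_equal(length(res3$territories), 2)
  expect_equal(res3$n_floaters, 0)
  ## split halves do not overlap
  r <- do.call(rbind, lapply(res3$territories, `[[`, "rect"))
  expect_false(skylarksim:::rects_overlap(r[1, ], r[2, , drop = FALSE]))
})

test_that("concurrent territories never overlap (random landscapes)", {
  set.seed(31)
  found_multi <- FALSE
  for (rep in 1:5) {
    nr <- sample(120:200, 1); nc <- sample(120:200, 1)
    npol <- 6
    cells <- matrix(sample.int(npol, nr * nc, replace = TRUE), nr, nc)
    tab <- data.frame(id = 1:npol,
                      elem_type = sample(c("field", "permanent_grass"),
                                         npol, replace = TRUE))
    g <- landscape_grid(cells, tab, cellsize = 2)
    scores <- stats::runif(npol, 20, 60)
    res <- acquire_territories(g, scores, n_males = 10, params = p)
    rects <- lapply(res$territories, `[[`, "rect")
    if (length(rects) >= 2) {
      found_multi <- TRUE
      for (i in seq_along(rects)) {
        others <- do.call(rbind, rects[-i])
        expect_false(skylarksim:::rects_overlap(rects[[i]], others))
      }
    }
  }
  expect_true(found_multi)
})
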