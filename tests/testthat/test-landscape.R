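make_tiny_grid <- function() {
  cells <- matrix(1L, 3, 3)
  landscape_grid(cells, data.frame(id = 1L, elem_type = "field"))
}

test_that("a single-polygon raster loads to one polygon of nine cells", {
  g <- make_tiny_grid()
  expect_equal(nrow(g$polygons), 1)
  expect_equal(g$polygons$n_cells, 9)
  expect_equal(g$polygons$area, 9)  # 1 m cells
})

test_that("unknown raster ids and duplicate polygon ids are errors", {
  cells <- matrix(c(1L, 1L, 2L, 1L), 2, 2)
  expect_error(landscape_grid(cells, data.frame(id = 1L, elem_type = "field")),
               "absent from the table")
  expect_error(landscape_grid(matrix(1L, 2, 2),
                              data.frame(id = c(1L, 1L),
                                         elem_type = c("field", "field"))),
               "duplicate")
  expect_error(landscape_grid(matrix(1L, 2, 2),
                              data.frame(id = 1L, elem_type = "lava")),
               "unknown element type")
})

test_that("landscapes round-trip through the raster + table files", {
  sc <- make_all_barley(0.25, seed = 4, cellsize = 4, years = 2)
  d <- tempfile()
  dir.create(d)
  write_landscape(sc$grid, file.path(d, "r.txt"), file.path(d, "p.csv"))
  g2 <- load_landscape(file.path(d, "r.txt"), file.path(d, "p.csv"),
                       plots = sc$grid$plots)
  expect_identical(g2$cells, sc$grid$cells)
  expect_equal(g2$polygons$elem_type, sc$grid$polygons$elem_type)
  expect_equal(g2$polygons$area, sc$grid$polygons$area)
  expect_identical(g2$plots, sc$grid$plots)
  ## malformed raster
  writeLines(c("ncols 3 nrows 2 cellsize 1", "1 1 1", "1 1"),
             file.path(d, "bad.txt"))
  expect_error(load_landscape(file.path(d, "bad.txt"), file.path(d, "p.csv")),
               "non-rectangular")
})

test_that("vegetation growth follows the temperature-scaled logistic", {
  curve <- default_growth_curves()$spring_barley
  ## at the base temperature the increment is zero
  v <- init_vegetation(curve)
  expect_identical(grow_vegetation(v, curve, curve$t_base), v)
  ## inert elements never change
  v0 <- init_vegetation(NULL)
  expect_identical(grow_vegetation(v0, NULL, 25), v0)
  hedge <- default_growth_curves()$hedgerow
  vh <- init_vegetation(hedge)
  expect_identical(grow_vegetation(vh, hedge, 25), vh)

  ## constant 15 degC from sowing: trajectory matches a brute-force
  ## integration of the stated logistic, is non-decreasing, and reaches the
  ## configured maximum within a season
  v <- init_vegetation(curve)
  traj <- numeric(150)
  b_oracle <- curve$b0
  tf <- max(0, 15 - curve$t_base) / curve$t_scale
  for (d in seq_len(150)) {
    v <- grow_vegetation(v, curve, 15)
    traj[d] <- v$height
    b_oracle <- b_oracle + curve$r * tf * b_oracle * max(0, 1 - b_oracle / curve$k)
  }
  expect_true(all(diff(traj) >= 0))
  expect_equal(v$biomass, b_oracle, tolerance = 1e-9)
  expect_gt(v$height, 0.99 * curve$max_height)
  expect_lte(v$height, curve$max_height)
})

test_that("insect food follows envelope x coefficient x saturation", {
  p <- skylark_params()
  ## no vegetation, no food
  expect_equal(update_insect_food(0, "field", 180, p), 0)
  ## linear in the element coefficient
  co <- default_insect_coefficients()
  co2 <- co; co2[["field"]] <- 2 * co[["field"]]
  f1 <- update_insect_food(200, "field", 150, p, coefficients = co)
  f2 <- update_insect_food(200, "field", 150, p, coefficients = co2)
  expect_equal(f2, 2 * f1)
  ## the midsummer peak day is the argmax over a constant-vegetation year
  series <- vapply(1:365, function(d) update_insect_food(200, "field", d, p),
                   numeric(1))
  expect_equal(which.max(series), p$INSECT_PEAK_DOY)
  ## monotone non-decreasing in biomass, all else equal
  bb <- seq(0, 500, by = 25)
  ff <- vapply(bb, function(b) update_insect_food(b, "field", 180, p),
               numeric(1))
  expect_true(all(diff(ff) >= 0))
  ## insecticide knock-down recovers linearly
  f_kd <- update_insect_food(200, "field", 180, p, days_since_spray = 0)
  f_half <- update_insect_food(200, "field", 180, p,
                               days_since_spray = p$INSECT_RECOVERY_DAYS / 2)
  f_full <- update_insect_food(200, "field", 180, p,
                               days_since_spray = p$INSECT_RECOVERY_DAYS)
  expect_equal(f_kd, series[180] * p$INSECT_KNOCKDOWN)
  expect_equal(f_half, mean(c(f_kd, f_full)))
  expect_equal(f_full, series[180])
})
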