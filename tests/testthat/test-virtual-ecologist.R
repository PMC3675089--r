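# hand-built event logs with known territory histories
log_row <- function(year, doy, event, id = NA, poly = NA, terr = NA,
                    cause = NA, value = NA) {
  data.frame(year = year, doy = doy, event = event, id = as.character(id),
             poly = as.integer(poly), terr = as.integer(terr),
             cause = as.character(cause), value = as.numeric(value),
             stringsAsFactors = FALSE)
}

test_that("census counts match a brute-force point-in-plot check", {
  ## territory 1: polygon 10, mated doy 120-200; territory 2: polygon 20,
  ## mated doy 140, abandoned doy 160; territory 3: unmated all season
  ev <- rbind(
    log_row(1, 110, "territory_acquired", terr = 1, poly = 10),
    log_row(1, 120, "pair_formed", terr = 1),
    log_row(1, 200, "territory_abandoned", terr = 1, poly = 10),
    log_row(1, 130, "territory_acquired", terr = 2, poly = 20),
    log_row(1, 140, "pair_formed", terr = 2),
    log_row(1, 160, "territory_abandoned", terr = 2, poly = 20),
    log_row(1, 115, "territory_acquired", terr = 3, poly = 10))
  plots <- list(A = c(10L), B = c(20L))
  visits <- c(100, 125, 150, 170, 205)
  mt <- map_territories(ev, plots, visits)
  a <- mt$census[mt$census$plot == "A", "pairs"]
  b <- mt$census[mt$census$plot == "B", "pairs"]
  ## brute force: pair counted iff paired <= v < abandoned and centre in plot
  expect_equal(a, c(0, 1, 1, 1, 0))
  expect_equal(b, c(0, 0, 1, 0, 0))
  expect_equal(mt$summary$max_pairs[mt$summary$plot == "A"], 1)
  expect_equal(mt$summary$max_pairs[mt$summary$plot == "B"], 1)
  ## no territories at all
  mt0 <- map_territories(log_row(1, 1, "year_end"), plots, visits)
  expect_true(all(mt0$census$pairs == 0))
  ## unknown plot polygons are an error
  expect_error(map_territories(ev, list(1, 2), visits), "named")
})

test_that("order of event-log records does not change census counts", {
  ev <- rbind(
    log_row(1, 110, "territory_acquired", terr = 1, poly = 10),
    log_row(1, 120, "pair_formed", terr = 1),
    log_row(1, 130, "territory_acquired", terr = 2, poly = 10),
    log_row(1, 131, "pair_formed", terr = 2),
    log_row(1, 180, "territory_abandoned", terr = 2, poly = 10))
  plots <- list(A = 10L)
  visits <- c(125, 150, 185)
  set.seed(3)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(map_territories(shuffled, plots, visits)$census$pairs,
               map_territories(ev, plots, visits)$census$pairs)
})

test_that("nest monitoring extracts lengths, fates and binned proportions", {
  ev <- rbind(
    log_row(41, 140, "incubation_start", id = "N1", poly = 1, terr = 1),
    log_row(41, 151, "hatch", id = "N1", poly = 1, terr = 1, value = 11),
    log_row(41, 159, "brood_leave", id = "N1", poly = 1, terr = 1, value = 8),
    log_row(41, 141, "incubation_start", id = "N2", poly = 1, terr = 2),
    log_row(41, 149, "clutch_predated", id = "N2", poly = 1, terr = 2),
    log_row(41, 150, "incubation_start", id = "N3", poly = 1, terr = 3),
    log_row(41, 161, "hatch", id = "N3", poly = 1, terr = 3, value = 11),
    log_row(41, 166, "brood_other", id = "N3", poly = 1, terr = 3,
            cause = "starved"))
  mn <- monitor_nests(ev, years = 41)
  expect_equal(nrow(mn$records), 3)
  expect_equal(mn$hatch_dist[["11"]], 2 / 3)
  expect_equal(mn$hatch_dist[["predated"]], 1 / 3)
  expect_equal(sum(mn$hatch_dist), 1)
  ## nestling-period distribution only over hatched nests
  expect_equal(mn$leave_dist[["8"]], 1 / 2)
  expect_equal(mn$leave_dist[["other"]], 1 / 2)
  ## single-outcome distribution: all clutches hatch on day 11
  ev1 <- ev[ev$id == "N1", ]
  mn1 <- monitor_nests(ev1, years = 41)
  expect_equal(mn1$hatch_dist[["11"]], 1)
})

test_that("nest monitoring defaults to the last 20 years of a longer log", {
  ev <- do.call(rbind, lapply(1:60, function(yr) rbind(
    log_row(yr, 140, "incubation_start", id = paste0("N", yr)),
    log_row(yr, 151, "hatch", id = paste0("N", yr), value = 11))))
  mn <- monitor_nests(ev)
  expect_equal(sort(unique(mn$records$year)), 41:60)
  expect_equal(nrow(mn$records), 20)
})

test_that("seasonal series averages per-date counts over years", {
  ev <- rbind(
    ## year 41: one pair on field 5 all season
    log_row(41, 100, "territory_acquired", terr = 1, poly = 5),
    log_row(41, 100, "pair_formed", terr = 1),
    ## year 42: two pairs, one abandoning mid-season
    log_row(42, 100, "territory_acquired", terr = 2, poly = 5),
    log_row(42, 101, "pair_formed", terr = 2),
    log_row(42, 100, "territory_acquired", terr = 3, poly = 5),
    log_row(42, 110, "pair_formed", terr = 3),
    log_row(42, 150, "territory_abandoned", terr = 3, poly = 5))
  ss <- seasonal_series(ev, 5L, visit_doys = c(120, 160), years = 41:42)
  expect_equal(ss$mean_pairs, c((1 + 2) / 2, (1 + 1) / 2))
  ## an empty field is all zeros
  ss0 <- seasonal_series(ev, 99L, visit_doys = c(120, 160), years = 41:42)
  expect_equal(ss0$mean_pairs, c(0, 0))
})
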