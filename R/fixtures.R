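#' @title Synthetic scenario generators
#' @description Seeded generators for the three study designs the model is
#'   exercised on: a multi-plot mixed-farmland landscape (territory-census
#'   protocol), an all-spring-barley landscape (nest-monitoring protocol),
#'   and the two-field skylark-scrape experiment (seasonal-series protocol).
#'   Every scenario is fully self-contained: given its seed it reproduces a
#'   run bit-for-bit.
#' @name fixtures
NULL

## assemble a grid from horizontal bands of vertical field strips, inside a
## hedgerow border; a hedgerow separator strip precedes a band only when the
## band sets `sep = TRUE` (e.g. between study plots, not between the fields
## of one open block of farmland)
band_landscape <- function(bands, cellsize, hedge_w = 4, plots = NULL) {
  ## bands: list of list(fields = widths in m, height = m, elem, crop, farm,
  ##                     scrapes (logical vector or FALSE), sep (logical))
  hedge_cells <- max(1L, round(hedge_w / cellsize))
  seps <- vapply(seq_along(bands), function(i)
    i > 1L && isTRUE(bands[[i]]$sep), logical(1))
  width_m <- max(vapply(bands, function(b) sum(b$fields), numeric(1)))
  ncol_cells <- ceiling(width_m / cellsize)
  rows_per_band <- vapply(bands, function(b)
    max(1L, as.integer(round(b$height / cellsize))), integer(1))
  nrow_cells <- sum(rows_per_band) + hedge_cells * (2L + sum(seps))
  cells <- matrix(0L, nrow_cells, ncol_cells + 2L * hedge_cells)
  polys <- list()
  pid <- 0L
  add_poly <- function(elem, farm = NA_integer_, crop = NA_character_,
                       scrapes = FALSE) {
    pid <<- pid + 1L
    polys[[pid]] <<- data.frame(id = pid, elem_type = elem, farm_id = farm,
                                crop = crop, has_scrapes = scrapes,
                                stringsAsFactors = FALSE)
    pid
  }
  hedge_id <- add_poly("hedgerow")
  cells[, ] <- hedge_id
  r <- hedge_cells
  band_fields <- vector("list", length(bands))
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    if (seps[bi]) r <- r + hedge_cells
    rr <- (r + 1L):(r + rows_per_band[bi])
    cc0 <- hedge_cells
    ids <- integer(length(b$fields))
    for (fi in seq_along(b$fields)) {
      w_cells <- max(1L, round(b$fields[fi] / cellsize))
      cc <- (cc0 + 1L):min(cc0 + w_cells, ncol(cells) - hedge_cells)
      scr <- if (length(b$scrapes) > 1) b$scrapes[fi] else isTRUE(b$scrapes)
      ids[fi] <- add_poly(b$elem, farm = b$farm, crop = b$crop, scrapes = scr)
      cells[rr, cc] <- ids[fi]
      cc0 <- cc0 + w_cells
    }
    band_fields[[bi]] <- ids
    r <- r + rows_per_band[bi]
  }
  ptab <- do.call(rbind, polys)
  grid <- landscape_grid(cells, ptab, cellsize = cellsize,
                         plots = plots %||% list())
  list(grid = grid, band_fields = band_fields)
}

#' All-spring-barley scenario (nest-monitoring protocol)
#'
#' A block of spring-barley fields run under one arable farm, monitored with
#' the nest protocol: incubation length and fate, nestling period and fate,
#' for the last 20 years of the run.
#'
#' @param area_km2 landscape area in km2 (>= 0.25).
#' @param seed scenario seed (landscape and weather).
#' @param cellsize cell size in metres.
#' @param years simulated years.
#' @param initial_pairs founding population (pairs).
#' @return a scenario list.
#' @export
make_all_barley <- function(area_km2 = 0.25, seed = 1, cellsize = 2,
                            years = 60, initial_pairs = 8) {
  stopifnot(area_km2 >= 0.25)
  side_m <- sqrt(area_km2) * 1000
  n_fields <- 4L
  bands <- list(
    list(fields = rep(side_m / 2, 2), height = side_m / 2, elem = "field",
         crop = "spring_barley", farm = 1L, scrapes = FALSE),
    list(fields = rep(side_m / 2, 2), height = side_m / 2, elem = "field",
         crop = "spring_barley", farm = 1L, scrapes = FALSE)
  )
  bl <- band_landscape(bands, cellsize)
  field_ids <- unlist(bl$band_fields)
  grid <- bl$grid
  grid$plots <- list(all_fields = field_ids)
  farms <- list(farm(1L, "arable", field_ids,
                     rotation = rep("spring_barley", n_fields)))
  list(name = "all_barley", grid = grid, farms = farms,
       params = skylark_params(), years = years, weather_seed = seed,
       weather_args = list(), initial_pairs = initial_pairs,
       protocol = "nests", seed = seed)
}

#' Two-field skylark-scrape experiment scenario (seasonal-series protocol)
#'
#' One 22 ha spring-barley field provided with unsown scrapes (~100 of
#' ~40 m2, represented as a per-field flag) and with tramlines kept open,
#' and one 35 ha spring-barley field without scrapes whose tramlines are
#' allowed to close; weekly territory mapping through the breeding season.
#'
#' @param seed scenario seed.
#' @param scrape_count number of scrapes on the treatment field (0 makes the
#'   two fields identical except for area).
#' @param cellsize cell size in metres.
#' @param years simulated years.
#' @param initial_pairs founding population (pairs).
#' @return a scenario list with `scrape_field` and `control_field` polygon
#'   ids and weekly `visit_doys`.
#' @export
make_scrape_experiment <- function(seed = 1, scrape_count = 100,
                                   cellsize = 2, years = 60,
                                   initial_pairs = 10) {
  height_m <- 500
  w_scrape <- 22 * 1e4 / height_m   # 440 m -> 22 ha
  w_control <- 35 * 1e4 / height_m  # 700 m -> 35 ha
  has_scr <- scrape_count > 0
  bands <- list(
    list(fields = c(w_scrape, w_control), height = height_m, elem = "field",
         crop = "spring_barley", farm = 1L, scrapes = c(has_scr, FALSE))
  )
  bl <- band_landscape(bands, cellsize)
  ids <- bl$band_fields[[1]]
  grid <- bl$grid
  grid$plots <- list(scrape_field = ids[1], control_field = ids[2])
  farms <- list(farm(1L, "arable", ids, rotation = c("spring_barley")))
  list(name = "scrape_experiment", grid = grid, farms = farms,
       params = skylark_params(), years = years, weather_seed = seed,
       initial_pairs = initial_pairs, protocol = "series",
       scrape_field = ids[1], control_field = ids[2],
       always_tram = if (has_scr) ids[1] else integer(0),
       visit_doys = seq(75, 184, by = 7), scrape_count = scrape_count,
       seed = seed)
}

#' Multi-plot mixed-farmland scenario (territory-census protocol)
#'
#' `plot_count` study plots of mixed conventional farmland, each a stack of
#' field strips averaging `mean_field_ha`, each plot farmed by its own farm
#' (types cycling pig / arable / mixed) with a rotation matched to common
#' crop shares; mapped eight times per season.
#'
#' @param plot_count number of study plots.
#' @param mean_field_ha mean field size (ha).
#' @param seed scenario seed.
#' @param cellsize cell size in metres.
#' @param years simulated years.
#' @param plot_area_range_ha plot areas drawn uniformly in this range.
#' @param initial_pairs founding population (default 2 pairs per plot).
#' @return a scenario list with named plots and 8 `visit_doys`.
#' @export
make_bjerringbro_like <- function(plot_count = 16, mean_field_ha = 3.9,
                                  seed = 1, cellsize = 4, years = 60,
                                  plot_area_range_ha = c(35, 59),
                                  initial_pairs = 2L * plot_count) {
  stopifnot(plot_count >= 1)
  set.seed(seed)
  plot_w_m <- 600
  bands <- list()
  plot_names <- sprintf("plot%02d", seq_len(plot_count))
  types <- rep(c("pig", "arable", "mixed"), length.out = plot_count)
  targets <- c(spring_barley = 0.45, winter_wheat = 0.35, grass_ley = 0.20)
  for (i in seq_len(plot_count)) {
    area_ha <- stats::runif(1, plot_area_range_ha[1], plot_area_range_ha[2])
    nf <- max(1L, round(area_ha / mean_field_ha))
    ## field strips: heights jittered around the mean, then rescaled so the
    ## mean field area is exact
    h <- stats::runif(nf, 0.7, 1.3)
    h <- h / sum(h) * (nf * mean_field_ha * 1e4 / plot_w_m)
    for (j in seq_len(nf)) {
      bands[[length(bands) + 1L]] <- list(
        fields = plot_w_m, height = h[j], elem = "field",
        crop = NA_character_, farm = i, scrapes = FALSE, plot = i,
        sep = (j == 1L))   # hedgerows between plots, open fields within
    }
  }
  bl <- band_landscape(bands, cellsize)
  plot_of_band <- vapply(bands, function(b) b$plot, numeric(1))
  plots <- lapply(seq_len(plot_count), function(i)
    unlist(bl$band_fields[plot_of_band == i]))
  names(plots) <- plot_names
  grid <- bl$grid
  grid$plots <- plots
  farms <- lapply(seq_len(plot_count), function(i) {
    flds <- plots[[i]]
    rot <- assign_rotations(flds, targets)
    farm(i, types[i], flds, rotation = rot$rotation, phases = rot$phases)
  })
  areas <- vapply(plots, function(p)
    sum(grid$polygons$area[match(p, grid$polygons$id)]) / 1e4, numeric(1))
  list(name = "bjerringbro_like", grid = grid, farms = farms,
       params = skylark_params(), years = years, weather_seed = seed,
       initial_pairs = initial_pairs, protocol = "census",
       plot_areas_ha = areas,
       visit_doys = round(seq(105, 208, length.out = 8)), seed = seed)
}

#' Write / read a scenario to a directory
#'
#' The landscape goes to `raster.txt` + `polygons.csv`; everything else
#' (farms, parameters, protocol, seeds) to `scenario.yml`; a `manifest.txt`
#' records the seed and content summary for reproducibility.
#'
#' @param scenario a scenario list.
#' @param dir output directory (created if needed).
#' @return `read_scenario` returns the scenario list.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape(scenario$grid, file.path(dir, "raster.txt"),
                  file.path(dir, "polygons.csv"))
  meta <- scenario
  meta$grid <- NULL
  meta$params <- unclass(scenario$params)
  meta$farms <- lapply(scenario$farms, unclass)
  meta$plots <- scenario$grid$plots
  yaml::write_yaml(meta, file.path(dir, "scenario.yml"))
  writeLines(c(
    sprintf("scenario: %s", scenario$name),
    sprintf("seed: %s", scenario$seed %||% NA),
    sprintf("polygons: %d", nrow(scenario$grid$polygons)),
    sprintf("cells: %d x %d @ %g m", scenario$grid$nrows,
            scenario$grid$ncols, scenario$grid$cellsize),
    sprintf("written: R %s, skylarksim %s", getRversion(),
            as.character(utils::packageVersion("skylarksim")))),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scenario.yml"))
  plots <- lapply(meta$plots, unlist)
  grid <- load_landscape(file.path(dir, "raster.txt"),
                         file.path(dir, "polygons.csv"), plots = plots)
  meta$plots <- NULL
  sc <- meta
  sc$grid <- grid
  sc$params <- do.call(skylark_params, meta$params)
  sc$farms <- lapply(meta$farms, function(fm)
    farm(fm$id, fm$type, unlist(fm$fields), unlist(fm$rotation),
         unlist(fm$phases)))
  for (k in c("always_tram", "visit_doys"))
    if (!is.null(sc[[k]])) sc[[k]] <- unlist(sc[[k]])
  sc
}

## ---- pattern extraction and the POM runner --------------------------------

#' Extract the scenario's observation-protocol patterns from a run
#'
#' Applies the scenario's virtual-ecologist protocol: `census` (per-plot
#' mean seasonal-maximum pair density), `nests` (hatch and nest-leaving
#' distributions), or `series` (per-date mean pairs on the scrape and
#' control fields).
#'
#' @param run a `skylark_run`.
#' @param scenario the scenario it came from.
#' @param years years to use (default: last 20 present, burn-in discarded).
#' @return a named list of pattern vectors.
#' @export
extract_patterns <- function(run, scenario, years = NULL) {
  ev <- run$events
  all_years <- sort(unique(ev$year))
  if (is.null(years)) years <- all_years[all_years > max(all_years) - 20L]
  if (identical(scenario$protocol, "census")) {
    mt <- map_territories(ev, scenario$grid$plots, scenario$visit_doys,
                          years = years,
                          plot_areas_ha = scenario$plot_areas_ha)
    dens <- stats::aggregate(density ~ plot, mt$summary, mean)
    list(plot_density = stats::setNames(dens$density, dens$plot))
  } else if (identical(scenario$protocol, "nests")) {
    mn <- monitor_nests(ev, years = years)
    list(hatch_dist = mn$hatch_dist, leave_dist = mn$leave_dist)
  } else if (identical(scenario$protocol, "series")) {
    s1 <- seasonal_series(ev, scenario$scrape_field, scenario$visit_doys,
                          years = years)
    s0 <- seasonal_series(ev, scenario$control_field, scenario$visit_doys,
                          years = years)
    list(series_with_scrapes = s1$mean_pairs,
         series_no_scrapes = s0$mean_pairs)
  } else stop("unknown protocol: ", scenario$protocol)
}

#' The six pattern-fit statistics from observed and modelled patterns
#'
#' @param observed,modelled pattern lists with `plot_density`, `hatch_dist`,
#'   `leave_dist`, `series_no_scrapes`, `series_with_scrapes`.
#' @param m_slope,m_r2 scaling constants for the slope and R2 statistics.
#' @return named numeric of the six scaled statistics, with the regression
#'   details (`slope`, `r2`) and scaling constants as attributes.
#' @export
pom_statistics <- function(observed, modelled, m_slope = 1, m_r2 = 1) {
  reg <- regression_origin(observed$plot_density, modelled$plot_density)
  worst <- 1
  hatch <- if (is.null(modelled$hatch_dist)) worst else
    ssd_distribution_fit(observed$hatch_dist, modelled$hatch_dist)$scaled
  leave <- if (is.null(modelled$leave_dist)) worst else
    ssd_distribution_fit(observed$leave_dist, modelled$leave_dist)$scaled
  out <- c(
    bjerringbro_slope = scaled_slope_fit(reg$slope, m_slope),
    bjerringbro_r2 = scaled_r2_fit(reg$r2, m_r2),
    hatch_fit = hatch,
    nest_leaving_fit = leave,
    density_no_scrapes = density_series_fit(observed$series_no_scrapes,
                                            modelled$series_no_scrapes),
    density_with_scrapes = density_series_fit(observed$series_with_scrapes,
                                              modelled$series_with_scrapes))
  attr(out, "details") <- list(slope = reg$slope, r2 = reg$r2,
                               m_slope = m_slope, m_r2 = m_r2)
  out
}

#' Bundle the three miniature pattern scenarios for scan work
#'
#' Miniature versions of the three study designs (few plots, the minimum
#' all-barley area, the two-field scrape experiment at coarse cells) with a
#' short horizon, plus synthetic "observed" patterns generated from a
#' baseline run at the default parameters. Problem sizes are deliberately
#' small so a full 30-parameter one-at-a-time scan stays cheap.
#'
#' @param seed bundle seed.
#' @param years simulated years per run.
#' @param window years of data used (the rest is burn-in).
#' @param obs_seed behavioural seed of the baseline run providing the
#'   synthetic observed patterns.
#' @return list with `scenarios`, `observed`, `years`, `window`.
#' @export
make_miniature_patterns <- function(seed = 1, years = 3, window = 2,
                                    obs_seed = 99) {
  scen <- list(
    census = make_bjerringbro_like(plot_count = 3, seed = seed, cellsize = 6,
                                   years = years,
                                   plot_area_range_ha = c(8, 14),
                                   initial_pairs = 6),
    nests = make_all_barley(0.25, seed = seed + 1, cellsize = 6,
                            years = years, initial_pairs = 8),
    series = make_scrape_experiment(seed = seed + 2, cellsize = 6,
                                    years = years, initial_pairs = 30))
  obs <- list()
  for (nm in names(scen)) {
    run <- simulate_skylarks(scen[[nm]], years = years, seed = obs_seed)
    win <- observation_window(run, window)
    obs <- c(obs, extract_patterns(run, scen[[nm]], years = win))
  }
  ## degenerate guards: a usable observed pattern set needs every component
  if (is.null(obs$hatch_dist) || sum(obs$series_no_scrapes) == 0)
    warning("baseline run produced an incomplete observed pattern set")
  list(scenarios = scen, observed = obs, years = years, window = window)
}

observation_window <- function(run, window) {
  yrs <- sort(unique(run$events$year))
  yrs[yrs > max(yrs) - window]
}

#' Build a six-statistic runner over the three pattern scenarios
#'
#' Returns `function(params) -> named six statistics`, suitable for
#' [sensitivity_scan()] and [guided_scan()]: it simulates the three
#' scenarios with the given parameters (same weather and behavioural seed
#' each call, so parameter effects are not confounded with RNG noise) and
#' scores the extracted patterns against the bundle's observed patterns.
#'
#' @param bundle from [make_miniature_patterns()].
#' @param sim_seed behavioural seed used for every run.
#' @param m_slope,m_r2 scaling constants.
#' @return a runner closure.
#' @export
make_pom_runner <- function(bundle, sim_seed = 7, m_slope = 1, m_r2 = 1) {
  force(bundle); force(sim_seed)
  function(params) {
    mod <- list()
    for (nm in names(bundle$scenarios)) {
      run <- simulate_skylarks(bundle$scenarios[[nm]],
                               years = bundle$years, seed = sim_seed,
                               params = params)
      win <- observation_window(run, bundle$window)
      mod <- c(mod, extract_patterns(run, bundle$scenarios[[nm]],
                                     years = win))
    }
    pom_statistics(bundle$observed, mod, m_slope = m_slope, m_r2 = m_r2)
  }
}
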