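#' @title Landscape grid, vegetation growth and insect food
#' @description The landscape is a rectangular raster of cells, each belonging
#'   to exactly one polygon; polygons carry an element type, an optional crop
#'   and farm, and a vegetation state updated daily. Named plots (sets of
#'   polygons) define the observation areas used by the census protocols.
#' @name landscape
NULL

.element_types <- c("field", "field_margin", "hedgerow", "woodland", "road",
                    "building", "water", "permanent_grass", "bare", "other")

#' Element types known to the landscape model
#' @return character vector of the 10 element types.
#' @export
element_types <- function() .element_types

#' Construct a landscape grid
#'
#' @param cells integer matrix (nrows x ncols) of polygon ids.
#' @param polygons data.frame with columns `id`, `elem_type`, and optionally
#'   `farm_id`, `crop`, `has_scrapes`.
#' @param cellsize cell edge length in metres (default 1).
#' @param plots named list of polygon-id vectors defining observation plots.
#' @return an object of class `landscape_grid`.
#' @export
landscape_grid <- function(cells, polygons, cellsize = 1, plots = list()) {
  stopifnot(is.matrix(cells))
  if (is.null(polygons$farm_id)) polygons$farm_id <- NA_integer_
  if (is.null(polygons$crop)) polygons$crop <- NA_character_
  if (is.null(polygons$has_scrapes)) polygons$has_scrapes <- FALSE
  if (anyDuplicated(polygons$id)) stop("duplicate polygon ids")
  bad <- setdiff(unique(as.vector(cells)), polygons$id)
  if (length(bad)) stop("raster contains polygon id(s) absent from the table: ",
                        paste(bad, collapse = ", "))
  if (!all(polygons$elem_type %in% .element_types))
    stop("unknown element type(s): ",
         paste(setdiff(polygons$elem_type, .element_types), collapse = ", "))
  for (p in plots) {
    if (!all(p %in% polygons$id)) stop("plot refers to unknown polygon id(s)")
  }
  idx <- match(as.vector(cells), polygons$id)
  n_cells <- tabulate(idx, nbins = nrow(polygons))
  polygons$n_cells <- n_cells
  polygons$area <- n_cells * cellsize^2
  structure(list(
    nrows = nrow(cells), ncols = ncol(cells), cellsize = cellsize,
    cells = cells, poly_index = matrix(idx, nrow(cells), ncol(cells)),
    polygons = polygons, plots = plots
  ), class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("<landscape_grid> ", x$nrows, "x", x$ncols, " cells (",
      x$cellsize, " m), ", nrow(x$polygons), " polygons, ",
      length(x$plots), " plots; total ",
      round(x$nrows * x$ncols * x$cellsize^2 / 1e4, 1), " ha\n", sep = "")
  invisible(x)
}

#' Write a landscape to plain-text files
#'
#' The raster is an integer grid with a one-line header
#' (`ncols <n> nrows <n> cellsize <m>`) followed by one row of ids per line,
#' row-major from the top-left. Polygon attributes go to a CSV with a header.
#'
#' @param grid a `landscape_grid`.
#' @param raster_path,table_path output paths.
#' @export
write_landscape <- function(grid, raster_path, table_path) {
  con <- file(raster_path, "w")
  on.exit(close(con))
  writeLines(sprintf("ncols %d nrows %d cellsize %g",
                     grid$ncols, grid$nrows, grid$cellsize), con)
  writeLines(apply(grid$cells, 1, paste, collapse = " "), con)
  tab <- grid$polygons[, c("id", "elem_type", "farm_id", "crop", "has_scrapes")]
  utils::write.csv(tab, table_path, row.names = FALSE)
  invisible(grid)
}

#' Load a landscape from a raster file and polygon attribute table
#'
#' @param raster_path path to the integer raster (see [write_landscape()]).
#' @param table_path path to the polygon attribute CSV.
#' @param plots optional named list of polygon-id vectors.
#' @return a validated `landscape_grid`; raster ids absent from the table are
#'   an error.
#' @export
load_landscape <- function(raster_path, table_path, plots = list()) {
  lines <- readLines(raster_path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 6 || any(hdr[c(1, 3, 5)] != c("ncols", "nrows", "cellsize")))
    stop("malformed raster header: ", lines[1])
  ncols <- as.integer(hdr[2]); nrows <- as.integer(hdr[4])
  cellsize <- as.numeric(hdr[6])
  rows <- lapply(lines[-1][seq_len(nrows)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(rows) != ncols)) stop("non-rectangular raster")
  cells <- do.call(rbind, rows)
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  if (!is.null(tab$has_scrapes)) tab$has_scrapes <- as.logical(tab$has_scrapes)
  landscape_grid(cells, tab, cellsize = cellsize, plots = plots)
}

## ---- vegetation growth ----------------------------------------------------

#' Default vegetation growth curves
#'
#' Each curve is a logistic in biomass with a temperature factor
#' `max(0, mean_temp - t_base) / t_scale` scaling the daily increment; height
#' and density are monotone (linear in biomass) up to crop-specific maxima.
#' Static elements (hedgerow, woodland) have fixed structure; inert elements
#' (road, building, water, bare) carry no curve.
#'
#' @return named list of curves with fields `r` (intrinsic daily rate),
#'   `k` (biomass ceiling), `b0` (biomass at sowing/season start),
#'   `t_base`, `t_scale` (degC), `max_height` (cm), `max_density` (0-100),
#'   `patchy` (logical), `static` (logical; fixed structure).
#' @export
default_growth_curves <- function() {
  curve <- function(r, k, b0, t_base, t_scale, max_h, max_d,
                    patchy = FALSE, static = FALSE)
    list(r = r, k = k, b0 = b0, t_base = t_base, t_scale = t_scale,
         max_height = max_h, max_density = max_d, patchy = patchy,
         static = static)
  list(
    spring_barley   = curve(0.25, 600, 5, 5, 25, 90, 25),
    winter_wheat    = curve(0.18, 800, 30, 4, 25, 100, 30),
    grass_ley       = curve(0.20, 400, 40, 4, 25, 60, 35),
    maize           = curve(0.20, 900, 5, 8, 25, 220, 35),
    set_aside       = curve(0.15, 400, 60, 4, 25, 70, 30, patchy = TRUE),
    permanent_grass = curve(0.15, 400, 100, 4, 25, 50, 35),
    field_margin    = curve(0.15, 400, 80, 4, 25, 80, 30, patchy = TRUE),
    hedgerow        = curve(0, 500, 500, 0, 25, 400, 80, static = TRUE),
    woodland        = curve(0, 800, 800, 0, 25, 1500, 80, static = TRUE)
  )
}

#' Advance a vegetation state by one day
#'
#' Biomass follows `dB = r * tf * B * (1 - B/k)` with temperature factor
#' `tf = max(0, mean_temp - t_base) / t_scale`; height and density are
#' `max_height * B/k` and `max_density * B/k`. Static curves and missing
#' curves (inert elements: road, building, water, bare) are no-ops.
#'
#' @param veg list with `height`, `density`, `biomass`, `is_patchy`, `crop`.
#' @param curve a growth curve from [default_growth_curves()], or `NULL`.
#' @param mean_temp daily mean temperature (degC).
#' @return the updated vegetation state.
#' @export
grow_vegetation <- function(veg, curve, mean_temp) {
  if (is.null(curve) || isTRUE(curve$static)) return(veg)
  tf <- max(0, mean_temp - curve$t_base) / curve$t_scale
  if (tf > 0 && veg$biomass > 0) {
    veg$biomass <- veg$biomass +
      curve$r * tf * veg$biomass * max(0, 1 - veg$biomass / curve$k)
    frac <- min(1, veg$biomass / curve$k)
    veg$height <- curve$max_height * frac
    veg$density <- curve$max_density * frac
  }
  veg
}

#' Initial vegetation state for a curve
#'
#' @param curve a growth curve or `NULL` (inert element).
#' @param crop crop id carried on the state (or `NA`).
#' @return a vegetation state list.
#' @export
init_vegetation <- function(curve, crop = NA_character_) {
  if (is.null(curve))
    return(list(height = 0, density = 0, biomass = 0, is_patchy = FALSE,
                crop = crop))
  frac <- min(1, curve$b0 / curve$k)
  list(height = curve$max_height * frac, density = curve$max_density * frac,
       biomass = curve$b0, is_patchy = isTRUE(curve$patchy), crop = crop)
}

## ---- insect food ----------------------------------------------------------

#' Default element-type coefficients for insect food
#' @return named numeric vector, one multiplier per element type.
#' @export
default_insect_coefficients <- function() {
  c(field = 1.0, field_margin = 1.5, hedgerow = 1.0, woodland = 0.5,
    road = 0, building = 0, water = 0, permanent_grass = 1.2, bare = 0.3,
    other = 0.5)
}

#' Seasonal insect envelope
#'
#' Triangular ramp opening at `INSECT_SEASON_START`, peaking at
#' `INSECT_PEAK_DOY` with value `INSECT_PEAK`, closing at `INSECT_SEASON_END`.
#'
#' @param doy day-of-year (vectorised).
#' @param params a `skylark_params` object.
#' @return food envelope (units/m2).
#' @export
insect_envelope <- function(doy, params) {
  s <- params$INSECT_SEASON_START; p <- params$INSECT_PEAK_DOY
  e <- params$INSECT_SEASON_END
  up <- (doy - s) / (p - s)
  down <- (e - doy) / (e - p)
  params$INSECT_PEAK * pmax(0, pmin(up, down, 1))
}

#' Daily insect food biomass for a polygon
#'
#' `insect_food = envelope(doy) * element coefficient * B/(B + K_half)`,
#' optionally reduced by an insecticide knock-down with linear recovery.
#'
#' @param veg_biomass vegetation biomass (units/m2).
#' @param elem_type element type string.
#' @param doy day-of-year.
#' @param params a `skylark_params` object.
#' @param coefficients named coefficient vector
#'   (default [default_insect_coefficients()]).
#' @param days_since_spray days since the last insecticide application, or
#'   `Inf` if none.
#' @return insect food (units/m2).
#' @export
update_insect_food <- function(veg_biomass, elem_type, doy, params,
                               coefficients = default_insect_coefficients(),
                               days_since_spray = Inf) {
  coef <- coefficients[[elem_type]]
  sat <- veg_biomass / (veg_biomass + params$INSECT_KHALF)
  food <- insect_envelope(doy, params) * coef * sat
  if (is.finite(days_since_spray)) {
    f <- params$INSECT_KNOCKDOWN
    rec <- min(1, days_since_spray / params$INSECT_RECOVERY_DAYS)
    food <- food * (f + (1 - f) * rec)
  }
  food
}
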