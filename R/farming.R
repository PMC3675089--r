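#' @title Farms, crop rotations and daily farm operations
#' @description Each farm owns fields and cycles a crop rotation with a
#'   per-field phase offset, so that over the years every field experiences
#'   every crop in the rotation's proportions. Each crop has a management plan
#'   of probabilistic, weather-gated operations that reset vegetation, knock
#'   down insects, open tramlines and may destroy nests.
#' @name farming
NULL

#' Construct a farm operation
#'
#' @param kind one of `sow`, `plough`, `harrow`, `mechanical_weed`,
#'   `spray_insecticide`, `spray_other`, `harvest`, `mow`, `roll`.
#' @param window integer length-2 day-of-year range in which the operation is
#'   attempted.
#' @param prob daily attempt probability while eligible.
#' @param max_precip weather gate: the operation is deferred on days with
#'   precipitation above this (mm/day).
#' @param reset either `NULL` (no vegetation effect), the string `"sow"`
#'   (re-initialise the crop's growth curve), or a list with `height`,
#'   `density`, `biomass`.
#' @param knockdown logical; insecticide knock-down of insect food.
#' @param destroy named numeric: nest destruction probability per life stage,
#'   `c(clutch = ..., nestling = ...)`.
#' @param opens_tramlines logical; opens tramlines for `TRAMLINE_DECAYTIME`
#'   days.
#' @return a `farm_operation` list.
#' @export
farm_operation <- function(kind, window, prob, max_precip = 2,
                           reset = NULL, knockdown = FALSE,
                           destroy = c(clutch = 0, nestling = 0),
                           opens_tramlines = FALSE) {
  kinds <- c("sow", "plough", "harrow", "mechanical_weed", "spray_insecticide",
             "spray_other", "harvest", "mow", "roll")
  stopifnot(kind %in% kinds, length(window) == 2, window[1] <= window[2],
            prob >= 0, prob <= 1)
  structure(list(kind = kind, window = as.integer(window), prob = prob,
                 max_precip = max_precip, reset = reset, knockdown = knockdown,
                 destroy = destroy, opens_tramlines = opens_tramlines),
            class = "farm_operation")
}

#' Default crop management plans
#'
#' Operation windows and probabilities are illustrative defaults (Danish
#' conventional practice at a coarse grain) and are meant to be overridden
#' through scenario configuration. Organic variants drop all spray
#' operations.
#'
#' @param organic drop spray operations (organic farm types never spray).
#' @return named list of crop plans; each plan has `crop`, `curve` (growth
#'   curve id) and `operations` (ordered by window start).
#' @export
default_crop_plans <- function(organic = FALSE) {
  soil_kill <- c(clutch = 1, nestling = 1)
  none <- c(clutch = 0, nestling = 0)
  plans <- list(
    spring_barley = list(
      crop = "spring_barley", curve = "spring_barley",
      operations = list(
        farm_operation("plough", c(80, 100), 0.3, 2, reset = list(height = 0, density = 0, biomass = 0), destroy = soil_kill),
        farm_operation("sow", c(95, 118), 0.5, 2, reset = "sow", destroy = soil_kill),
        farm_operation("spray_other", c(140, 158), 0.4, 1, destroy = none, opens_tramlines = TRUE),
        farm_operation("spray_insecticide", c(160, 178), 0.25, 1, knockdown = TRUE, destroy = none, opens_tramlines = TRUE),
        farm_operation("harvest", c(225, 250), 0.4, 1, reset = list(height = 10, density = 5, biomass = 40), destroy = c(clutch = 1, nestling = 0.9))
      )),
    winter_wheat = list(
      crop = "winter_wheat", curve = "winter_wheat",
      operations = list(
        farm_operation("spray_other", c(130, 148), 0.4, 1, destroy = none, opens_tramlines = TRUE),
        farm_operation("spray_insecticide", c(150, 168), 0.25, 1, knockdown = TRUE, destroy = none, opens_tramlines = TRUE),
        farm_operation("harvest", c(230, 255), 0.4, 1, reset = list(height = 10, density = 5, biomass = 40), destroy = c(clutch = 1, nestling = 0.9)),
        farm_operation("plough", c(258, 270), 0.3, 2, reset = list(height = 0, density = 0, biomass = 0), destroy = soil_kill),
        farm_operation("sow", c(265, 285), 0.5, 2, reset = "sow", destroy = soil_kill)
      )),
    grass_ley = list(
      crop = "grass_ley", curve = "grass_ley",
      operations = list(
        farm_operation("mow", c(150, 165), 0.4, 1, reset = list(height = 5, density = 10, biomass = 80), destroy = c(clutch = 0.9, nestling = 0.9)),
        farm_operation("mow", c(195, 210), 0.4, 1, reset = list(height = 5, density = 10, biomass = 80), destroy = c(clutch = 0.9, nestling = 0.9))
      )),
    set_aside = list(crop = "set_aside", curve = "set_aside", operations = list())
  )
  if (organic) {
    plans <- lapply(plans, function(pl) {
      keep <- !vapply(pl$operations, function(o)
        o$kind %in% c("spray_insecticide", "spray_other"), logical(1))
      pl$operations <- pl$operations[keep]
      ## organic weed control replaces herbicides in row crops
      if (pl$crop %in% c("spring_barley", "winter_wheat"))
        pl$operations <- c(pl$operations, list(
          farm_operation("mechanical_weed", c(125, 140), 0.3, 1,
                         destroy = c(clutch = 1, nestling = 1))))
      ord <- order(vapply(pl$operations, function(o) o$window[1], numeric(1)))
      pl$operations <- pl$operations[ord]
      pl
    })
  }
  plans
}

#' Construct a farm
#'
#' @param id farm id.
#' @param type one of `pig`, `arable`, `mixed`, `organic_pig`,
#'   `organic_arable`, `organic_mixed`.
#' @param fields polygon ids of the farm's fields.
#' @param rotation character vector of crop ids cycled yearly.
#' @param phases integer phase offset per field (defaults to `0:(n-1)`,
#'   spreading the rotation across fields).
#' @return a `farm` list.
#' @export
farm <- function(id, type, fields, rotation, phases = seq_along(fields) - 1L) {
  types <- c("pig", "arable", "mixed", "organic_pig", "organic_arable",
             "organic_mixed")
  stopifnot(type %in% types, length(phases) == length(fields))
  structure(list(id = id, type = type, fields = fields, rotation = rotation,
                 phases = as.integer(phases),
                 organic = startsWith(type, "organic")),
            class = "farm")
}

#' Crop grown on each field of a farm in a given simulation year
#'
#' Field `f` grows `rotation[(year + phase_f) mod L + 1]`.
#'
#' @param farm a [farm()].
#' @param year simulation year index (0-based or 1-based; only differences
#'   matter).
#' @return character vector of crop ids, one per field.
#' @export
farm_year_crops <- function(farm, year) {
  L <- length(farm$rotation)
  farm$rotation[((year + farm$phases) %% L) + 1L]
}

#' Assign phased rotations to match long-run crop area targets
#'
#' Builds a rotation in which each crop appears in proportion to its target
#' area share (largest-remainder rounding to the number of fields), and
#' assigns distinct phase offsets so the yearly crop mix is spread across
#' fields. The long-run mean annual area of each crop then matches its target
#' to within one field's area.
#'
#' @param fields polygon ids of the fields.
#' @param targets named numeric vector of crop area shares (will be
#'   normalised).
#' @return list with `rotation` (length = number of fields) and `phases`.
#' @export
assign_rotations <- function(fields, targets) {
  if (any(targets < 0)) stop("negative crop area target")
  if (sum(targets) <= 0) stop("infeasible crop area targets")
  n <- length(fields)
  share <- targets / sum(targets)
  raw <- share * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  rotation <- rep(names(targets), times = cnt)
  list(rotation = rotation, phases = seq_len(n) - 1L)
}

#' One day of farm management
#'
#' Each operation of the field's current crop plan that is inside its window,
#' not yet done this year, and not weather-gated fires with its daily attempt
#' probability (in plan order). Uses the current R RNG stream.
#'
#' @param farm a [farm()].
#' @param crops character vector: current crop per field (see
#'   [farm_year_crops()]).
#' @param done logical matrix `n_fields x max_ops`: operations already done
#'   this year.
#' @param doy day-of-year.
#' @param precipitation today's precipitation (mm).
#' @param plans crop plan list (see [default_crop_plans()]).
#' @return list with `executed` (data.frame: field polygon id, op index, kind)
#'   and the updated `done` matrix.
#' @export
step_farm_day <- function(farm, crops, done, doy, precipitation, plans) {
  ex_field <- integer(0); ex_op <- integer(0); ex_kind <- character(0)
  for (i in seq_along(farm$fields)) {
    pl <- plans[[crops[i]]]
    if (is.null(pl)) next
    for (j in seq_along(pl$operations)) {
      op <- pl$operations[[j]]
      if (done[i, j] || doy < op$window[1] || doy > op$window[2]) next
      if (precipitation > op$max_precip) next
      if (stats::runif(1) < op$prob) {
        done[i, j] <- TRUE
        ex_field <- c(ex_field, farm$fields[i])
        ex_op <- c(ex_op, j)
        ex_kind <- c(ex_kind, op$kind)
      }
    }
  }
  executed <- if (length(ex_field)) {
    data.frame(field = ex_field, op = ex_op, kind = ex_kind,
               stringsAsFactors = FALSE)
  } else .empty_executed
  list(executed = executed, done = done)
}

.empty_executed <- data.frame(field = integer(0), op = integer(0),
                              kind = character(0), stringsAsFactors = FALSE)

#' Apply a farm operation's effects to a polygon's vegetation state
#'
#' Vegetation resets and tramline opening are applied here; nest destruction
#' is drawn by the caller (the simulator), which knows the nests present.
#'
#' @param op a [farm_operation()].
#' @param veg vegetation state list.
#' @param curve the field's growth curve (used for `reset = "sow"`).
#' @param day absolute day index (for the tramline clock).
#' @param tram_until current tramline-open-until day.
#' @param params a `skylark_params` object.
#' @return list with updated `veg`, `tram_until`, and `sprayed` (logical:
#'   insecticide applied).
#' @export
apply_operation <- function(op, veg, curve, day, tram_until, params) {
  if (!is.null(op$reset)) {
    if (identical(op$reset, "sow")) {
      veg <- init_vegetation(curve, crop = veg$crop)
    } else {
      veg$height <- op$reset$height
      veg$density <- op$reset$density
      veg$biomass <- op$reset$biomass
    }
  }
  if (op$opens_tramlines) tram_until <- day + params$TRAMLINE_DECAYTIME
  list(veg = veg, tram_until = tram_until, sprayed = isTRUE(op$knockdown))
}
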