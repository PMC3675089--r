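#' Fitted and structural parameters of the skylark model
#'
#' Builds the full parameter set driving the simulation: the 30 named
#' calibration parameters (energetics, reproduction, mortality and territory
#' quality) at their fitted values, plus the structural design constants of
#' this implementation (baseline crop habitat score, energy budgets, clutch
#' size distribution, season calendar, and the scale factors used to interpret
#' the bare-integer probability parameters).
#'
#' Probability-parameter scales: `ADULTRETURNMORT`, `JUVRETURNMORT` and
#' `NESTLEAVECHANCE` are percentages; `CLUTCH_MORT_PROB` and `NEST_MORT_PROB`
#' are daily probabilities on a 1e-4 scale (350 -> 0.035/day). The scale
#' factors themselves (`MORT_PROB_SCALE`, `PERCENT_SCALE`) are parameters so
#' alternative readings remain testable.
#'
#' @param ... named overrides, e.g. `skylark_params(PEMAX = 5)`. Unknown names
#'   are an error.
#' @return an object of class `skylark_params`: a named list of numeric values.
#' @examples
#' p <- skylark_params()
#' p$MINDAYSTOHATCH
#' skylark_params(TRIPLENGTH = 12)$TRIPLENGTH
#' @export
skylark_params <- function(...) {
  p <- list(
    ## -- energetics (E) --
    EXTRACTION_RATE   = 0.00053, # food units extracted per unit food m^-2 min^-1
    HINDCONSTH_B      = -0.025,  # accessibility slope per cm above HEIGHTCONST_C
    HINDCONSTD_B      = -0.22,   # accessibility slope per density unit above DENSITYCONST_C
    MAXFEEDRAIN       = 4.7,     # mm/day at which foraging is prevented
    PEMAX             = 4.54,    # max nestling growth g/day
    RAINHINDPOW       = 4,       # power of rain-hindrance curve
    TRAMLINE_FORAGING = 0.45,    # hindrance reduction with tramlines/scrapes
    ## -- mortality (M) --
    ADULTRETURNMORT   = 35,      # percent overwinter+return mortality, adults
    CLUTCH_MORT_PROB  = 350,     # daily clutch predation, 1e-4 scale
    JUVRETURNMORT     = 35.0,    # percent overwinter+return mortality, juveniles
    NEST_MORT_PROB    = 23,      # daily nestling (brood) predation, 1e-4 scale
    ## -- reproduction (R) --
    COOLING_RATE_EGGS = 3,       # egg cooling rate, degC hr^-1 degC^-1
    EGGTEMP           = 36.1,    # incubation temperature degC
    MD_THRESHOLD      = 25.8,    # threshold for physiological egg development degC
    MINDAYSTOHATCH    = 10.2,    # minimum incubation time at optimal temperature, days
    NESTLEAVECHANCE   = 23,      # percent/day chance of leaving nest from min age
    TRIPLENGTH        = 10.5,    # minutes off nest per feeding trip
    ## -- territory quality (T) --
    DENSITYCONST_B    = -0.26,   # habitat-score exponent, density
    HEIGHTCONST_B     = -0.22,   # habitat-score exponent, height
    HQBAREEARTH       = 3,       # score/m2, vegetation < 3 cm
    HQHEDGE           = -250,    # score/m2, hedgerow/woodland/tall objects > 3 m
    HQTALL            = -2,      # score/m2, vegetation 1.1-2 m
    HQTALLVEG         = -10,     # score/m2, vegetation 2-3 m
    MINFEMACCEPTSCORE = 300000,  # minimum total territory score for acceptance
    PATCHYPREMIUM     = 47,      # score/m2 premium, patchy habitat < 2 m
    SKSCRAPESPREMIUM  = 0.24,    # score/m2 premium, fields with scrapes
    TRAMLINEPREMIUM   = 6,       # score/m2 premium, open tramlines
    DENSITYCONST_C    = 10,      # density threshold (density units)
    HEIGHTCONST_C     = 38.0,    # height threshold (cm)
    TRAMLINE_DECAYTIME = 21,     # days tramlines stay open

    ## -- structural design constants --
    MORT_PROB_SCALE   = 1e-4,    # scale for CLUTCH_MORT_PROB / NEST_MORT_PROB
    PERCENT_SCALE     = 1e-2,    # scale for percent-valued parameters
    Q0_CROP_SCORE     = 40,      # baseline score/m2 for vegetation 3 cm - 1.1 m
    TERRITORY_AREA    = 10000,   # m2, fixed square territory blocks
    SPLIT_MULTIPLIER  = 2.0,     # occupied territory may split above this x MINFEMACCEPTSCORE
    ADULT_MAINTENANCE = 6,       # food units/day, adult self-maintenance
    THERMO_THRESHOLD  = 10,      # degC below which thermoregulation surcharge applies
    THERMO_SLOPE      = 0.4,     # food units/day per degC below THERMO_THRESHOLD
    ASSIMILATION      = 0.5,     # g nestling growth per food unit delivered
    MAX_TRIPS_PER_DAY = 45,      # daylight cap on feeding trips
    DEFICIT_SEVERITY  = 0.5,     # a day counts towards abandonment below this fraction of need
    DEFICIT_DAYS_ABANDON = 4,    # consecutive severe-deficit days before nest abandonment
    STARVE_FRACTION   = 0.5,     # growth below this x PEMAX counts as a starvation day
    STARVE_DAYS       = 3,       # consecutive starvation days before brood death
    CLUTCH_SIZES      = 3,       # min clutch size (uniform on CLUTCH_SIZES..CLUTCH_SIZE_MAX)
    CLUTCH_SIZE_MAX   = 5,
    MIN_LEAVE_AGE     = 7,       # days, minimum nest-leaving age
    MAX_LEAVE_AGE     = 11,      # days, forced nest leaving
    NEST_HEIGHT_MIN   = 10,      # cm, nest-site vegetation window
    NEST_HEIGHT_MAX   = 60,
    ARRIVAL_START     = 74,      # day-of-year, arrival window (mid March)
    ARRIVAL_END       = 105,     # mid April
    LAST_INITIATION   = 212,     # 31 July, last day a new attempt may start
    SEASON_END        = 273,     # end of season bookkeeping (end September)
    INDEPENDENCE_AGE  = 30,      # days post-hatch to independence
    PREFLEDGE_SURVIVAL = 0.93,   # daily survival, nest-leaving to independence
    RENEST_DELAY      = 5,       # days between attempts
    IMMIGRANTS_MEAN   = 2,       # Poisson mean, spring immigrants (birds); 0 = closed
    PROVISION_SHARE_FEMALE = 0.5, # female share of brood provisioning
    ## -- insect food submodel (stand-in, defined by this package) --
    INSECT_PEAK       = 300,     # food units/m2 at the midsummer envelope peak
    INSECT_SEASON_START = 60,    # day-of-year the seasonal envelope opens
    INSECT_PEAK_DOY   = 180,     # envelope peak (midsummer)
    INSECT_SEASON_END = 300,     # envelope closes
    INSECT_KHALF      = 100,     # biomass half-saturation of food availability
    INSECT_KNOCKDOWN  = 0.4,     # multiplier right after an insecticide spray
    INSECT_RECOVERY_DAYS = 10    # linear recovery time after a spray
  )
  class(p) <- "skylark_params"
  override_params(p, list(...))
}

#' Override named parameters
#'
#' @param params a `skylark_params` object.
#' @param overrides named list of replacement values.
#' @return updated `skylark_params`.
#' @export
override_params <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) stop("parameter overrides must be named")
  unknown <- setdiff(nm, names(params))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  for (k in nm) params[[k]] <- overrides[[k]]
  params
}

#' Names of the calibration parameters scanned in sensitivity analysis
#'
#' The 30 named parameters varied during pattern-oriented fitting. Parameters
#' flagged as small integers are perturbed additively (+/-1, 2, 4, 8); the
#' rest multiplicatively (+/-5, 10, 20, 40 percent).
#'
#' @return data.frame with columns `name` and `integer` (logical).
#' @export
calibration_parameters <- function() {
  nm <- c("EXTRACTION_RATE", "HINDCONSTH_B", "HINDCONSTD_B", "MAXFEEDRAIN",
          "PEMAX", "RAINHINDPOW", "TRAMLINE_FORAGING", "ADULTRETURNMORT",
          "CLUTCH_MORT_PROB", "JUVRETURNMORT", "NEST_MORT_PROB",
          "COOLING_RATE_EGGS", "EGGTEMP", "MD_THRESHOLD", "MINDAYSTOHATCH",
          "NESTLEAVECHANCE", "TRIPLENGTH", "DENSITYCONST_B", "HEIGHTCONST_B",
          "HQBAREEARTH", "HQHEDGE", "HQTALL", "HQTALLVEG", "MINFEMACCEPTSCORE",
          "PATCHYPREMIUM", "SKSCRAPESPREMIUM", "TRAMLINEPREMIUM",
          "DENSITYCONST_C", "HEIGHTCONST_C", "TRAMLINE_DECAYTIME")
  int <- nm %in% c("RAINHINDPOW", "COOLING_RATE_EGGS", "HQBAREEARTH", "HQTALL",
                   "HQTALLVEG", "TRAMLINEPREMIUM", "DENSITYCONST_C",
                   "TRAMLINE_DECAYTIME", "NEST_MORT_PROB", "NESTLEAVECHANCE",
                   "ADULTRETURNMORT", "PATCHYPREMIUM")
  data.frame(name = nm, integer = int, stringsAsFactors = FALSE)
}

#' @export
print.skylark_params <- function(x, ...) {
  cal <- calibration_parameters()$name
  cat("<skylark_params> ", length(x), " parameters (",
      sum(names(x) %in% cal), " calibration, ",
      sum(!names(x) %in% cal), " structural)\n", sep = "")
  invisible(x)
}

#' Write / read a parameter file
#'
#' Parameters are stored as YAML keyed by parameter name.
#'
#' @param params a `skylark_params` object.
#' @param path file path.
#' @return `read_params` returns a `skylark_params` object.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(skylark_params, vals)
}
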