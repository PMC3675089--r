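#' @title Virtual-ecologist observation protocols
#' @description Turn simulation event logs into the data structures field
#'   workers produce: repeated territory censuses per plot, nest monitoring
#'   with incubation/nestling-period distributions, and per-date seasonal
#'   series of pair counts. All are pure functions of the event log.
#' @name virtual_ecologist
NULL

## mated-territory intervals for one simulated year: data.frame per territory
territory_intervals <- function(events, yr) {
  e <- events[events$year == yr, ]
  acq <- e[e$event == "territory_acquired", c("terr", "doy", "poly")]
  if (!nrow(acq))
    return(data.frame(terr = integer(0), poly = integer(0), acq = integer(0),
                      aband = integer(0), paired = integer(0)))
  ab <- e[e$event == "territory_abandoned", c("terr", "doy")]
  pf <- e[e$event == "pair_formed", c("terr", "doy")]
  out <- data.frame(terr = acq$terr, poly = acq$poly, acq = acq$doy,
                    aband = NA_integer_, paired = NA_integer_)
  out$aband <- ab$doy[match(out$terr, ab$terr)]
  out$paired <- pf$doy[match(out$terr, pf$terr)]
  out
}

count_pairs <- function(iv, polys, doy) {
  sum(!is.na(iv$paired) & iv$paired <= doy & iv$acq <= doy &
        (is.na(iv$aband) | iv$aband > doy) & iv$poly %in% polys)
}

#' Territory-mapping census over plots
#'
#' A pair is counted for a plot on a visit date if a mated territory's centre
#' lies inside the plot (centre-in-plot rule) on that date.
#'
#' @param events event log data.frame from [simulate_skylarks()].
#' @param plots named list of polygon-id vectors (the observation plots).
#' @param visit_doys integer days-of-year of the mapping visits.
#' @param years integer vector of years to census (default: all in the log).
#' @param plot_areas_ha optional named numeric of plot areas (ha) for
#'   densities.
#' @return list with `census` (plot, year, doy, pairs) and `summary`
#'   (plot, year, max_pairs, and `density` per ha if areas given).
#' @export
map_territories <- function(events, plots, visit_doys, years = NULL,
                            plot_areas_ha = NULL) {
  if (!length(plots) || is.null(names(plots)))
    stop("plots must be a named list of polygon ids")
  if (is.null(years)) years <- sort(unique(events$year))
  rows <- list()
  for (yr in years) {
    iv <- territory_intervals(events, yr)
    for (pn in names(plots)) {
      for (v in visit_doys) {
        rows[[length(rows) + 1L]] <-
          data.frame(plot = pn, year = yr, doy = v,
                     pairs = count_pairs(iv, plots[[pn]], v))
      }
    }
  }
  census <- do.call(rbind, rows)
  agg <- stats::aggregate(pairs ~ plot + year, census, max)
  names(agg)[3] <- "max_pairs"
  if (!is.null(plot_areas_ha))
    agg$density <- agg$max_pairs / plot_areas_ha[agg$plot]
  list(census = census, summary = agg)
}

#' Nest monitoring: incubation and nestling-period distributions
#'
#' Extracts one record per monitored nest (incubation length in days or fate:
#' predated / other; then nestling period in days or fate) and bins them into
#' normalised proportion vectors: incubation over days `hatch_bins` plus the
#' two fate categories, nest leaving over days `leave_bins` plus the two fate
#' categories. Periods outside the bin range are counted in the nearest bin.
#'
#' @param events event log data.frame.
#' @param years years to use; default the last 20 years present (burn-in
#'   discarded).
#' @param hatch_bins integer bins for incubation length (default 9:17).
#' @param leave_bins integer bins for nest-leaving day (default 6:11).
#' @return list with `records` (data.frame), `hatch_dist`, `leave_dist`
#'   (named proportion vectors summing to 1, or NULL when no records).
#' @export
monitor_nests <- function(events, years = NULL, hatch_bins = 9:17,
                          leave_bins = 6:11) {
  all_years <- sort(unique(events$year))
  if (is.null(years))
    years <- all_years[all_years > max(all_years) - 20L]
  e <- events[events$year %in% years, ]
  starts <- e[e$event == "incubation_start", ]
  by_id <- split(seq_len(nrow(e)), e$id)
  recs <- list()
  for (i in seq_len(nrow(starts))) {
    nid <- starts$id[i]
    after <- e[by_id[[nid]], ]
    after <- after[after$doy >= starts$doy[i] & after$year == starts$year[i], ]
    inc_len <- NA_real_; inc_fate <- NA_character_
    per <- NA_real_; per_fate <- NA_character_
    if (any(after$event == "hatch")) {
      inc_len <- after$value[after$event == "hatch"][1]
      if (any(after$event == "brood_leave")) {
        per <- after$value[after$event == "brood_leave"][1]
      } else if (any(after$event == "brood_predated")) {
        per_fate <- "predated"
      } else if (any(after$event == "brood_other")) {
        per_fate <- "other"
      }
    } else if (any(after$event == "clutch_predated")) {
      inc_fate <- "predated"
    } else if (any(after$event == "clutch_other")) {
      inc_fate <- "other"
    }
    recs[[length(recs) + 1L]] <- data.frame(
      nest = nid, year = starts$year[i], inc_length = inc_len,
      inc_fate = inc_fate, nest_period = per, nest_fate = per_fate,
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(nest = character(0), year = integer(0),
               inc_length = numeric(0), inc_fate = character(0),
               nest_period = numeric(0), nest_fate = character(0))
  list(records = records,
       hatch_dist = bin_periods(records$inc_length, records$inc_fate,
                                hatch_bins),
       leave_dist = bin_periods(records$nest_period[!is.na(records$inc_length)],
                                records$nest_fate[!is.na(records$inc_length)],
                                leave_bins))
}

## proportions over day bins plus the two fate categories
bin_periods <- function(days, fates, bins) {
  mask <- !is.na(days) | !is.na(fates)
  days <- days[mask]
  fates2 <- fates[mask]
  n <- length(days)
  if (n == 0) return(NULL)
  counts <- stats::setNames(numeric(length(bins) + 2),
                            c(as.character(bins), "predated", "other"))
  for (i in seq_len(n)) {
    if (!is.na(days[i])) {
      b <- min(max(round(days[i]), min(bins)), max(bins))
      counts[as.character(b)] <- counts[as.character(b)] + 1
    } else {
      counts[fates2[i]] <- counts[fates2[i]] + 1
    }
  }
  counts / sum(counts)
}

#' Seasonal series of pair counts on a focal field
#'
#' Mean number of mated pairs with territory centre in the focal field on
#' each mapping date, averaged over the chosen years (default: the last 20
#' present, discarding burn-in).
#'
#' @param events event log data.frame.
#' @param field_poly polygon id(s) of the focal field.
#' @param visit_doys mapping days-of-year.
#' @param years years to average over (default last 20 present).
#' @return data.frame `doy`, `mean_pairs`.
#' @export
seasonal_series <- function(events, field_poly, visit_doys, years = NULL) {
  all_years <- sort(unique(events$year))
  if (is.null(years))
    years <- all_years[all_years > max(all_years) - 20L]
  counts <- matrix(0, length(years), length(visit_doys))
  for (i in seq_along(years)) {
    iv <- territory_intervals(events, years[i])
    counts[i, ] <- vapply(visit_doys, function(v)
      count_pairs(iv, field_poly, v), numeric(1))
  }
  data.frame(doy = visit_doys, mean_pairs = colMeans(counts))
}
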