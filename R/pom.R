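#' @title Pattern-oriented-modelling fit statistics and sensitivity harness
#' @description The six fit statistics (regression slope and R2 of predicted
#'   vs observed plot densities; summed squared differences of the hatching
#'   and nest-leaving distributions; scaled density-series deviations with
#'   and without scrapes), their scaling to \[0,1\], the weighted overall
#'   statistic, and the one-at-a-time sensitivity scan.
#' @name pom_fit
NULL

#' Linear regression forced through the origin
#'
#' `b = sum(x*y) / sum(x^2)`; the coefficient of determination uses the
#' general expression `R2 = 1 - SS_err/SS_tot` with `SS_tot` taken about the
#' mean of `y`, so R2 can be negative.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with `slope` and `r2`.
#' @export
regression_origin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (all(x == 0)) stop("all-zero predictor")
  b <- sum(x * y) / sum(x^2)
  ss_err <- sum((y - b * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = b, r2 = 1 - ss_err / ss_tot)
}

#' Summed squared difference between two proportion distributions
#'
#' Bin structures must match (day bins plus the two fate categories). The
#' scaled statistic divides by the maximum attainable SSD of two proportion
#' vectors (2: disjoint point masses).
#'
#' @param observed,modelled numeric proportion vectors with identical names.
#' @return list with `ssd` (raw) and `scaled` (in \[0,1\]).
#' @export
ssd_distribution_fit <- function(observed, modelled) {
  if (length(observed) != length(modelled))
    stop("distribution bins mismatch")
  if (!is.null(names(observed)) && !is.null(names(modelled)) &&
      !identical(names(observed), names(modelled)))
    stop("distribution bins mismatch: ",
         paste(names(observed), collapse = ","), " vs ",
         paste(names(modelled), collapse = ","))
  ssd <- sum((observed - modelled)^2)
  list(ssd = ssd, scaled = min(1, ssd / 2))
}

#' Scaled deviation of a per-date pair-count series
#'
#' `SSD(model, observed) / SSD(0, observed)`: the deviation is scaled by the
#' score of an extinct population (the maximum negative deviation possible)
#' and clamped to \[0,1\] for overshoot.
#'
#' @param observed,modelled per-date pair counts (same dates).
#' @return scaled statistic in \[0,1\] (0 = perfect, 1 = extinct).
#' @export
density_series_fit <- function(observed, modelled) {
  if (length(observed) != length(modelled)) stop("dates mismatch")
  denom <- sum(observed^2)
  if (denom == 0) stop("observed series is all zero")
  min(1, sum((observed - modelled)^2) / denom)
}

#' Scaled slope and R2 statistics
#'
#' The slope statistic is `min(1, |1 - b| / M_slope)` where `M_slope` is the
#' range over which the slope varies across scanned scenarios with stable
#' populations; the R2 statistic is `min(1, (M_r2 - r2) / M_r2)` with `M_r2`
#' the best R2 observed. Both are 0 at the ideal value and 1 at the edge of
#' the observed range.
#'
#' @param b regression slope.
#' @param m_slope scaling range for the slope (> 0).
#' @return statistic in \[0,1\].
#' @export
scaled_slope_fit <- function(b, m_slope) {
  if (m_slope <= 0) stop("M must be positive")
  min(1, abs(1 - b) / m_slope)
}

#' @rdname scaled_slope_fit
#' @param r2 coefficient of determination.
#' @param m_r2 best R2 observed in the scan (> 0).
#' @export
scaled_r2_fit <- function(r2, m_r2) {
  if (m_r2 <= 0) stop("M must be positive")
  min(1, max(0, (m_r2 - r2) / m_r2))
}

#' Overall weighted fit statistic
#'
#' Mean of the per-pattern-set means, weighted (2, 2, 1) across sets 1-3 by
#' default: set 1 = (slope, R2), set 2 = (hatch fit, nest-leaving fit),
#' set 3 = (density without scrapes, density with scrapes). Lower is better;
#' 0 iff all six statistics are 0.
#'
#' @param stats named numeric of the six scaled statistics:
#'   `bjerringbro_slope`, `bjerringbro_r2`, `hatch_fit`, `nest_leaving_fit`,
#'   `density_no_scrapes`, `density_with_scrapes`.
#' @param weights length-3 weights for the three pattern sets.
#' @return overall fit in \[0,1\].
#' @export
overall_fit <- function(stats, weights = c(2, 2, 1)) {
  need <- c("bjerringbro_slope", "bjerringbro_r2", "hatch_fit",
            "nest_leaving_fit", "density_no_scrapes", "density_with_scrapes")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop("missing statistic(s): ", paste(miss, collapse = ", "))
  if (any(stats[need] < -1e-9 | stats[need] > 1 + 1e-9))
    stop("statistics must lie in [0,1]")
  set_means <- c(mean(stats[need[1:2]]), mean(stats[need[3:4]]),
                 mean(stats[need[5:6]]))
  sum(weights * set_means) / sum(weights)
}

#' One-at-a-time sensitivity scan
#'
#' Each parameter is perturbed one at a time around its fitted value
#' (+/- 5, 10, 20, 40 percent; small-integer parameters by +/- 1, 2, 4, 8)
#' while all others stay at their fitted values. The runner maps a parameter
#' set to the six scaled statistics; the overall statistic is computed per
#' run, and a parameter is classified insensitive if no perturbation moves
#' the overall statistic by more than `cutoff` (0.1) from the baseline.
#'
#' @param runner `function(params) -> named numeric` of the six statistics
#'   (see [overall_fit()] for the names).
#' @param params baseline `skylark_params`.
#' @param parameters character vector of parameter names to scan (default:
#'   all 30 calibration parameters).
#' @param cutoff insensitivity cut-off on the overall-fit deviation.
#' @param weights pattern-set weights for the overall statistic.
#' @return list with `table` (data.frame: parameter, perturbation, value, the
#'   six statistics, overall, deviation), `summary` (parameter, max
#'   deviation, insensitive flag) and `baseline` (the unperturbed run).
#' @export
sensitivity_scan <- function(runner, params = skylark_params(),
                             parameters = calibration_parameters()$name,
                             cutoff = 0.1, weights = c(2, 2, 1)) {
  meta <- calibration_parameters()
  base_stats <- run_stats(runner, params, "baseline")
  base_overall <- overall_fit(base_stats, weights)
  rows <- list()
  for (pn in parameters) {
    vals <- perturbation_values(params[[pn]],
                                integer = isTRUE(meta$integer[meta$name == pn]))
    for (i in seq_along(vals)) {
      p2 <- override_params(params, stats::setNames(list(vals[i]), pn))
      st <- run_stats(runner, p2, pn)
      ov <- overall_fit(st, weights)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pn, perturbation = names(vals)[i], value = vals[i],
        t(st), overall = ov, deviation = abs(ov - base_overall),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- stats::aggregate(deviation ~ parameter, tab, max)
  names(summ)[2] <- "max_deviation"
  summ$insensitive <- summ$max_deviation <= cutoff
  list(table = tab, summary = summ,
       baseline = c(base_stats, overall = base_overall))
}

run_stats <- function(runner, params, label) {
  st <- tryCatch(runner(params), error = function(e)
    stop("runner failed for parameter '", label, "': ", conditionMessage(e)))
  unlist(st)
}

#' Perturbation grid for one parameter
#'
#' @param value fitted value.
#' @param integer small-integer parameter: additive +/- 1, 2, 4, 8 steps;
#'   otherwise multiplicative +/- 5, 10, 20, 40 percent.
#' @return named numeric of the 8 perturbed values (sorted ascending).
#' @export
perturbation_values <- function(value, integer = FALSE) {
  if (integer) {
    steps <- c(-8, -4, -2, -1, 1, 2, 4, 8)
    vals <- value + steps
    names(vals) <- sprintf("%+d", steps)
  } else {
    steps <- c(-40, -20, -10, -5, 5, 10, 20, 40)
    vals <- value * (1 + steps / 100)
    names(vals) <- sprintf("%+d%%", steps)
  }
  vals
}

#' Scripted guided-fitting scan
#'
#' A scripted stand-in for iterative manual calibration: evaluates the six
#' statistics and the overall fit over a list of candidate parameter
#' overrides and returns them ranked by overall fit (best first).
#'
#' @param runner as in [sensitivity_scan()].
#' @param params baseline parameters.
#' @param candidates list of named override lists.
#' @param weights pattern-set weights.
#' @return data.frame of candidates with their overall fit, ranked.
#' @export
guided_scan <- function(runner, params, candidates, weights = c(2, 2, 1)) {
  rows <- lapply(seq_along(candidates), function(i) {
    p2 <- override_params(params, candidates[[i]])
    st <- run_stats(runner, p2, paste0("candidate ", i))
    data.frame(candidate = i,
               overrides = paste(names(candidates[[i]]),
                                 unlist(candidates[[i]]),
                                 sep = "=", collapse = ";"),
               t(st), overall = overall_fit(st, weights),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$overall), ]
}

## ---- pattern data ---------------------------------------------------------

#' Load an observed pair-count pattern file
#'
#' CSV with columns `year` (or `date`/`doy`) and `pairs`.
#'
#' @param path CSV path.
#' @return data.frame with a `pairs` column; `mean(x$pairs)` is the mean
#'   observed pair count.
#' @export
load_pattern_pairs <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pairs" %in% names(x)) stop("pattern file lacks a 'pairs' column")
  x
}

#' Load an observed proportion-distribution pattern file
#'
#' CSV with columns `bin` (day numbers and the fate categories `predated`,
#' `other`) and `proportion`; proportions must sum to 1.
#'
#' @param path CSV path.
#' @return named numeric proportion vector.
#' @export
load_pattern_distribution <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- stats::setNames(x$proportion, as.character(x$bin))
  if (abs(sum(v) - 1) > 1e-9) stop("proportions do not sum to 1")
  v
}
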