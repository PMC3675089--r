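#' @title Incubation temperature-logger feeding-trip analysis
#' @description Nest loggers sample temperature every 2 minutes at 0.1 degC
#'   resolution. Female off-bouts appear as runs of consecutive temperature
#'   drops; their daily rate, net of the "natural" drop rate recorded by
#'   buried control loggers, estimates the feeding-trip length distribution.
#' @name trip_logger
NULL

#' Construct a logger trace
#'
#' @param temperatures numeric vector (degC); quantised to 0.1 degC.
#' @param interval_min sampling interval in minutes (fixed at 2).
#' @param is_control control logger (buried near the nest)?
#' @return a `logger_trace` list.
#' @export
logger_trace <- function(temperatures, interval_min = 2, is_control = FALSE) {
  stopifnot(interval_min == 2)
  structure(list(temperatures = round(temperatures, 1), interval_min = 2,
                 is_control = is_control), class = "logger_trace")
}

#' Detect significant temperature-drop events in a trace
#'
#' An event is a maximal run of at least two consecutive 2-minute periods
#' each with a temperature drop of at least 0.2 degC; single-period drops
#' (e.g. egg-turning) are excluded. Detection uses first differences, so it
#' is invariant to adding a constant to the whole trace.
#'
#' @param trace a [logger_trace()] or numeric temperature vector.
#' @param min_drop drop threshold per period (degC).
#' @return data.frame with `start` (index of the sample beginning the run)
#'   and `duration_min` (run length x 2 minutes).
#' @export
detect_drops <- function(trace, min_drop = 0.2) {
  temps <- if (inherits(trace, "logger_trace")) trace$temperatures else trace
  d <- diff(round(temps, 1))
  drops <- round(d, 6) <= -(min_drop - 1e-9)
  r <- rle(drops)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  data.frame(start = starts[keep],
             duration_min = r$lengths[keep] * 2L)
}

#' Net feeding-trip distribution from nest and control traces
#'
#' Drop events are binned by duration (4, 6, 8, ... minutes) and converted to
#' daily rates separately for nest and control loggers; per-bin net rates are
#' the nest rate minus the control ("natural") rate, clamped at zero. The
#' mean trip length is the arithmetic mean of the net discrete distribution.
#'
#' @param nest_traces list of [logger_trace()] from nests.
#' @param control_traces list of control [logger_trace()].
#' @param min_drop drop threshold per period (degC).
#' @return list of class `trip_distribution`: `bins` (minutes), `nest_rate`,
#'   `control_rate`, `net_rate` (events/day), `mean_duration` (minutes;
#'   `NA` with `degenerate = TRUE` when all net rates are zero).
#' @export
net_trip_distribution <- function(nest_traces, control_traces,
                                  min_drop = 0.2) {
  if (!length(nest_traces) || !length(control_traces))
    stop("need at least one nest trace and one control trace")
  rate <- function(traces) {
    ev <- lapply(traces, detect_drops, min_drop = min_drop)
    days <- sum(vapply(traces, function(tr) {
      temps <- if (inherits(tr, "logger_trace")) tr$temperatures else tr
      length(temps) * 2 / (60 * 24)
    }, numeric(1)))
    durs <- unlist(lapply(ev, function(e) e$duration_min))
    list(durs = durs, days = days)
  }
  nr <- rate(nest_traces); cr <- rate(control_traces)
  all_d <- c(nr$durs, cr$durs)
  max_bin <- if (length(all_d)) max(all_d) else 4
  bins <- seq(4, max(4, max_bin), by = 2)
  nest_rate <- vapply(bins, function(b) sum(nr$durs == b), numeric(1)) / nr$days
  ctrl_rate <- vapply(bins, function(b) sum(cr$durs == b), numeric(1)) / cr$days
  net <- pmax(0, nest_rate - ctrl_rate)
  degenerate <- sum(net) == 0
  mean_dur <- if (degenerate) NA_real_ else sum(bins * net) / sum(net)
  structure(list(bins = bins, nest_rate = nest_rate, control_rate = ctrl_rate,
                 net_rate = net, mean_duration = mean_dur,
                 degenerate = degenerate),
            class = "trip_distribution")
}

#' @export
print.trip_distribution <- function(x, ...) {
  cat("<trip_distribution> bins ", min(x$bins), "-", max(x$bins),
      " min; mean trip length ",
      if (is.na(x$mean_duration)) "undefined (no net events)" else
        sprintf("%.1f min", x$mean_duration), "\n", sep = "")
  invisible(x)
}

#' Simulate a nest temperature-logger trace
#'
#' Ground-truth generator mirroring the incubation thermal model: the nest
#' sits at `egg_temp` plus a daily sinusoid; during each scheduled trip the
#' temperature decays exponentially towards ambient at `cooling_rate` per
#' hour, with instantaneous rewarming on return. Gaussian sensor noise is
#' added and the trace is quantised to 0.1 degC.
#'
#' @param trips data.frame with `start_min` and `duration_min` (trips must
#'   not overlap).
#' @param total_min trace length in minutes.
#' @param egg_temp incubated nest temperature (degC).
#' @param ambient ambient temperature (degC).
#' @param cooling_rate exponential cooling rate (per hour).
#' @param sin_amplitude amplitude of the daily sinusoid (degC).
#' @param noise_sd sd of sensor noise (degC).
#' @param seed RNG seed.
#' @return a [logger_trace()].
#' @export
simulate_trace <- function(trips, total_min = 1440, egg_temp = 36,
                           ambient = 15, cooling_rate = 3,
                           sin_amplitude = 0.5, noise_sd = 0, seed = 1) {
  if (nrow(trips) > 1) {
    o <- order(trips$start_min)
    trips <- trips[o, ]
    if (any(trips$start_min[-1] < (trips$start_min + trips$duration_min)[-nrow(trips)]))
      stop("overlapping trips")
  }
  set.seed(seed)
  t_min <- seq(0, total_min - 2, by = 2)
  base <- rep(egg_temp, length(t_min))
  for (i in seq_len(nrow(trips))) {
    s <- trips$start_min[i]; dur <- trips$duration_min[i]
    inside <- t_min >= s & t_min < s + dur
    dt_h <- (t_min[inside] - s) / 60
    base[inside] <- ambient + (egg_temp - ambient) * exp(-cooling_rate * dt_h)
  }
  sinus <- sin_amplitude * sin(2 * pi * t_min / 1440)
  noise <- if (noise_sd > 0) stats::rnorm(length(t_min), 0, noise_sd) else 0
  logger_trace(base + sinus + noise)
}

#' Read / write logger traces as CSV
#'
#' Columns: `minute`, `temperature`.
#'
#' @param trace a [logger_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(
    minute = seq(0, by = 2, length.out = length(trace$temperatures)),
    temperature = trace$temperatures), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param is_control control flag for the loaded trace.
#' @export
read_trace <- function(path, is_control = FALSE) {
  x <- utils::read.csv(path)
  logger_trace(x$temperature, is_control = is_control)
}
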