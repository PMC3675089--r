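#' Generate a synthetic daily weather series
#'
#' Mean temperature follows a seasonal sinusoid (peak in late July) with
#' Gaussian day-to-day noise; precipitation follows a two-state wet/dry Markov
#' chain with gamma-distributed wet-day amounts. The defaults approximate a
#' Danish lowland climate. The series is reproducible per seed.
#'
#' @param years number of simulated years (365-day years; leap days are not
#'   modelled).
#' @param seed integer seed for the series.
#' @param mean_temp annual mean temperature (degC).
#' @param amplitude seasonal half-range (degC); the seasonal peak is
#'   `mean_temp + amplitude` at `peak_doy`.
#' @param peak_doy day-of-year of the warmest day.
#' @param noise_sd sd of daily temperature noise (degC).
#' @param p_wet_dry probability a dry day is followed by a wet day.
#' @param p_wet_wet probability a wet day is followed by a wet day.
#' @param rain_shape,rain_scale gamma parameters of wet-day rainfall (mm).
#' @param start_year calendar year of the first day.
#' @return data.frame of class `daily_weather` with columns `date` (Date),
#'   `year`, `doy`, `mean_temp`, `precipitation`.
#' @examples
#' w <- generate_weather(1, seed = 1)
#' range(w$mean_temp)
#' @export
generate_weather <- function(years, seed, mean_temp = 8, amplitude = 9,
                             peak_doy = 205, noise_sd = 2.5,
                             p_wet_dry = 0.3, p_wet_wet = 0.6,
                             rain_shape = 0.8, rain_scale = 5,
                             start_year = 2001) {
  stopifnot(years >= 1)
  n <- years * 365L
  rng <- local({ set.seed(seed); list(
    noise = stats::rnorm(n, 0, noise_sd),
    u_wet = stats::runif(n),
    amt   = stats::rgamma(n, shape = rain_shape, scale = rain_scale)
  )})
  ## 365-day model years on a contiguous date axis (leap days not modelled,
  ## so calendar dates drift by one day across each real leap year)
  doy <- rep(seq_len(365L), years)
  year <- start_year + rep(seq_len(years) - 1L, each = 365L)
  temp <- mean_temp + amplitude * cos(2 * pi * (doy - peak_doy) / 365) + rng$noise
  wet <- logical(n)
  prev <- FALSE
  for (i in seq_len(n)) {
    p <- if (prev) p_wet_wet else p_wet_dry
    wet[i] <- rng$u_wet[i] < p
    prev <- wet[i]
  }
  precip <- ifelse(wet, rng$amt, 0)
  out <- data.frame(
    date = as.Date(paste0(start_year, "-01-01")) + (seq_len(n) - 1L),
    year = year, doy = doy,
    mean_temp = temp, precipitation = precip
  )
  class(out) <- c("daily_weather", "data.frame")
  out
}

#' Validate a daily weather series
#'
#' Checks the invariants required by the simulator: non-negative
#' precipitation and a contiguous daily series with no gaps.
#'
#' @param weather a data.frame with columns `date`, `mean_temp`,
#'   `precipitation`.
#' @return the validated series (invisibly), with `year`/`doy` columns added
#'   if absent.
#' @export
validate_weather <- function(weather) {
  need <- c("date", "mean_temp", "precipitation")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather series missing column(s): ", paste(miss, collapse = ", "))
  if (any(weather$precipitation < 0)) stop("negative precipitation in weather series")
  d <- as.Date(weather$date)
  if (nrow(weather) > 1 && any(diff(d) != 1)) stop("weather series has gaps or is unordered")
  if (is.null(weather$doy)) weather$doy <- as.integer(strftime(d, "%j"))
  if (is.null(weather$year)) weather$year <- as.integer(strftime(d, "%Y"))
  invisible(weather)
}

#' Read / write a weather series as CSV
#'
#' Columns: `date` (ISO-8601), `mean_temp` (degC), `precipitation` (mm/day).
#'
#' @param weather a weather data.frame.
#' @param path file path.
#' @return `read_weather` returns a validated `daily_weather` data.frame.
#' @export
write_weather <- function(weather, path) {
  utils::write.csv(weather[, c("date", "mean_temp", "precipitation")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  w$date <- as.Date(w$date)
  w <- validate_weather(w)
  w <- as.data.frame(w)
  class(w) <- c("daily_weather", "data.frame")
  w
}
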