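# Independent oracles used across tests. These deliberately use the dumbest
# possible algorithms (exhaustive window scans, fine-step Euler integration,
# brute-force minimisation) so they share no code path with the package.

# exhaustive-window drop detector: for every (start, length >= 2) window,
# check that every 2-min step drops by >= 0.2 and the run is maximal
brute_detect_drops <- function(temps, min_drop = 0.2) {
  d <- round(diff(round(temps, 1)), 6)
  is_drop <- d <= -(min_drop - 1e-9)
  n <- length(d)
  out <- list()
  for (s in seq_len(max(0, n - 1))) {
    for (len in 2:(n - s + 1)) {
      if (all(is_drop[s:(s + len - 1)])) {
        left_max <- (s == 1) || !is_drop[s - 1]
        right_max <- (s + len - 1 == n) || !is_drop[s + len]
        if (left_max && right_max)
          out[[length(out) + 1L]] <- c(start = s, duration_min = len * 2L)
      } else break
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), duration_min = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# fine-step Euler integration of one off-bout: egg cools from egg_temp
# towards ambient at rate k per hour; development is the integral of the
# excess over the threshold
euler_trip_development <- function(tau_hours, ambient, params, dt = 1e-4) {
  k <- params$COOLING_RATE_EGGS
  t_egg <- params$EGGTEMP
  dev <- 0
  t <- 0
  while (t < tau_hours) {
    dev <- dev + max(0, t_egg - params$MD_THRESHOLD) * dt
    t_egg <- t_egg - k * (t_egg - ambient) * dt
    t <- t + dt
  }
  dev
}

# brute-force least squares for regression through the origin
brute_origin_slope <- function(x, y) {
  stats::optimize(function(b) sum((y - b * x)^2),
                  interval = range(c(-10, 10, y / pmax(x, 1e-9))))$minimum
}

# a fast analytic "runner" for harness-mechanics tests: responds only to six
# named parameters, so any other parameter is ignored by construction
analytic_runner <- function() {
  base <- skylark_params()
  function(p) {
    rel <- function(nm) abs(p[[nm]] - base[[nm]]) / max(abs(base[[nm]]), 1e-12)
    ## PEMAX drives both pattern-set-1 statistics so a 40% perturbation
    ## moves the overall statistic by 2/5 * 0.4 = 0.16 (> the 0.1 cut-off)
    c(bjerringbro_slope = min(1, rel("PEMAX")),
      bjerringbro_r2 = min(1, rel("PEMAX")),
      hatch_fit = min(1, rel("MINDAYSTOHATCH")),
      nest_leaving_fit = min(1, rel("NESTLEAVECHANCE") / 10),
      density_no_scrapes = min(1, rel("EXTRACTION_RATE")),
      density_with_scrapes = min(1, rel("TRAMLINEPREMIUM") / 10))
  }
}
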