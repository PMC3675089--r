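#' @title The daily simulation loop
#' @description Weather -> farming -> vegetation/insects -> birds, every day,
#'   with a structured event log sufficient for all observation protocols.
#' @name simulate
NULL

## vectorised polygon habitat scoring (mirror of habitat_score_cell)
score_polys <- function(h, d, elem, patchy, tram, scr, p) {
  n <- length(h)
  base <- numeric(n)
  hedge <- elem %in% c("hedgerow", "woodland", "building", "water") | h > 300
  road <- elem == "road" & !hedge
  rest <- !hedge & !road
  bare <- rest & h < 3
  tallveg <- rest & h > 200
  tall <- rest & h > 110 & h <= 200
  mid <- rest & !bare & !tallveg & !tall
  base[hedge] <- p$HQHEDGE
  base[bare] <- p$HQBAREEARTH
  base[tallveg] <- p$HQTALLVEG
  base[tall] <- p$HQTALL
  if (any(mid)) {
    f_h <- pmin(1, (h[mid] / p$HEIGHTCONST_C)^p$HEIGHTCONST_B)
    f_d <- ifelse(d[mid] <= 0, 1,
                  pmin(1, (d[mid] / p$DENSITYCONST_C)^p$DENSITYCONST_B))
    base[mid] <- p$Q0_CROP_SCORE * f_h * f_d
  }
  prem <- ifelse(patchy & h < 200, p$PATCHYPREMIUM, 0) +
    ifelse(tram, p$TRAMLINEPREMIUM, 0) +
    ifelse(scr, p$SKSCRAPESPREMIUM, 0)
  base + ifelse(rest, prem, 0)
}

## growing event log kept as parallel vectors, finalised once
new_eventlog <- function() {
  e <- new.env(parent = emptyenv())
  e$year <- integer(0); e$doy <- integer(0); e$event <- character(0)
  e$id <- character(0); e$poly <- integer(0); e$terr <- integer(0)
  e$cause <- character(0); e$value <- numeric(0)
  e$n <- 0L
  e
}

log_event <- function(ev, year, doy, event, id = NA_character_,
                      poly = NA_integer_, terr = NA_integer_,
                      cause = NA_character_, value = NA_real_) {
  i <- ev$n + 1L
  ev$year[i] <- year; ev$doy[i] <- doy; ev$event[i] <- event
  ev$id[i] <- id; ev$poly[i] <- poly; ev$terr[i] <- terr
  ev$cause[i] <- cause; ev$value[i] <- value
  ev$n <- i
  invisible(NULL)
}

eventlog_df <- function(ev) {
  data.frame(year = ev$year, doy = ev$doy, event = ev$event, id = ev$id,
             poly = ev$poly, terr = ev$terr, cause = ev$cause,
             value = ev$value, stringsAsFactors = FALSE)
}

#' Run the skylark simulation
#'
#' Runs the full daily loop over a scenario: farm operations fire
#' probabilistically, vegetation grows with temperature, insect food follows
#' the seasonal envelope, and the birds play out their annual cycle
#' (arrival, territory acquisition with best-first claiming and splitting,
#' pairing, laying, trip-interrupted incubation with degree-day egg
#' development, energetics-limited provisioning, probabilistic predation,
#' nest leaving, independence, and overwinter return mortality). All
#' randomness comes from a single stream seeded with `seed`, so identical
#' scenario + seed yields a bit-identical event log.
#'
#' @param scenario a scenario list (see [make_all_barley()] and friends).
#' @param years simulated years (defaults to `scenario$years`).
#' @param seed integer seed for the behavioural RNG stream.
#' @param params a `skylark_params` object (defaults to `scenario$params`).
#' @param weather optional daily weather data.frame covering `years`;
#'   generated from `scenario$weather_seed` if missing, so weather is shared
#'   across runs that differ only in bird parameters.
#' @return list of class `skylark_run`: `events` (data.frame), `daily`
#'   (per-day in-season population state), `years`, `scenario_name`.
#' @export
simulate_skylarks <- function(scenario, years = scenario$years, seed = 1,
                              params = NULL, weather = NULL) {
  if (is.null(params)) params <- scenario$params
  if (is.null(params)) params <- skylark_params()
  grid <- scenario$grid
  farms <- scenario$farms
  if (is.null(weather)) {
    wargs <- scenario$weather_args
    if (is.null(wargs)) wargs <- list()
    weather <- do.call(generate_weather,
                       c(list(years = years, seed = scenario$weather_seed),
                         wargs))
  }
  stopifnot(nrow(weather) >= years * 365)
  set.seed(seed)

  np <- nrow(grid$polygons)
  elem <- grid$polygons$elem_type
  scr <- grid$polygons$has_scrapes
  always_tram <- grid$polygons$id %in% (scenario$always_tram %||% integer(0))
  curves <- default_growth_curves()
  coefs <- default_insect_coefficients()[elem]
  plans_conv <- default_crop_plans(organic = FALSE)
  plans_org <- default_crop_plans(organic = TRUE)
  cands <- territory_candidates(grid, params)
  nest_ok <- elem %in% c("field", "permanent_grass", "field_margin")
  a_cell <- grid$cellsize^2
  ## static curve per non-field polygon by element type
  elem_curve <- c(field = NA, field_margin = "field_margin",
                  hedgerow = "hedgerow", woodland = "woodland",
                  permanent_grass = "permanent_grass")[elem]

  ev <- new_eventlog()
  nest_id <- 0L; terr_id <- 0L
  daily <- list()

  ## initial adults
  n0 <- scenario$initial_pairs %||% 10L
  n_males <- n0; n_females <- n0

  for (yr in seq_len(years)) {
    wyr <- weather[((yr - 1) * 365 + 1):(yr * 365), ]

    ## ---- year setup: rotation advance, vegetation reset ----
    curve_id <- elem_curve
    crops_by_farm <- list()
    for (fi in seq_along(farms)) {
      fm <- farms[[fi]]
      cy <- farm_year_crops(fm, yr - 1L)
      crops_by_farm[[fi]] <- cy
      pidx <- match(fm$fields, grid$polygons$id)
      plan_set <- if (fm$organic) plans_org else plans_conv
      curve_id[pidx] <- vapply(cy, function(cr) plan_set[[cr]]$curve,
                               character(1))
    }
    B <- Hgt <- Dns <- numeric(np)
    patchy <- logical(np)
    for (i in seq_len(np)) {
      cv <- if (!is.na(curve_id[i])) curves[[curve_id[i]]] else NULL
      spring <- FALSE
      if (!is.na(curve_id[i]) &&
          curve_id[i] %in% c("spring_barley", "maize")) spring <- TRUE
      v <- if (spring) init_vegetation(NULL) else init_vegetation(cv)
      B[i] <- v$biomass; Hgt[i] <- v$height; Dns[i] <- v$density
      patchy[i] <- if (!is.null(cv)) isTRUE(cv$patchy) else FALSE
    }
    r_v <- k_v <- tb_v <- ts_v <- mh_v <- md_v <- numeric(np)
    static_v <- logical(np)
    for (i in seq_len(np)) {
      cv <- if (!is.na(curve_id[i])) curves[[curve_id[i]]] else NULL
      if (is.null(cv)) { static_v[i] <- TRUE; k_v[i] <- 1; next }
      r_v[i] <- cv$r; k_v[i] <- cv$k; tb_v[i] <- cv$t_base
      ts_v[i] <- cv$t_scale; mh_v[i] <- cv$max_height; md_v[i] <- cv$max_density
      static_v[i] <- isTRUE(cv$static)
      if (static_v[i]) { B[i] <- cv$k; Hgt[i] <- cv$max_height; Dns[i] <- cv$max_density }
    }
    tram_until <- rep(-Inf, np)
    spray_day <- rep(-Inf, np)
    done <- lapply(seq_along(farms), function(fi)
      matrix(FALSE, length(farms[[fi]]$fields), 12L))

    ## ---- birds: season containers ----
    arr_m <- sample(params$ARRIVAL_START:params$ARRIVAL_END, n_males, replace = TRUE)
    arr_f <- sample(params$ARRIVAL_START:params$ARRIVAL_END, n_females, replace = TRUE)
    males <- lapply(seq_len(n_males), function(i)
      list(id = i, arrive = arr_m[i], state = "pre", terr = NA_integer_))
    females <- lapply(seq_len(n_females), function(i)
      list(id = i, arrive = arr_f[i], state = "pre", terr = NA_integer_,
           stage = NA_character_, clutch = NULL, brood = NULL,
           eggs = 0L, eggs_target = 0L, deficit = 0L, renest = 0L,
           nest = NA_integer_))
    terrs <- list()
    prefledge <- list()   # each: list(n, days_left)
    n_juveniles <- 0L

    for (doy in seq_len(365L)) {
      temp <- wyr$mean_temp[doy]; rain <- wyr$precipitation[doy]
      day_abs <- (yr - 1L) * 365L + doy

      ## ---- farming ----
      for (fi in seq_along(farms)) {
        fm <- farms[[fi]]
        plan_set <- if (fm$organic) plans_org else plans_conv
        res <- step_farm_day(fm, crops_by_farm[[fi]], done[[fi]], doy, rain,
                             plan_set)
        done[[fi]] <- res$done
        if (nrow(res$executed)) {
          for (r in seq_len(nrow(res$executed))) {
            pid <- res$executed$field[r]
            pi <- match(pid, grid$polygons$id)
            op <- plan_set[[crops_by_farm[[fi]][match(pid, fm$fields)]]]$operations[[res$executed$op[r]]]
            veg <- list(height = Hgt[pi], density = Dns[pi], biomass = B[pi],
                        is_patchy = patchy[pi], crop = crops_by_farm[[fi]][match(pid, fm$fields)])
            upd <- apply_operation(op, veg,
                                   curves[[curve_id[pi]]], day_abs,
                                   tram_until[pi], params)
            Hgt[pi] <- upd$veg$height; Dns[pi] <- upd$veg$density
            B[pi] <- upd$veg$biomass
            tram_until[pi] <- upd$tram_until
            if (upd$sprayed) spray_day[pi] <- day_abs
            log_event(ev, yr, doy, "operation", poly = pid, cause = op$kind)
            ## nest destruction
            for (k in seq_along(females)) {
              f <- females[[k]]
              if (is.na(f$terr) || !identical(terrs[[f$terr]]$centre_pid, pid)) next
              if (identical(f$stage, "laying") || identical(f$stage, "incubating")) {
                if (stats::runif(1) < op$destroy[["clutch"]]) {
                  if (identical(f$stage, "incubating"))
                    log_event(ev, yr, doy, "clutch_other", id = paste0("N", f$nest),
                              poly = pid, terr = terrs[[f$terr]]$id,
                              cause = "farm_operation")
                  females[[k]] <- fail_attempt(f, params)
                }
              } else if (identical(f$stage, "caring")) {
                if (stats::runif(1) < op$destroy[["nestling"]]) {
                  log_event(ev, yr, doy, "brood_other", id = paste0("N", f$nest),
                            poly = pid, terr = terrs[[f$terr]]$id,
                            cause = "farm_operation")
                  females[[k]] <- fail_attempt(f, params)
                }
              }
            }
          }
        }
      }

      ## ---- vegetation growth (vectorised logistic) ----
      tf <- pmax(0, temp - tb_v) / ts_v
      grow <- !static_v & B > 0 & tf > 0
      if (any(grow)) {
        B[grow] <- B[grow] + r_v[grow] * tf[grow] * B[grow] *
          pmax(0, 1 - B[grow] / k_v[grow])
        frac <- pmin(1, B[grow] / k_v[grow])
        Hgt[grow] <- mh_v[grow] * frac
        Dns[grow] <- md_v[grow] * frac
      }

      ## ---- insect food ----
      env_now <- insect_envelope(doy, params)
      food <- env_now * coefs * B / (B + params$INSECT_KHALF)
      since <- day_abs - spray_day
      rec <- pmin(1, since / params$INSECT_RECOVERY_DAYS)
      kd <- params$INSECT_KNOCKDOWN
      food <- ifelse(is.finite(since), food * (kd + (1 - kd) * rec), food)

      ## ---- birds ----
      if (doy >= params$ARRIVAL_START && doy <= params$SEASON_END) {
        tram_open <- always_tram | (day_abs < tram_until)
        pscore <- score_polys(Hgt, Dns, elem, patchy, tram_open, scr, params)
        access <- foraging_accessibility(Hgt, Dns, tram_open | scr, params)
        cscore <- as.numeric(cands$comp %*% pscore) * a_cell

        ## arrivals
        for (k in seq_along(males))
          if (males[[k]]$state == "pre" && males[[k]]$arrive <= doy)
            males[[k]]$state <- "search"
        for (k in seq_along(females))
          if (females[[k]]$state == "pre" && females[[k]]$arrive <= doy)
            females[[k]]$state <- "search"

        ## territory maintenance: abandonment when quality collapses
        for (t in seq_along(terrs)) {
          tr <- terrs[[t]]
          if (!tr$active) next
          tot <- sum(tr$comp * pscore) * a_cell
          terrs[[t]]$total <- tot
          if (tot < params$MINFEMACCEPTSCORE) {
            nest_active <- FALSE
            if (!is.na(tr$female)) {
              stg <- females[[tr$female]]$stage
              nest_active <- identical(stg, "laying") ||
                identical(stg, "incubating") || identical(stg, "caring")
            }
            if (!nest_active) {
              terrs[[t]]$active <- FALSE
              log_event(ev, yr, doy, "territory_abandoned", terr = tr$id,
                        poly = tr$centre_pid, cause = "quality")
              males[[tr$owner]]$state <- "search"
              males[[tr$owner]]$terr <- NA_integer_
              if (!is.na(tr$female)) {
                log_event(ev, yr, doy, "pair_dissolved", terr = tr$id,
                          cause = "quality")
                females[[tr$female]]$state <- "search"
                females[[tr$female]]$terr <- NA_integer_
                females[[tr$female]]$stage <- NA_character_
              }
            }
          }
        }

        ## acquisition (males in arrival order)
        searchers <- which(vapply(males, function(m) m$state == "search", logical(1)))
        if (length(searchers)) {
          ord <- searchers[order(vapply(males, function(m) m$arrive, numeric(1))[searchers])]
          occ <- active_rects(terrs)
          cord <- which(cscore >= params$MINFEMACCEPTSCORE &
                          nest_ok[cands$centre_poly])
          cord <- cord[order(cscore[cord], decreasing = TRUE)]
          crects <- cands$rects[cord, , drop = FALSE]
          dead <- overlaps_any(crects, occ)
          for (k in ord) {
            claimed <- FALSE
            j <- which(!dead)[1]
            if (!is.na(j)) {
              ci <- cord[j]
              rect <- cands$rects[ci, ]
              terr_id <- terr_id + 1L
              terrs[[length(terrs) + 1L]] <- list(
                id = terr_id, rect = rect,
                centre = cands$centres[ci, ],
                centre_pid = grid$polygons$id[cands$centre_poly[ci]],
                comp = cands$comp[ci, ], total = cscore[ci],
                owner = k, female = NA_integer_, active = TRUE)
              males[[k]]$state <- "holder"
              males[[k]]$terr <- length(terrs)
              dead <- dead | overlaps_any(crects, matrix(rect, 1))
              log_event(ev, yr, doy, "territory_acquired", terr = terr_id,
                        poly = terrs[[length(terrs)]]$centre_pid,
                        value = cscore[ci])
              claimed <- TRUE
            }
            if (!claimed) {
              ## try splitting the richest splittable territory
              act <- which(vapply(terrs, function(tr) tr$active, logical(1)))
              if (length(act)) {
                tots <- vapply(terrs[act], function(tr) tr$total, numeric(1))
                for (t in act[order(tots, decreasing = TRUE)]) {
                  tr <- terrs[[t]]
                  if (tr$total < params$SPLIT_MULTIPLIER * params$MINFEMACCEPTSCORE) break
                  if (!is.na(tr$female) &&
                      !is.na(females[[tr$female]]$stage) &&
                      females[[tr$female]]$stage %in%
                        c("laying", "incubating", "caring")) next
                  halves <- split_rect(tr$rect)
                  comp1 <- rect_comp(grid, halves[[1]])
                  comp2 <- rect_comp(grid, halves[[2]])
                  t1 <- sum(comp1 * pscore) * a_cell
                  t2 <- sum(comp2 * pscore) * a_cell
                  if (t1 < params$MINFEMACCEPTSCORE ||
                      t2 < params$MINFEMACCEPTSCORE) next
                  ## owner keeps half 1 under a new id; newcomer takes half 2
                  terrs[[t]]$active <- FALSE
                  log_event(ev, yr, doy, "territory_abandoned", terr = tr$id,
                            poly = tr$centre_pid, cause = "split")
                  h1 <- half_territory(grid, halves[[1]], t1)
                  h2 <- half_territory(grid, halves[[2]], t2)
                  terr_id <- terr_id + 1L
                  terrs[[length(terrs) + 1L]] <- list(
                    id = terr_id, rect = h1$rect, centre = h1$centre,
                    centre_pid = grid$polygons$id[h1$centre_poly],
                    comp = comp1, total = t1, owner = tr$owner,
                    female = tr$female, active = TRUE)
                  males[[tr$owner]]$terr <- length(terrs)
                  log_event(ev, yr, doy, "territory_acquired", terr = terr_id,
                            poly = grid$polygons$id[h1$centre_poly],
                            cause = "split", value = t1)
                  if (!is.na(tr$female)) {
                    females[[tr$female]]$terr <- length(terrs)
                    log_event(ev, yr, doy, "pair_formed", terr = terr_id)
                  }
                  terr_id <- terr_id + 1L
                  terrs[[length(terrs) + 1L]] <- list(
                    id = terr_id, rect = h2$rect, centre = h2$centre,
                    centre_pid = grid$polygons$id[h2$centre_poly],
                    comp = comp2, total = t2, owner = k,
                    female = NA_integer_, active = TRUE)
                  males[[k]]$state <- "holder"
                  males[[k]]$terr <- length(terrs)
                  log_event(ev, yr, doy, "territory_acquired", terr = terr_id,
                            poly = grid$polygons$id[h2$centre_poly],
                            cause = "split", value = t2)
                  claimed <- TRUE
                  break
                }
              }
            }
            ## nothing claimable and no split possible: the remaining
            ## searchers stay floaters today
            if (!claimed) break
          }
        }

        ## pairing (females in arrival order)
        fsearch <- which(vapply(females, function(f) f$state == "search", logical(1)))
        if (length(fsearch)) {
          ord <- fsearch[order(vapply(females, function(f) f$arrive, numeric(1))[fsearch])]
          for (k in ord) {
            free <- which(vapply(terrs, function(tr)
              tr$active && is.na(tr$female), logical(1)))
            free <- free[vapply(terrs[free], function(tr)
              tr$total >= params$MINFEMACCEPTSCORE, logical(1))]
            if (!length(free)) break
            t <- free[which.max(vapply(terrs[free], function(tr) tr$total,
                                       numeric(1)))]
            terrs[[t]]$female <- k
            females[[k]]$state <- "paired"
            females[[k]]$terr <- t
            females[[k]]$stage <- "pre_breeding"
            females[[k]]$deficit <- 0L
            log_event(ev, yr, doy, "pair_formed", terr = terrs[[t]]$id,
                      poly = terrs[[t]]$centre_pid)
          }
        }

        ## female breeding state machines
        for (k in seq_along(females)) {
          f <- females[[k]]
          if (!identical(f$state, "paired") || is.na(f$terr)) next
          tr <- terrs[[f$terr]]
          tp <- which(tr$comp > 0)
          f_food <- food[tp]; f_acc <- access[tp]
          np_pid <- tr$centre_pid
          npi <- match(np_pid, grid$polygons$id)
          stage <- f$stage
          if (identical(stage, "pre_breeding")) {
            if (doy <= params$LAST_INITIATION &&
                Hgt[npi] >= params$NEST_HEIGHT_MIN &&
                Hgt[npi] <= params$NEST_HEIGHT_MAX) {
              nest_id <- nest_id + 1L
              f$nest <- nest_id
              f$eggs_target <- sample(params$CLUTCH_SIZES:params$CLUTCH_SIZE_MAX, 1)
              f$eggs <- 1L
              f$stage <- "laying"
              log_event(ev, yr, doy, "lay_start", id = paste0("N", nest_id),
                        poly = np_pid, terr = tr$id)
            }
          } else if (identical(stage, "laying")) {
            if (!daily_predation_survives("clutch", params)) {
              log_event(ev, yr, doy, "clutch_predated_laying",
                        id = paste0("N", f$nest), poly = np_pid, terr = tr$id)
              f <- fail_attempt(f, params)
            } else {
              f$eggs <- f$eggs + 1L
              if (f$eggs >= f$eggs_target) {
                f$clutch <- new_clutch(f$eggs, params)
                f$stage <- "incubating"
                f$deficit <- 0L
                log_event(ev, yr, doy, "incubation_start",
                          id = paste0("N", f$nest), poly = np_pid,
                          terr = tr$id, value = f$eggs)
              }
            }
          } else if (identical(stage, "incubating")) {
            if (!daily_predation_survives("clutch", params)) {
              log_event(ev, yr, doy, "clutch_predated",
                        id = paste0("N", f$nest), poly = np_pid, terr = tr$id)
              f <- fail_attempt(f, params)
            } else {
              req <- adult_requirement(temp, 0, params)
              fs <- female_daily_step(req, f_food, f_acc, rain, params)
              severe <- fs$gained < params$DEFICIT_SEVERITY * req
              f$deficit <- if (severe) f$deficit + 1L else 0L
              if (f$deficit >= params$DEFICIT_DAYS_ABANDON) {
                log_event(ev, yr, doy, "clutch_other",
                          id = paste0("N", f$nest), poly = np_pid,
                          terr = tr$id, cause = "abandoned")
                f <- fail_attempt(f, params)
              } else {
                f$clutch <- incubation_step(f$clutch, fs$trips, temp, params)
                if (f$clutch$hatched) {
                  log_event(ev, yr, doy, "hatch", id = paste0("N", f$nest),
                            poly = np_pid, terr = tr$id,
                            value = f$clutch$days)
                  f$brood <- new_brood(f$clutch$eggs)
                  f$clutch <- NULL
                  f$stage <- "caring"
                  f$deficit <- 0L
                }
              }
            }
          } else if (identical(stage, "caring")) {
            if (!daily_predation_survives("nestling", params)) {
              log_event(ev, yr, doy, "brood_predated",
                        id = paste0("N", f$nest), poly = np_pid, terr = tr$id)
              f <- fail_attempt(f, params)
            } else {
              demand <- f$brood$n * params$PEMAX / params$ASSIMILATION
              share_f <- params$PROVISION_SHARE_FEMALE * demand
              share_m <- demand - share_f
              delivered <- 0
              for (share in c(share_f, share_m)) {
                maint <- adult_requirement(temp, 0, params)
                res <- female_daily_step(maint + share, f_food, f_acc, rain,
                                         params)
                delivered <- delivered + min(share, max(0, res$gained - maint))
              }
              f$brood <- nestling_daily_step(f$brood, delivered, params)
              if (!f$brood$alive) {
                log_event(ev, yr, doy, "brood_other",
                          id = paste0("N", f$nest), poly = np_pid,
                          terr = tr$id, cause = "starved")
                f <- fail_attempt(f, params)
              } else if (f$brood$left) {
                log_event(ev, yr, doy, "brood_leave",
                          id = paste0("N", f$nest), poly = np_pid,
                          terr = tr$id, value = f$brood$age)
                prefledge[[length(prefledge) + 1L]] <- list(
                  n = f$brood$n,
                  days_left = params$INDEPENDENCE_AGE - f$brood$age)
                f <- fail_attempt(f, params)  # same post-attempt path
              }
            }
          } else if (identical(stage, "post")) {
            f$renest <- f$renest - 1L
            if (f$renest <= 0L) {
              if (doy <= params$LAST_INITIATION && terrs[[f$terr]]$active &&
                  terrs[[f$terr]]$total >= params$MINFEMACCEPTSCORE) {
                f$stage <- "pre_breeding"
              } else {
                f$stage <- "idle"
              }
            }
          } else if (identical(stage, "idle")) {
            if (doy <= params$LAST_INITIATION && terrs[[f$terr]]$active &&
                terrs[[f$terr]]$total >= params$MINFEMACCEPTSCORE &&
                Hgt[npi] >= params$NEST_HEIGHT_MIN &&
                Hgt[npi] <= params$NEST_HEIGHT_MAX) {
              f$stage <- "pre_breeding"
            }
          }
          females[[k]] <- f
        }

        ## pre-fledglings
        if (length(prefledge)) {
          keep <- logical(length(prefledge))
          for (g in seq_along(prefledge)) {
            pf <- prefledge[[g]]
            pf$n <- stats::rbinom(1, pf$n, params$PREFLEDGE_SURVIVAL)
            pf$days_left <- pf$days_left - 1L
            if (pf$n <= 0) { keep[g] <- FALSE; next }
            if (pf$days_left <= 0L) {
              n_juveniles <- n_juveniles + pf$n
              log_event(ev, yr, doy, "independent", value = pf$n)
              keep[g] <- FALSE
            } else {
              prefledge[[g]] <- pf
              keep[g] <- TRUE
            }
          }
          prefledge <- prefledge[keep]
        }

        ## daily state
        n_pairs <- sum(vapply(terrs, function(tr)
          tr$active && !is.na(tr$female), logical(1)))
        n_terr <- sum(vapply(terrs, function(tr) tr$active, logical(1)))
        daily[[length(daily) + 1L]] <- c(yr, doy, n_terr, n_pairs)

        ## season end: dissolve everything
        if (doy == params$SEASON_END) {
          for (t in seq_along(terrs)) {
            tr <- terrs[[t]]
            if (!tr$active) next
            if (!is.na(tr$female)) {
              f <- females[[tr$female]]
              if (!is.na(f$stage) &&
                  f$stage %in% c("laying", "incubating", "caring")) {
                what <- if (identical(f$stage, "caring")) "brood_other" else "clutch_other"
                if (!identical(f$stage, "laying"))
                  log_event(ev, yr, doy, what, id = paste0("N", f$nest),
                            poly = tr$centre_pid, terr = tr$id,
                            cause = "season_end")
                females[[tr$female]] <- fail_attempt(f, params)
              }
              log_event(ev, yr, doy, "pair_dissolved", terr = tr$id,
                        cause = "season_end")
            }
            terrs[[t]]$active <- FALSE
            log_event(ev, yr, doy, "territory_abandoned", terr = tr$id,
                      poly = tr$centre_pid, cause = "season_end")
          }
          ## remaining dependent young survive (or not) to independence
          for (g in seq_along(prefledge)) {
            pf <- prefledge[[g]]
            n <- pf$n
            for (d2 in seq_len(max(0L, pf$days_left)))
              n <- stats::rbinom(1, n, params$PREFLEDGE_SURVIVAL)
            if (n > 0) {
              n_juveniles <- n_juveniles + n
              log_event(ev, yr, doy, "independent", value = n)
            }
          }
          prefledge <- list()
        }
      }
    }

    ## ---- overwinter: return mortality, recruitment, immigration ----
    surv_m <- stats::rbinom(1, n_males,
                            1 - params$ADULTRETURNMORT * params$PERCENT_SCALE)
    surv_f <- stats::rbinom(1, n_females,
                            1 - params$ADULTRETURNMORT * params$PERCENT_SCALE)
    surv_j <- stats::rbinom(1, n_juveniles,
                            1 - params$JUVRETURNMORT * params$PERCENT_SCALE)
    jm <- stats::rbinom(1, surv_j, 0.5)
    imm <- stats::rpois(1, scenario$immigrants_mean %||% params$IMMIGRANTS_MEAN)
    im <- stats::rbinom(1, imm, 0.5)
    n_males <- surv_m + jm + im
    n_females <- surv_f + (surv_j - jm) + (imm - im)
    log_event(ev, yr, 365L, "year_end", value = n_males + n_females)
  }

  dmat <- do.call(rbind, daily)
  daily_df <- data.frame(year = dmat[, 1], doy = dmat[, 2],
                         territories = dmat[, 3], pairs = dmat[, 4])
  structure(list(events = eventlog_df(ev), daily = daily_df, years = years,
                 scenario_name = scenario$name %||% "scenario"),
            class = "skylark_run")
}

## close out a breeding attempt and schedule a renesting wait
fail_attempt <- function(f, params) {
  f$clutch <- NULL; f$brood <- NULL
  f$eggs <- 0L; f$eggs_target <- 0L
  f$nest <- NA_integer_
  f$deficit <- 0L
  f$stage <- "post"
  f$renest <- params$RENEST_DELAY
  f
}

## vectorised: does each rect in `rects` overlap any row of `occ`?
overlaps_any <- function(rects, occ) {
  out <- logical(nrow(rects))
  for (i in seq_len(nrow(occ))) {
    out <- out | (rects[, 1] <= occ[i, 2] & rects[, 2] >= occ[i, 1] &
                    rects[, 3] <= occ[i, 4] & rects[, 4] >= occ[i, 3])
  }
  out
}

active_rects <- function(terrs) {
  act <- Filter(function(tr) tr$active, terrs)
  if (!length(act)) return(matrix(0L, 0, 4))
  do.call(rbind, lapply(act, `[[`, "rect"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.skylark_run <- function(x, ...) {
  cat("<skylark_run> '", x$scenario_name, "': ", x$years, " years, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Write the event log and daily state of a run to CSV
#'
#' @param run a `skylark_run`.
#' @param events_path,daily_path output paths (either may be `NULL`).
#' @export
write_run <- function(run, events_path = NULL, daily_path = NULL) {
  if (!is.null(events_path))
    utils::write.csv(run$events, events_path, row.names = FALSE)
  if (!is.null(daily_path))
    utils::write.csv(run$daily, daily_path, row.names = FALSE)
  invisible(run)
}
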