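#' Habitat score of a cell (per square metre)
#'
#' Piecewise score by vegetation structure: below 3 cm the bare-earth value;
#' hedgerow/woodland (or any vegetation above 3 m, and buildings/water as
#' tall objects) the strong negative hedge value; 1.1-2 m and 2-3 m bands
#' their own penalties; between 3 cm and 1.1 m the baseline crop score
#' modulated by power-law height and density factors
#' `f_h = min(1, (h/HEIGHTCONST_C)^HEIGHTCONST_B)` and
#' `f_d = min(1, (d/DENSITYCONST_C)^DENSITYCONST_B)`. Premiums for patchy
#' vegetation (< 2 m), open tramlines and skylark scrapes are then added.
#'
#' @param height vegetation height (cm).
#' @param density vegetation density (0-100).
#' @param elem_type element type string.
#' @param is_patchy logical, patchy vegetation.
#' @param tramlines_open logical, tramlines currently open.
#' @param has_scrapes logical, field provided with skylark scrapes.
#' @param params a `skylark_params` object.
#' @return habitat score per m2 (can be negative).
#' @examples
#' p <- skylark_params()
#' habitat_score_cell(2, 0, "field", params = p)    # bare earth: 3
#' habitat_score_cell(76, 10, "field", params = p)  # power-law band
#' @export
habitat_score_cell <- function(height, density, elem_type,
                               is_patchy = FALSE, tramlines_open = FALSE,
                               has_scrapes = FALSE, params = skylark_params()) {
  if (elem_type %in% c("hedgerow", "woodland", "building", "water") ||
      height > 300) {
    return(params$HQHEDGE)
  }
  if (elem_type == "road") return(0)
  if (height < 3) {
    base <- params$HQBAREEARTH
  } else if (height > 200) {
    base <- params$HQTALLVEG
  } else if (height > 110) {
    base <- params$HQTALL
  } else {
    f_h <- min(1, (height / params$HEIGHTCONST_C)^params$HEIGHTCONST_B)
    f_d <- if (density <= 0) 1
           else min(1, (density / params$DENSITYCONST_C)^params$DENSITYCONST_B)
    base <- params$Q0_CROP_SCORE * f_h * f_d
  }
  if (is_patchy && height < 200) base <- base + params$PATCHYPREMIUM
  if (tramlines_open) base <- base + params$TRAMLINEPREMIUM
  if (has_scrapes) base <- base + params$SKSCRAPESPREMIUM
  base
}

#' Per-polygon habitat scores for a landscape state
#'
#' @param grid a `landscape_grid`.
#' @param height,density numeric vectors over polygons.
#' @param is_patchy,tramlines_open,has_scrapes logical vectors over polygons.
#' @param params a `skylark_params` object.
#' @return numeric vector of scores per m2, one per polygon.
#' @export
polygon_scores <- function(grid, height, density, is_patchy, tramlines_open,
                           has_scrapes, params = skylark_params()) {
  vapply(seq_len(nrow(grid$polygons)), function(i)
    habitat_score_cell(height[i], density[i], grid$polygons$elem_type[i],
                       is_patchy[i], tramlines_open[i], has_scrapes[i],
                       params),
    numeric(1))
}

#' Foraging accessibility of vegetation
#'
#' Accessibility declines linearly above the height and density thresholds:
#' `a_h = clamp(1 + HINDCONSTH_B * (h - HEIGHTCONST_C), 0, 1)` for
#' `h > HEIGHTCONST_C` (else 1), analogously `a_d`. The combined hindrance
#' `H = 1 - a_h * a_d` is reduced by the proportion `TRAMLINE_FORAGING` when
#' tramlines are open or scrapes are present.
#'
#' @param height vegetation height (cm).
#' @param density vegetation density (0-100).
#' @param tram_or_scrapes logical: open tramlines or scrapes give access.
#' @param params a `skylark_params` object.
#' @return accessibility fraction in \[0, 1\].
#' @export
foraging_accessibility <- function(height, density, tram_or_scrapes = FALSE,
                                   params = skylark_params()) {
  a_h <- ifelse(height > params$HEIGHTCONST_C,
                pmin(1, pmax(0, 1 + params$HINDCONSTH_B *
                                  (height - params$HEIGHTCONST_C))), 1)
  a_d <- ifelse(density > params$DENSITYCONST_C,
                pmin(1, pmax(0, 1 + params$HINDCONSTD_B *
                                  (density - params$DENSITYCONST_C))), 1)
  H <- 1 - a_h * a_d
  H <- ifelse(tram_or_scrapes, H * (1 - params$TRAMLINE_FORAGING), H)
  1 - H
}

#' Rain hindrance to foraging
#'
#' `min(1, (r / MAXFEEDRAIN)^RAINHINDPOW)`: foraging is fully prevented at or
#' above `MAXFEEDRAIN` mm/day.
#'
#' @param precipitation mm/day (vectorised).
#' @param params a `skylark_params` object.
#' @return hindrance fraction in \[0, 1\].
#' @export
rain_hindrance <- function(precipitation, params = skylark_params()) {
  pmin(1, (precipitation / params$MAXFEEDRAIN)^params$RAINHINDPOW)
}

#' Food intake over a foraging bout
#'
#' The bird forages its best cell first: with per-cell insect food and
#' accessibility, intake is
#' `max(food * accessibility) * EXTRACTION_RATE * (1 - rain_hindrance) *
#' minutes`.
#'
#' @param insect_food food density per candidate cell (units/m2).
#' @param accessibility accessibility per candidate cell.
#' @param precipitation mm/day.
#' @param minutes foraging minutes.
#' @param params a `skylark_params` object.
#' @return food units obtained.
#' @export
foraging_intake <- function(insect_food, accessibility, precipitation,
                            minutes, params = skylark_params()) {
  stopifnot(minutes >= 0)
  if (minutes == 0 || length(insect_food) == 0) return(0)
  best <- max(insect_food * accessibility)
  best * params$EXTRACTION_RATE *
    (1 - rain_hindrance(precipitation, params)) * minutes
}

## ---- territories ----------------------------------------------------------

#' Candidate territory blocks on a coarse lattice
#'
#' Square blocks of the configured territory area, centred on a lattice with
#' spacing of half the block side, clipped to the grid. For each candidate
#' the polygon composition (cell counts per polygon) is precomputed so that
#' daily scores are a single matrix product.
#'
#' @param grid a `landscape_grid`.
#' @param params a `skylark_params` object.
#' @return list with `rects` (matrix r0,r1,c0,c1), `centres` (matrix row,col),
#'   `comp` (candidates x polygons cell-count matrix), `centre_poly`
#'   (polygon index of each centre).
#' @export
territory_candidates <- function(grid, params = skylark_params()) {
  side <- max(1L, as.integer(round(sqrt(params$TERRITORY_AREA) / grid$cellsize)))
  sp <- max(1L, side %/% 2L)
  half <- side %/% 2L
  lattice <- function(n) {
    lo <- min(n, 1L + half)
    hi <- max(lo, n - (side - half) + 1L)
    unique(pmin(pmax(seq.int(lo, hi, by = sp), 1L), n))
  }
  rs <- lattice(grid$nrows)
  cs <- lattice(grid$ncols)
  centres <- as.matrix(expand.grid(row = rs, col = cs))
  np <- nrow(grid$polygons)
  n <- nrow(centres)
  rects <- matrix(0L, n, 4, dimnames = list(NULL, c("r0", "r1", "c0", "c1")))
  comp <- matrix(0, n, np)
  for (i in seq_len(n)) {
    r0 <- max(1L, centres[i, 1] - half); r1 <- min(grid$nrows, r0 + side - 1L)
    r0 <- max(1L, r1 - side + 1L)
    c0 <- max(1L, centres[i, 2] - half); c1 <- min(grid$ncols, c0 + side - 1L)
    c0 <- max(1L, c1 - side + 1L)
    rects[i, ] <- c(r0, r1, c0, c1)
    comp[i, ] <- tabulate(grid$poly_index[r0:r1, c0:c1], nbins = np)
  }
  dup <- duplicated(rects)
  list(rects = rects[!dup, , drop = FALSE],
       centres = centres[!dup, , drop = FALSE],
       comp = comp[!dup, , drop = FALSE],
       centre_poly = grid$poly_index[centres[!dup, , drop = FALSE]])
}

#' Evaluate a candidate territory centred on a cell
#'
#' The territory is the square block of the configured area centred on the
#' cell (clipped to the grid); its total score is the sum of cell scores
#' times cell area. It is acceptable if the total reaches
#' `MINFEMACCEPTSCORE`.
#'
#' @param grid a `landscape_grid`.
#' @param poly_scores score per m2 per polygon (see [polygon_scores()]).
#' @param centre length-2 integer (row, col).
#' @param params a `skylark_params` object.
#' @return list with `rect`, `total`, `acceptable`.
#' @export
evaluate_territory <- function(grid, poly_scores, centre,
                               params = skylark_params()) {
  side <- max(1L, round(sqrt(params$TERRITORY_AREA) / grid$cellsize))
  half <- side %/% 2L
  r0 <- max(1L, centre[1] - half); r1 <- min(grid$nrows, r0 + side - 1L)
  r0 <- max(1L, r1 - side + 1L)
  c0 <- max(1L, centre[2] - half); c1 <- min(grid$ncols, c0 + side - 1L)
  c0 <- max(1L, c1 - side + 1L)
  comp <- tabulate(grid$poly_index[r0:r1, c0:c1], nbins = nrow(grid$polygons))
  total <- sum(comp * poly_scores) * grid$cellsize^2
  list(rect = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1), total = total,
       acceptable = total >= params$MINFEMACCEPTSCORE)
}

rects_overlap <- function(rect, others) {
  if (is.null(others) || nrow(others) == 0) return(FALSE)
  any(rect[1] <= others[, 2] & rect[2] >= others[, 1] &
      rect[3] <= others[, 4] & rect[4] >= others[, 3])
}

rect_comp <- function(grid, rect) {
  tabulate(grid$poly_index[rect[1]:rect[2], rect[3]:rect[4]],
           nbins = nrow(grid$polygons))
}

#' Best-first territory acquisition on the candidate lattice
#'
#' Males (in arrival order) each claim the highest-scoring acceptable
#' candidate block not overlapping an existing territory. A male finding no
#' free acceptable candidate may split the best occupied territory whose
#' score reaches `SPLIT_MULTIPLIER * MINFEMACCEPTSCORE` along its longer
#' axis, provided both halves remain acceptable; the newcomer takes one half.
#' Males left without a territory are floaters.
#'
#' @param grid a `landscape_grid`.
#' @param poly_scores score per m2 per polygon.
#' @param n_males number of males searching (claims are made one at a time).
#' @param params a `skylark_params` object.
#' @param cands precomputed [territory_candidates()] (recomputed if `NULL`).
#' @param nest_ok logical vector over polygons: nest-capable centre (defaults
#'   to field-like elements).
#' @return list of territories (`rect`, `centre`, `centre_poly`, `total`) and
#'   `n_floaters`.
#' @export
acquire_territories <- function(grid, poly_scores, n_males,
                                params = skylark_params(), cands = NULL,
                                nest_ok = NULL) {
  if (is.null(cands)) cands <- territory_candidates(grid, params)
  if (is.null(nest_ok))
    nest_ok <- grid$polygons$elem_type %in%
      c("field", "permanent_grass", "field_margin")
  a <- grid$cellsize^2
  scores <- as.numeric(cands$comp %*% poly_scores) * a
  free <- rep(TRUE, length(scores)) & nest_ok[cands$centre_poly]
  terrs <- list()
  occ <- matrix(0L, 0, 4)
  for (m in seq_len(n_males)) {
    avail <- which(free & scores >= params$MINFEMACCEPTSCORE)
    claimed <- FALSE
    while (length(avail)) {
      best <- avail[which.max(scores[avail])]
      rect <- cands$rects[best, ]
      if (rects_overlap(rect, occ)) {
        free[best] <- FALSE
        avail <- setdiff(avail, best)
        next
      }
      terrs[[length(terrs) + 1L]] <- list(
        rect = rect, centre = cands$centres[best, ],
        centre_poly = cands$centre_poly[best], total = scores[best])
      occ <- rbind(occ, rect)
      free[best] <- FALSE
      claimed <- TRUE
      break
    }
    if (!claimed && length(terrs)) {
      tot <- vapply(terrs, `[[`, numeric(1), "total")
      cand <- order(tot, decreasing = TRUE)
      for (ti in cand) {
        if (tot[ti] < params$SPLIT_MULTIPLIER * params$MINFEMACCEPTSCORE) break
        halves <- split_rect(terrs[[ti]]$rect)
        t1 <- sum(rect_comp(grid, halves[[1]]) * poly_scores) * a
        t2 <- sum(rect_comp(grid, halves[[2]]) * poly_scores) * a
        if (t1 >= params$MINFEMACCEPTSCORE && t2 >= params$MINFEMACCEPTSCORE) {
          terrs[[ti]] <- half_territory(grid, halves[[1]], t1)
          terrs[[length(terrs) + 1L]] <- half_territory(grid, halves[[2]], t2)
          occ <- do.call(rbind, lapply(terrs, `[[`, "rect"))
          claimed <- TRUE
          break
        }
      }
    }
  }
  list(territories = terrs, n_floaters = n_males - length(terrs))
}

split_rect <- function(rect) {
  h <- rect[2] - rect[1] + 1L; w <- rect[4] - rect[3] + 1L
  if (h >= w) {
    mid <- rect[1] + h %/% 2L - 1L
    list(c(rect[1], mid, rect[3], rect[4]),
         c(mid + 1L, rect[2], rect[3], rect[4]))
  } else {
    mid <- rect[3] + w %/% 2L - 1L
    list(c(rect[1], rect[2], rect[3], mid),
         c(rect[1], rect[2], mid + 1L, rect[4]))
  }
}

half_territory <- function(grid, rect, total) {
  centre <- c(row = (rect[1] + rect[2]) %/% 2L, col = (rect[3] + rect[4]) %/% 2L)
  list(rect = rect, centre = centre,
       centre_poly = grid$poly_index[centre[1], centre[2]], total = total)
}
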