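## Cellular fire-spread surrogate: annual uniform ignition, fuel-gated
## stochastic contagion, fire effects on state classes, and burn metrics.
## This is a documented surrogate for a full fire-behavior model: it keeps
## the qualitative mechanism (fire size grows with contiguous high-cover
## area) without weather, wind, or topography.

#' Fuel table
#'
#' Per-state-class spread weights of the fire surrogate. Only classes with
#' more than 10% buffelgrass cover carry fire, so by default `cover_10_50`,
#' `cover_gt50`, and `converted` are flammable; everything else has weight
#' 0. Excluded (forest) cells never burn.
#'
#' @param weights named numeric spread weights in `[0, 1]` for the flammable
#'   classes.
#' @return Numeric vector of length 7 (one weight per [STATE_CLASSES] code).
#' @export
fuel_table <- function(weights = c(cover_10_50 = 0.6, cover_gt50 = 1.0,
                                   converted = 1.0)) {
  if (any(weights < 0 | weights > 1))
    stop("spread weights must lie in [0, 1]", call. = FALSE)
  w <- stats::setNames(numeric(length(STATE_CLASSES)), names(STATE_CLASSES))
  w[names(weights)] <- weights
  if (any(w[c("uninvaded", "seedbank", "cover_lt1", "cover_1_10")] > 0))
    stop("classes at or below 10% cover cannot carry fire", call. = FALSE)
  w
}

#' Draw one annual ignition location
#'
#' One cell uniformly at random among all simulated (non-excluded) cells,
#' flammable or not: an ignition landing on non-flammable fuel produces a
#' zero-area fire.
#'
#' @param landscape a `bg_landscape`.
#' @param seed optional integer seeding the draw.
#' @return Integer `c(row, col)`.
#' @export
ignite <- function(landscape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- which(landscape$stratum != STRATA[["excluded"]])
  if (!length(cells)) stop("landscape has no simulated cells", call. = FALSE)
  idx <- cells[sample.int(length(cells), 1L)]
  c(row = ((idx - 1L) %% landscape$nrow) + 1L,
    col = ((idx - 1L) %/% landscape$nrow) + 1L)
}

#' Spread a fire from an ignition cell
#'
#' Stochastic contagion on the grid: if the ignition cell is non-flammable
#' the burned set is empty; otherwise each burning cell attempts each of its
#' 8 neighbors exactly once, succeeding with probability
#' `spread_prob * weight(neighbor)`, and the front advances until no new
#' cells ignite or `max_steps` rounds have run. With success probability 1
#' the burned set is exactly the 8-connected flammable component of the
#' ignition.
#'
#' @param landscape a `bg_landscape`.
#' @param ignition integer `c(row, col)`.
#' @param fuels a [fuel_table()].
#' @param spread_prob baseline spread probability in `[0, 1]` (a per-year
#'   weather-severity multiplier can be folded in here).
#' @param max_steps maximum number of front-growth rounds (>= 0).
#' @param seed optional integer seeding the draws.
#' @param year year label recorded on the event.
#' @return A `bg_fire_event`: list with `year`, `ignition`, `burned`
#'   (integer cell indices), `area_ha`, and `reached_forest_edge`.
#' @export
spread_fire <- function(landscape, ignition, fuels = fuel_table(),
                        spread_prob = 0.35, max_steps = 1000L, seed = NULL,
                        year = NA_integer_) {
  if (spread_prob < 0 || spread_prob > 1)
    stop("spread_prob must lie in [0, 1]", call. = FALSE)
  if (max_steps < 0) stop("max_steps must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nr <- landscape$nrow; nc <- landscape$ncol
  weight <- matrix(fuels[landscape$state + 1L], nr, nc)
  weight[landscape$stratum == STRATA[["excluded"]]] <- 0
  ign_idx <- (ignition[[2]] - 1L) * nr + ignition[[1]]
  burned <- matrix(FALSE, nr, nc)
  if (weight[ign_idx] > 0) {
    burned[ign_idx] <- TRUE
    frontier <- ign_idx
    off <- moore_offsets(1)
    steps <- 0L
    while (length(frontier) && steps < max_steps) {
      fr_r <- ((frontier - 1L) %% nr) + 1L
      fr_c <- ((frontier - 1L) %/% nr) + 1L
      new_cells <- integer(0)
      for (k in seq_len(nrow(off))) {
        rr <- fr_r + off$di[k]; cc <- fr_c + off$dj[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        tgt <- (cc[ok] - 1L) * nr + rr[ok]
        tgt <- tgt[!burned[tgt] & weight[tgt] > 0 & !(tgt %in% new_cells)]
        # duplicate targets within one offset are impossible (one source per
        # offset per target); across offsets each source-target attempt is an
        # independent trial, so re-draw for targets not yet ignited this round
        if (length(tgt)) {
          hit <- stats::runif(length(tgt)) < spread_prob * weight[tgt]
          new_cells <- c(new_cells, tgt[hit])
        }
      }
      burned[new_cells] <- TRUE
      frontier <- new_cells
      steps <- steps + 1L
    }
  }
  burned_idx <- which(burned)
  structure(
    list(year = year,
         ignition = c(row = as.integer(ignition[[1]]),
                      col = as.integer(ignition[[2]])),
         burned = burned_idx,
         area_ha = length(burned_idx) * landscape$cell_area,
         reached_forest_edge = any(landscape$forest_edge[burned_idx])),
    class = "bg_fire_event")
}

#' Apply a fire event's effects to the landscape
#'
#' Burned `cover_gt50` cells convert to buffelgrass savanna (`converted`,
#' age 0); burned `converted` cells stay converted. Burned `cover_10_50`
#' cells follow the configured post-burn rule: `"none"` (default, class and
#' age retained), `"reset_age"`, or `"promote"` (to `cover_gt50`, age 0).
#' Unburned cells are unchanged.
#'
#' @param landscape a `bg_landscape`.
#' @param event a `bg_fire_event`.
#' @param post_burn_cover_10_50 rule for burned `cover_10_50` cells.
#' @return The updated landscape.
#' @export
apply_fire_effects <- function(landscape, event,
                               post_burn_cover_10_50 = c("none", "reset_age",
                                                         "promote")) {
  rule <- match.arg(post_burn_cover_10_50)
  b <- event$burned
  if (!length(b)) return(landscape)
  hi <- b[landscape$state[b] == STATE_CLASSES[["cover_gt50"]]]
  landscape$state[hi] <- STATE_CLASSES[["converted"]]
  landscape$age[hi] <- 0L
  if (rule != "none") {
    mid <- b[landscape$state[b] == STATE_CLASSES[["cover_10_50"]]]
    if (rule == "reset_age") {
      landscape$age[mid] <- 0L
    } else {
      landscape$state[mid] <- STATE_CLASSES[["cover_gt50"]]
      landscape$age[mid] <- 0L
    }
  }
  landscape
}

#' Summarize a simulation's fire events
#'
#' Computes the burn metrics of a 30-year run: number of years with fire (a
#' year with an ignition and burned area > 0 ha), cumulative burned area
#' (sum of annual burned areas, so re-burned cells count every year),
#' landscape burned area (area of the union of all cells that burned in at
#' least one year), and the number of fires reaching the forest edge.
#'
#' @param events list of `bg_fire_event`, one per simulated year (possibly
#'   zero-area).
#' @param cell_area cell area in ha.
#' @return Named list: `years_with_fire`, `cumulative_burned_ha`,
#'   `landscape_burned_ha`, `fires_to_forest_edge`.
#' @export
fire_metrics <- function(events, cell_area = 0.25) {
  areas <- vapply(events, function(e) e$area_ha, numeric(1))
  union_cells <- unique(unlist(lapply(events, function(e) e$burned)))
  list(
    years_with_fire = sum(areas > 0),
    cumulative_burned_ha = sum(areas),
    landscape_burned_ha = length(union_cells) * cell_area,
    fires_to_forest_edge = sum(vapply(events, function(e)
      isTRUE(e$reached_forest_edge), logical(1)))
  )
}
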