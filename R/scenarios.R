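## Factorial scenario construction and the Monte Carlo ensemble runner.

LEVELS3 <- c("low", "moderate", "high")
ACCEL_LEVELS <- c(low = "slow", moderate = "moderate", high = "fast")

#' Define one simulation scenario
#'
#' One factorial combination of initialization levels (habitat-suitability
#' threshold and initial buffelgrass conditions) and ecological parameter
#' levels (patch infill rate, wet-year probability, wet-year infill
#' acceleration), plus the fire switch and the wet-year timing mode.
#'
#' @param scenario_id character label.
#' @param susceptibility,initial initialization levels.
#' @param infill,wet_prob infill-rate and wet-year-probability levels
#'   (`low`/`moderate`/`high`).
#' @param accel acceleration level (`slow`/`moderate`/`fast`).
#' @param fire logical; simulate annual ignitions and spread?
#' @param wet_mode wet-year timing across realizations: `"variable"`
#'   (independent schedules) or `"constant"` (one schedule shared by all
#'   realizations, as used with fire).
#' @param horizon simulated years.
#' @param n_reps Monte Carlo realizations.
#' @param seed master seed; scenarios run with the same master seed share
#'   random-number streams (common random numbers).
#' @return A list of class `bg_scenario`.
#' @export
scenario_spec <- function(scenario_id = NULL,
                          susceptibility = "moderate", initial = "moderate",
                          infill = "moderate", wet_prob = "moderate",
                          accel = "moderate",
                          fire = FALSE,
                          wet_mode = c("variable", "constant"),
                          horizon = 30L, n_reps = 20L, seed = 1L) {
  susceptibility <- match.arg(susceptibility, LEVELS3)
  initial <- match.arg(initial, LEVELS3)
  infill <- match.arg(infill, LEVELS3)
  wet_prob <- match.arg(wet_prob, LEVELS3)
  accel <- match.arg(accel, unname(ACCEL_LEVELS))
  wet_mode <- match.arg(wet_mode)
  if (is.null(scenario_id))
    scenario_id <- paste(susceptibility, initial, infill, wet_prob, accel,
                         if (fire) "fire" else "nofire", sep = "_")
  structure(
    list(scenario_id = scenario_id, susceptibility = susceptibility,
         initial = initial, infill = infill, wet_prob = wet_prob,
         accel = accel, fire = fire, wet_mode = wet_mode,
         horizon = as.integer(horizon), n_reps = as.integer(n_reps),
         seed = as.integer(seed)),
    class = "bg_scenario")
}

#' The nine initialization scenarios
#'
#' The 3 x 3 cross of habitat-susceptibility level and initial-condition
#' level, at moderate ecological parameters.
#'
#' @param ... arguments passed to [scenario_spec()] (e.g. `horizon`,
#'   `n_reps`, `seed`, `fire`).
#' @return List of 9 `bg_scenario`.
#' @export
build_initialization_scenarios <- function(...) {
  grid <- expand.grid(susceptibility = LEVELS3, initial = LEVELS3,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scenario_spec(susceptibility = grid$susceptibility[i],
                  initial = grid$initial[i], ...))
}

#' The 27 ecological scenarios
#'
#' The 3 x 3 x 3 cross of infill rate, wet-year probability, and wet-year
#' infill acceleration, at moderate initialization. Includes the named
#' presets: dry-slow = (low, low, slow), moderate = (moderate, moderate,
#' moderate), wet-fast = (high, high, fast).
#'
#' @inheritParams build_initialization_scenarios
#' @return List of 27 `bg_scenario`.
#' @export
build_ecological_scenarios <- function(...) {
  grid <- expand.grid(infill = LEVELS3, wet_prob = LEVELS3,
                      accel = unname(ACCEL_LEVELS), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scenario_spec(infill = grid$infill[i], wet_prob = grid$wet_prob[i],
                  accel = grid$accel[i], ...))
}

#' The three fire-scenario ecological presets
#'
#' Fire runs are restricted by default to the lower-bound, middle, and
#' upper-bound ecological presets (dry-slow, moderate, wet-fast), with fire
#' on and constant wet-year timing.
#'
#' @inheritParams build_initialization_scenarios
#' @return List of 3 `bg_scenario`.
#' @export
build_fire_scenarios <- function(...) {
  presets <- list(c("low", "low", "slow"),
                  c("moderate", "moderate", "moderate"),
                  c("high", "high", "fast"))
  ids <- c("dry-slow", "moderate", "wet-fast")
  lapply(seq_along(presets), function(i)
    scenario_spec(scenario_id = ids[i], infill = presets[[i]][1],
                  wet_prob = presets[[i]][2], accel = presets[[i]][3],
                  fire = TRUE, wet_mode = "constant", ...))
}

#' Run the Monte Carlo ensemble for one scenario
#'
#' For each realization: build (or reuse) the initialized landscape, draw
#' the wet-year schedule, and iterate the annual step (dispersal, seedbank
#' dynamics, infill), followed by one ignition and fire spread when fire is
#' enabled. Per-year state-class areas, invaded area, and burned area are
#' recorded.
#'
#' Child seeds are derived from the master seed and (process, realization,
#' year) only, so scenarios run with the same master seed are coupled by
#' common random numbers: dominance comparisons (faster vs slower infill,
#' wetter vs drier) hold realization by realization.
#'
#' @param spec a [scenario_spec()].
#' @param landscape_config a [landscape_config()].
#' @param params optional [eco_params()]; defaults to the spec's levels.
#' @param fire_config list with `spread_prob`, `max_steps`, `weights`
#'   (passed to [fuel_table()]), `post_burn_cover_10_50`.
#' @param share_landscape logical; reuse one landscape across realizations
#'   (default `FALSE`: each realization regenerates its landscape from a
#'   realization-specific seed).
#' @return A list of class `bg_results`: `table` (data frame keyed by
#'   scenario_id, realization, year with per-class areas in ha,
#'   `invaded_ha`, `burned_ha`), `events` (per-realization fire event
#'   lists), `fire_summary` (per-realization [fire_metrics()] data frame,
#'   or `NULL`), and `spec`.
#' @export
run_ensemble <- function(spec, landscape_config = landscape_config(),
                         params = NULL, fire_config = list(),
                         share_landscape = FALSE) {
  params <- params %||%
    eco_params(infill = spec$infill, wet = spec$wet_prob, accel = spec$accel,
               ecotone_invadable = landscape_config$ecotone_invadable)
  fc <- utils::modifyList(list(spread_prob = 0.35, max_steps = 1000L,
                               weights = c(cover_10_50 = 0.6, cover_gt50 = 1.0,
                                           converted = 1.0),
                               post_burn_cover_10_50 = "none"),
                          fire_config)
  fuels <- fuel_table(fc$weights)
  horizon <- spec$horizon
  rows <- vector("list", spec$n_reps * (horizon + 1L))
  events_by_rep <- vector("list", spec$n_reps)
  fire_rows <- vector("list", spec$n_reps)
  shared_ls <- if (share_landscape)
    build_landscape(landscape_config, spec$susceptibility, spec$initial,
                    seed = derive_seed(spec$seed, "landscape", 0L))
  ri <- 0L
  for (rep in seq_len(spec$n_reps)) {
    ls <- if (share_landscape) shared_ls else
      build_landscape(landscape_config, spec$susceptibility, spec$initial,
                      seed = derive_seed(spec$seed, "landscape", rep))
    wet_rep <- if (spec$wet_mode == "constant") 0L else rep
    wet <- sample_wet_years(params$wet_prob, horizon, mode = "constant",
                            n_reps = 1L,
                            seed = derive_seed(spec$seed, "wet", wet_rep))[, 1]
    events <- vector("list", horizon)
    record <- function(year, burned) {
      a <- state_class_areas(ls)
      ri <<- ri + 1L
      rows[[ri]] <<- data.frame(scenario_id = spec$scenario_id,
                                realization = rep, year = year,
                                as.list(a), invaded_ha = invaded_area(a),
                                burned_ha = burned, check.names = FALSE)
    }
    record(0L, 0)
    for (t in seq_len(horizon)) {
      ls <- stsm_step(ls, wet[t], params,
                      seed = derive_seed(spec$seed, "eco", rep, t))
      burned <- 0
      if (isTRUE(spec$fire)) {
        fseed <- derive_seed(spec$seed, "fire", rep, t)
        ign <- ignite(ls, seed = fseed)
        ev <- spread_fire(ls, ign, fuels, fc$spread_prob, fc$max_steps,
                          seed = derive_seed(fseed, "spread"), year = t)
        ls <- apply_fire_effects(ls, ev, fc$post_burn_cover_10_50)
        events[[t]] <- ev
        burned <- ev$area_ha
      }
      record(t, burned)
    }
    events_by_rep[[rep]] <- events
    if (isTRUE(spec$fire)) {
      fm <- fire_metrics(events, cell_area = ls$cell_area)
      fire_rows[[rep]] <- data.frame(scenario_id = spec$scenario_id,
                                     realization = rep, as.list(fm))
    }
  }
  structure(
    list(table = do.call(rbind, rows[seq_len(ri)]),
         events = events_by_rep,
         fire_summary = if (isTRUE(spec$fire)) do.call(rbind, fire_rows),
         spec = spec),
    class = "bg_results")
}

#' @export
print.bg_results <- function(x, ...) {
  cat(sprintf("<bg_results> scenario '%s': %d realizations x %d years\n",
              x$spec$scenario_id, x$spec$n_reps, x$spec$horizon))
  last <- x$table[x$table$year == x$spec$horizon, ]
  cat(sprintf("end-of-run invaded area: mean %.1f ha (range %.1f-%.1f)\n",
              mean(last$invaded_ha), min(last$invaded_ha), max(last$invaded_ha)))
  invisible(x)
}

#' Run a set of scenarios and bind their result tables
#'
#' @param specs list of [scenario_spec()].
#' @param ... passed to [run_ensemble()].
#' @return Data frame of all scenarios' result rows, with the design levels
#'   attached as columns.
#' @export
run_scenarios <- function(specs, ...) {
  out <- lapply(specs, function(sp) {
    res <- run_ensemble(sp, ...)
    tab <- res$table
    tab$susceptibility <- sp$susceptibility
    tab$initial <- sp$initial
    tab$infill <- sp$infill
    tab$wet_prob <- sp$wet_prob
    tab$accel <- sp$accel
    tab
  })
  do.call(rbind, out)
}
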