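## YAML run configuration: schema-validated loading with full defaults.

#' Default run configuration
#'
#' The complete configuration schema with every default resolved, in four
#' sections: `landscape` (grid extent, suitability autocorrelation, target
#' areas, clustering), `ecological` (time-in-class tables, wet-year
#' probability levels, acceleration divisors, dispersal and seedbank
#' parameters), `fire` (fuel weights, spread probability, post-burn rule),
#' and `run` (horizon, realizations, wet-year timing mode, scenario set,
#' output directory).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  lc <- landscape_config()
  list(
    landscape = list(
      ncol = lc$ncol, desert_rows = lc$desert_rows,
      ecotone_rows = lc$ecotone_rows, forest_rows = lc$forest_rows,
      cell_area = lc$cell_area, correlation_length = lc$correlation_length,
      n_patches = lc$n_patches, ecotone_invadable = lc$ecotone_invadable,
      scale_targets = TRUE,
      susceptible_ha = as.list(lc$susceptible_ha),
      thresholds = as.list(lc$thresholds),
      cover_ha = lapply(seq_len(nrow(lc$cover_ha)),
                        function(i) as.list(lc$cover_ha[i, ])) |>
        stats::setNames(rownames(lc$cover_ha))
    ),
    ecological = list(
      # time-in-class defaults are working assumptions, not elicited data
      time_in_class = list(low = c(12, 12, 12), moderate = c(8, 8, 8),
                           high = c(5, 5, 5)),
      wet_prob = list(low = 0.10, moderate = 0.267, high = 0.57),
      accel_divisor = list(slow = 2L, moderate = 3L, fast = 4L),
      dispersal_prob = list(cover_lt1 = 0.01, cover_1_10 = 0.05,
                            cover_10_50 = 0.15, cover_gt50 = 0.30),
      dispersal_radius = 1L,
      establishment_prob = 0.2,
      seedbank_mortality = 0.1,
      seedbank_in_unsusceptible = TRUE
    ),
    fire = list(
      spread_prob = 0.35, max_steps = 1000L,
      weights = list(cover_10_50 = 0.6, cover_gt50 = 1.0, converted = 1.0),
      post_burn_cover_10_50 = "none"
    ),
    run = list(
      horizon = 30L, n_reps = 20L, wet_mode = "variable",
      scenario_set = "ecological", out_dir = "output", seed = 1L
    )
  )
}

check_range <- function(cfg, keys, lo, hi) {
  for (k in keys) {
    v <- unlist(cfg[[k[1]]][[k[2]]])
    if (any(v < lo | v > hi))
      stop(sprintf("config key %s.%s out of range [%g, %g]", k[1], k[2], lo, hi),
           call. = FALSE)
  }
}

validate_config <- function(cfg) {
  defaults <- default_config()
  for (sec in names(cfg)) {
    if (!sec %in% names(defaults))
      stop("unknown config section: ", sec, call. = FALSE)
    extra <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(extra))
      stop(sprintf("unknown config key: %s.%s", sec, extra[1]), call. = FALSE)
  }
  check_range(cfg, list(c("ecological", "wet_prob"),
                        c("ecological", "dispersal_prob"),
                        c("ecological", "establishment_prob"),
                        c("ecological", "seedbank_mortality"),
                        c("fire", "spread_prob"),
                        c("fire", "weights"),
                        c("landscape", "thresholds")), 0, 1)
  if (any(unlist(cfg$ecological$time_in_class) < 1))
    stop("config key ecological.time_in_class must be >= 1", call. = FALSE)
  if (any(unlist(cfg$ecological$accel_divisor) < 1))
    stop("config key ecological.accel_divisor must be >= 1", call. = FALSE)
  if (cfg$run$horizon < 1 || cfg$run$n_reps < 1)
    stop("config keys run.horizon and run.n_reps must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Missing keys take their documented defaults; unknown keys and
#' out-of-range values are rejected with the offending key named. An empty
#' file yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return Validated nested list (see [default_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("unknown config section: ", sec, call. = FALSE)
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
    }
    # surface unknown keys before merge hides them
    validate_config(user)
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration snapshot
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Landscape settings from a run configuration
#' @param cfg configuration list from [load_config()].
#' @return A [landscape_config()].
#' @export
config_landscape <- function(cfg) {
  l <- cfg$landscape
  cover <- do.call(rbind, lapply(l$cover_ha, unlist))
  landscape_config(ncol = l$ncol, desert_rows = l$desert_rows,
                   ecotone_rows = l$ecotone_rows, forest_rows = l$forest_rows,
                   cell_area = l$cell_area,
                   correlation_length = l$correlation_length,
                   n_patches = l$n_patches,
                   ecotone_invadable = l$ecotone_invadable,
                   susceptible_ha = unlist(l$susceptible_ha),
                   thresholds = unlist(l$thresholds),
                   cover_ha = cover,
                   scale_targets = l$scale_targets)
}

#' Ecological parameters from a run configuration
#' @param cfg configuration list from [load_config()].
#' @param infill,wet,accel levels selecting among the configured values.
#' @return An [eco_params()].
#' @export
config_params <- function(cfg, infill = "moderate", wet = "moderate",
                          accel = "moderate") {
  e <- cfg$ecological
  tic <- unlist(e$time_in_class[[infill]])
  names(tic) <- c("cover_lt1", "cover_1_10", "cover_10_50")
  eco_params(time_in_class = tic,
             wet_prob = e$wet_prob[[wet]],
             accel_divisor = e$accel_divisor[[accel]],
             dispersal_prob = unlist(e$dispersal_prob),
             dispersal_radius = e$dispersal_radius,
             establishment_prob = e$establishment_prob,
             seedbank_mortality = e$seedbank_mortality,
             seedbank_in_unsusceptible = e$seedbank_in_unsusceptible,
             ecotone_invadable = cfg$landscape$ecotone_invadable)
}
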