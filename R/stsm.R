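## State-and-transition engine: annual per-cell updates for seed dispersal,
## seedbank establishment/mortality, and age-deterministic patch infill with
## wet-year acceleration.

#' Ecological parameter set
#'
#' Collects the transition parameters of the annual update. The three named
#' levels of each uncertain factor follow the sensitivity design: patch
#' infill rate (time-in-class, years), wet-year probability, and the
#' wet-year infill acceleration divisor.
#'
#' Time-in-class defaults (12 / 8 / 5 years for low / moderate / high infill)
#' are working assumptions chosen so a cell takes one to a few decades to run
#' through the cover classes under dry conditions; no public figures exist
#' for the expert-elicited transition times. All qualitative behavior of the
#' simulator (orderings, conservation, dominance) holds for any values.
#'
#' @param infill infill-rate level (`low` = slow, `high` = fast) or a named
#'   numeric of times-in-class via `time_in_class`.
#' @param wet wet-year probability level.
#' @param accel wet-year acceleration level (`slow`/`moderate`/`fast`,
#'   divisors 2/3/4).
#' @param time_in_class optional named numeric overriding the level: years a
#'   cell must accumulate in `cover_lt1`, `cover_1_10`, `cover_10_50` before
#'   advancing.
#' @param wet_prob optional numeric in `[0, 1]` overriding the level.
#' @param accel_divisor optional integer >= 1 overriding the level.
#' @param dispersal_prob named per-source-class annual probability that a
#'   source seeds a given neighboring cell; `converted` sources use the
#'   `cover_gt50` value.
#' @param dispersal_radius Moore-neighborhood radius of the dispersal kernel
#'   (cells).
#' @param establishment_prob annual probability a seedbank cell establishes
#'   to `cover_lt1` (invadable strata only).
#' @param seedbank_mortality annual probability a non-establishing seedbank
#'   cell reverts to uninvaded.
#' @param seedbank_in_unsusceptible logical; may unsusceptible desert hold
#'   (but never establish) seedbank?
#' @param ecotone_invadable logical; is the grassland ecotone invadable like
#'   susceptible desert?
#' @return A list of class `bg_params`.
#' @export
eco_params <- function(infill = "moderate", wet = "moderate",
                       accel = "moderate",
                       time_in_class = NULL, wet_prob = NULL,
                       accel_divisor = NULL,
                       dispersal_prob = c(cover_lt1 = 0.01, cover_1_10 = 0.05,
                                          cover_10_50 = 0.15, cover_gt50 = 0.30),
                       dispersal_radius = 1L,
                       establishment_prob = 0.2,
                       seedbank_mortality = 0.1,
                       seedbank_in_unsusceptible = TRUE,
                       ecotone_invadable = TRUE) {
  tic_levels <- list(low = c(cover_lt1 = 12, cover_1_10 = 12, cover_10_50 = 12),
                     moderate = c(cover_lt1 = 8, cover_1_10 = 8, cover_10_50 = 8),
                     high = c(cover_lt1 = 5, cover_1_10 = 5, cover_10_50 = 5))
  p_levels <- c(low = 0.10, moderate = 0.267, high = 0.57)
  n_levels <- c(slow = 2L, moderate = 3L, fast = 4L)
  T_c <- time_in_class %||% tic_levels[[match.arg(infill, names(tic_levels))]]
  p <- wet_prob %||% p_levels[[match.arg(wet, names(p_levels))]]
  n <- accel_divisor %||% n_levels[[match.arg(accel, names(n_levels))]]
  probs <- c(dispersal_prob, establishment_prob, seedbank_mortality, p)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(T_c < 1)) stop("time-in-class must be >= 1 year", call. = FALSE)
  if (n < 1) stop("acceleration divisor must be >= 1", call. = FALSE)
  structure(
    list(time_in_class = T_c, wet_prob = p, accel_divisor = as.integer(n),
         dispersal_prob = dispersal_prob,
         dispersal_radius = as.integer(dispersal_radius),
         establishment_prob = establishment_prob,
         seedbank_mortality = seedbank_mortality,
         seedbank_in_unsusceptible = seedbank_in_unsusceptible,
         ecotone_invadable = ecotone_invadable),
    class = "bg_params")
}

#' Years added to class age in one time step
#'
#' A cell's class age normally advances 1 year per step. In a wet year the
#' acceleration divisor `n` is applied additively: the default 1 year plus
#' `n - 1` additional years, so a divisor of 2 adds 1 extra year, 3 adds 2,
#' and 4 adds 3, making transitions 2x/3x/4x as fast if every year were wet.
#'
#' @param n acceleration divisor (integer >= 1).
#' @param is_wet logical; is this a wet year?
#' @return Integer total years added (1 if dry, `n` if wet).
#' @export
age_increment <- function(n, is_wet) {
  if (n < 1) stop("acceleration divisor must be >= 1", call. = FALSE)
  if (isTRUE(is_wet)) as.integer(n) else 1L
}

#' Patch-infill transition for a single cell
#'
#' A cover-class cell advances to the next cover class only when its class
#' age has reached the time-in-class for its current class, and its age then
#' resets to 0. At most one advance occurs per call regardless of overshoot.
#' `cover_gt50` and `converted` never advance by infill.
#'
#' @param state a [STATE_CLASSES] code of a cover class (or `converted`).
#' @param age current class age (years).
#' @param time_in_class named numeric as in [eco_params()].
#' @return `list(state, age)` after the (possible) transition.
#' @export
infill_transition <- function(state, age, time_in_class) {
  if (!state %in% c(COVER_CLASSES, STATE_CLASSES[["converted"]]))
    stop("infill applies to cover-class cells only", call. = FALSE)
  if (state %in% INFILL_CLASSES) {
    cls <- names(STATE_CLASSES)[match(state, STATE_CLASSES)]
    if (age >= time_in_class[[cls]]) return(list(state = state + 1L, age = 0L))
  }
  list(state = as.integer(state), age = as.integer(age))
}

# strata where buffelgrass can establish and grow
invadable_mask <- function(landscape, params) {
  m <- landscape$stratum == STRATA[["susceptible_desert"]]
  if (isTRUE(params$ecotone_invadable))
    m <- m | landscape$stratum == STRATA[["grassland_ecotone"]]
  m
}

# strata that can hold seedbank (a superset of invadable when allowed)
seedbank_mask <- function(landscape, params) {
  m <- invadable_mask(landscape, params)
  if (isTRUE(params$seedbank_in_unsusceptible))
    m <- m | landscape$stratum == STRATA[["unsusceptible_desert"]]
  m
}

#' Annual seed dispersal
#'
#' Every occupied cell (any cover class; `converted` disperses like
#' `cover_gt50`) seeds each uninvaded cell within the Moore-kernel radius
#' independently with its per-source-class probability; a target cell
#' becomes seedbank if any trial succeeds. Targets must lie in a stratum
#' that can hold seedbank.
#'
#' @param landscape a `bg_landscape`.
#' @param params a [eco_params()].
#' @param seed optional integer; if given, seeds the draw.
#' @return The updated landscape.
#' @export
disperse_seeds <- function(landscape, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(landscape$nrow * landscape$ncol),
              landscape$nrow, landscape$ncol)
  disperse_seeds_u(landscape, params, u)
}

# dispersal with an externally supplied uniform matrix (fixed draw order
# keeps common-random-number coupling across scenarios)
disperse_seeds_u <- function(landscape, params, u) {
  st <- landscape$state
  r <- params$dispersal_radius
  q <- params$dispersal_prob
  # probability a target is NOT seeded by any in-kernel source
  p_none <- matrix(1, landscape$nrow, landscape$ncol)
  src_classes <- list(cover_lt1 = STATE_CLASSES[["cover_lt1"]],
                      cover_1_10 = STATE_CLASSES[["cover_1_10"]],
                      cover_10_50 = STATE_CLASSES[["cover_10_50"]],
                      cover_gt50 = c(STATE_CLASSES[["cover_gt50"]],
                                     STATE_CLASSES[["converted"]]))
  for (cls in names(src_classes)) {
    cnt <- neighbor_sum(matrix(st %in% src_classes[[cls]],
                               landscape$nrow, landscape$ncol), r)
    p_none <- p_none * (1 - q[[cls]])^cnt
  }
  targets <- st == STATE_CLASSES[["uninvaded"]] & seedbank_mask(landscape, params)
  newly <- targets & (u < 1 - p_none)
  landscape$state[newly] <- STATE_CLASSES[["seedbank"]]
  landscape$age[newly] <- 0L
  landscape
}

#' Annual seedbank establishment and mortality
#'
#' Each seedbank cell first attempts establishment (to `cover_lt1`, age 0;
#' invadable strata only); a cell that does not establish dies back to
#' uninvaded with the mortality probability, else persists as seedbank.
#'
#' @inheritParams disperse_seeds
#' @return The updated landscape.
#' @export
seedbank_update <- function(landscape, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- landscape$nrow * landscape$ncol
  u_est <- matrix(stats::runif(n), landscape$nrow, landscape$ncol)
  u_mort <- matrix(stats::runif(n), landscape$nrow, landscape$ncol)
  seedbank_update_u(landscape, params, u_est, u_mort,
                    landscape$state == STATE_CLASSES[["seedbank"]])
}

seedbank_update_u <- function(landscape, params, u_est, u_mort, eligible) {
  est <- eligible & invadable_mask(landscape, params) &
    (u_est < params$establishment_prob)
  mort <- eligible & !est & (u_mort < params$seedbank_mortality)
  landscape$state[est] <- STATE_CLASSES[["cover_lt1"]]
  landscape$age[est] <- 0L
  landscape$state[mort] <- STATE_CLASSES[["uninvaded"]]
  landscape$age[mort] <- 0L
  landscape
}

#' One annual step of the state-and-transition model
#'
#' Applies, in order: seed dispersal; seedbank establishment/mortality
#' (restricted to cells already seedbank at the start of the step, so seed
#' that arrives this year cannot establish this year); then aging and patch
#' infill for cells that were cover classes at the start of the step. Aging
#' adds [age_increment()] years; a cell advances at most one cover class per
#' year and its age resets to 0 on transition even if the increment overshot.
#'
#' Stochastic draws are three full-grid uniform matrices in a fixed order,
#' so runs that share a seed are coupled by common random numbers whatever
#' the parameter levels.
#'
#' @param landscape a `bg_landscape`.
#' @param is_wet logical; is this year wet?
#' @param params a [eco_params()].
#' @param seed optional integer seeding the step's draws.
#' @return The updated landscape.
#' @export
stsm_step <- function(landscape, is_wet, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- landscape$nrow; nc <- landscape$ncol
  u_disp <- matrix(stats::runif(nr * nc), nr, nc)
  u_est <- matrix(stats::runif(nr * nc), nr, nc)
  u_mort <- matrix(stats::runif(nr * nc), nr, nc)

  pre_seedbank <- landscape$state == STATE_CLASSES[["seedbank"]]
  pre_cover <- matrix(landscape$state %in% COVER_CLASSES, nr, nc)

  landscape <- disperse_seeds_u(landscape, params, u_disp)
  landscape <- seedbank_update_u(landscape, params, u_est, u_mort, pre_seedbank)

  inc <- age_increment(params$accel_divisor, is_wet)
  landscape$age[pre_cover] <- landscape$age[pre_cover] + inc
  T_by_code <- rep(Inf, length(STATE_CLASSES))
  T_by_code[INFILL_CLASSES + 1L] <-
    params$time_in_class[c("cover_lt1", "cover_1_10", "cover_10_50")]
  Tmat <- matrix(T_by_code[landscape$state + 1L], nr, nc)
  adv <- pre_cover & matrix(landscape$state %in% INFILL_CLASSES, nr, nc) &
    landscape$age >= Tmat
  landscape$state[adv] <- landscape$state[adv] + 1L
  landscape$age[adv] <- 0L
  landscape
}
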