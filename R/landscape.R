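## Synthetic landscape generation: autocorrelated habitat-suitability surface,
## strata layout (desert / grassland ecotone / excluded forest), threshold
## calibration against target susceptible areas, and clustered initial
## buffelgrass cover allocation.

#' Generate an autocorrelated habitat-suitability surface
#'
#' Produces a continuous suitability value in `[0, 1]` per grid cell by
#' smoothing Gaussian white noise with a Gaussian kernel (FFT convolution on
#' a torus) and mapping the standardized field through the normal CDF. The
#' transform is monotone, so cell ranks are those of the smoothed field.
#' `correlation_length = 0` returns mutually independent cell values.
#'
#' @param dims integer vector `c(nrow, ncol)` of grid dimensions.
#' @param correlation_length kernel standard deviation in cells (>= 0);
#'   controls how fast spatial autocorrelation decays.
#' @param seed integer seed; identical inputs give identical surfaces.
#' @return A numeric `nrow x ncol` matrix with values in `[0, 1]`.
#' @export
generate_suitability_surface <- function(dims, correlation_length = 15, seed = 1L) {
  if (length(dims) != 2 || any(dims < 1))
    stop("`dims` must be two positive grid dimensions", call. = FALSE)
  if (correlation_length < 0)
    stop("`correlation_length` must be >= 0", call. = FALSE)
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (correlation_length > 0) {
    # toroidal distances for the kernel, centered at (1, 1)
    dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    d2 <- outer(dr^2, dc^2, "+")
    kern <- exp(-0.5 * d2 / correlation_length^2)
    kern <- kern / sum(kern)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
    z <- (z - mean(z)) / stats::sd(z)
  }
  stats::pnorm(z)
}

#' Build the stratum layout for a synthetic landscape
#'
#' Lays out a desert block (initially all unsusceptible), a grassland-ecotone
#' strip, and an excluded high-elevation forest block along the bottom edge,
#' and flags forest-edge cells (simulated cells 8-adjacent to the excluded
#' block).
#'
#' @param desert_rows,ecotone_rows,forest_rows row counts of the three bands.
#' @param ncol number of grid columns.
#' @return A list with integer matrix `stratum` (codes in [STRATA]), logical
#'   matrix `forest_edge`, and logical matrix `desert_mask`.
#' @export
base_strata <- function(desert_rows, ecotone_rows, forest_rows, ncol) {
  if (any(c(desert_rows, ncol) < 1) || any(c(ecotone_rows, forest_rows) < 0))
    stop("invalid strata dimensions", call. = FALSE)
  nr <- desert_rows + ecotone_rows + forest_rows
  stratum <- matrix(STRATA[["unsusceptible_desert"]], nr, ncol)
  if (ecotone_rows > 0)
    stratum[desert_rows + seq_len(ecotone_rows), ] <- STRATA[["grassland_ecotone"]]
  if (forest_rows > 0)
    stratum[desert_rows + ecotone_rows + seq_len(forest_rows), ] <- STRATA[["excluded"]]
  excluded <- stratum == STRATA[["excluded"]]
  forest_edge <- neighbor_any(excluded) & !excluded
  list(stratum = stratum,
       forest_edge = forest_edge,
       desert_mask = stratum == STRATA[["unsusceptible_desert"]])
}

#' Calibrate a suitability surface against target susceptible areas
#'
#' Rescales a surface by a monotone piecewise-linear transform so that, for
#' each susceptibility threshold, the desert area at or above the threshold
#' matches its target area (e.g. the reference 9,735 / 10,845 / 12,013 ha at
#' thresholds 0.55 / 0.50 / 0.45). Cell rank order is preserved.
#'
#' @param surface numeric matrix from [generate_suitability_surface()].
#' @param taus numeric thresholds in `[0, 1]`.
#' @param target_ha target susceptible area (ha) for each threshold; must be
#'   non-increasing in `taus` and each no larger than the desert area.
#' @param desert_mask logical matrix marking desert cells.
#' @param cell_area cell area in ha (default 0.25).
#' @return The rescaled surface (values in `[0, 1]`, ranks unchanged).
#' @export
calibrate_thresholds <- function(surface, taus, target_ha, desert_mask,
                                 cell_area = 0.25) {
  if (length(taus) != length(target_ha))
    stop("`taus` and `target_ha` lengths differ", call. = FALSE)
  if (any(taus < 0 | taus > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  n_desert <- sum(desert_mask)
  m <- round(target_ha / cell_area) # cells that must sit at/above each tau
  if (any(m > n_desert))
    stop("calibration target exceeds desert area", call. = FALSE)
  ord <- order(taus)
  taus <- taus[ord]; m <- m[ord]
  if (is.unsorted(rev(m)))
    stop("target areas must be non-increasing in threshold", call. = FALSE)
  sv <- sort(surface[desert_mask])
  cut_for <- function(mk) {
    if (mk >= n_desert) return(sv[1] - 1e-9)
    if (mk <= 0) return(sv[n_desert] + 1e-9)
    (sv[n_desert - mk] + sv[n_desert - mk + 1]) / 2
  }
  x <- vapply(m, cut_for, numeric(1))
  # anchors must be strictly increasing for a rank-preserving transform
  x <- cummax(x + seq_along(x) * 1e-12)
  lo <- min(surface, x) - 1e-6
  hi <- max(surface, x) + 1e-6
  xa <- c(lo, x, hi)
  ya <- c(0, taus, 1)
  out <- matrix(stats::approx(xa, ya, xout = as.vector(surface))$y,
                nrow(surface), ncol(surface))
  pmin(pmax(out, 0), 1)
}

#' Classify desert cells as susceptible by thresholding suitability
#'
#' Desert cells whose suitability is at or above the threshold become
#' susceptible desert; remaining desert cells become unsusceptible. Ecotone
#' and excluded cells are untouched. Lower thresholds give larger (supersets
#' of) susceptible areas.
#'
#' @param surface suitability matrix (typically calibrated).
#' @param tau threshold in `[0, 1]`.
#' @param strata list from [base_strata()].
#' @return `strata` with its `stratum` matrix updated.
#' @export
threshold_susceptibility <- function(surface, tau, strata) {
  if (tau < 0 || tau > 1)
    stop("threshold `tau` must lie in [0, 1]", call. = FALSE)
  desert <- strata$stratum %in% c(STRATA[["unsusceptible_desert"]],
                                  STRATA[["susceptible_desert"]])
  dim(desert) <- dim(strata$stratum)
  sus <- desert & surface >= tau
  strata$stratum[desert] <- STRATA[["unsusceptible_desert"]]
  strata$stratum[sus] <- STRATA[["susceptible_desert"]]
  strata$desert_mask <- desert
  strata
}

#' Assign clustered initial buffelgrass cover
#'
#' Places the target area of each cover class onto susceptible desert cells
#' by seeded cluster growth: patch seeds are drawn with probability
#' proportional to suitability, and patches accrete 8-neighbor cells (again
#' suitability-weighted) until the class target is met. Targets are rounded
#' to whole cells, so assigned area is within one cell (0.25 ha) of target.
#'
#' @param strata list from [threshold_susceptibility()].
#' @param surface suitability matrix (placement weights).
#' @param targets_ha named numeric: target area (ha) for `cover_lt1`,
#'   `cover_1_10`, `cover_10_50`, `cover_gt50`.
#' @param n_patches number of cluster seeds per cover class.
#' @param seed integer seed; identical inputs give identical placements.
#' @param cell_area cell area in ha.
#' @return A landscape object (see [new_landscape()]) with class ages 0.
#' @export
assign_initial_cover <- function(strata, surface, targets_ha,
                                 n_patches = 25, seed = 1L, cell_area = 0.25) {
  classes <- c("cover_lt1", "cover_1_10", "cover_10_50", "cover_gt50")
  missing_cls <- setdiff(names(targets_ha), classes)
  if (length(missing_cls))
    stop("unknown cover class in targets: ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  m_cells <- round(targets_ha / cell_area)
  if (sum(m_cells) > sum(strata$stratum == STRATA[["susceptible_desert"]]))
    stop("initial cover targets exceed susceptible area", call. = FALSE)
  set.seed(seed)
  nr <- nrow(strata$stratum); nc <- ncol(strata$stratum)
  state <- matrix(STATE_CLASSES[["uninvaded"]], nr, nc)
  avail <- strata$stratum == STRATA[["susceptible_desert"]]
  off <- moore_offsets(1)
  neighbors_of <- function(idx) {
    r <- ((idx - 1) %% nr) + 1
    c <- ((idx - 1) %/% nr) + 1
    nb <- integer(0)
    for (k in seq_len(nrow(off))) {
      rr <- r + off$di[k]; cc <- c + off$dj[k]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- c(nb, (cc[ok] - 1) * nr + rr[ok])
    }
    unique(nb)
  }
  # high-cover cores first so later (larger, lower-cover) classes wrap them
  for (cls in rev(classes)) {
    need <- if (cls %in% names(m_cells)) m_cells[[cls]] else 0
    if (is.na(need) || need <= 0) next
    pool <- which(avail)
    if (!length(pool)) stop("no susceptible cells left for ", cls, call. = FALSE)
    k <- max(1L, min(n_patches, need, length(pool)))
    seeds <- pool[sample.int(length(pool), k, prob = surface[pool])]
    assigned <- seeds[seq_len(min(k, need))]
    avail[assigned] <- FALSE
    frontier <- setdiff(unlist(lapply(assigned, neighbors_of)), assigned)
    frontier <- frontier[avail[frontier]]
    while (length(assigned) < need) {
      if (!length(frontier)) {
        pool <- which(avail)
        pick <- pool[sample.int(length(pool), 1, prob = surface[pool])]
      } else if (length(frontier) == 1L) {
        pick <- frontier
      } else {
        pick <- frontier[sample.int(length(frontier), 1, prob = surface[frontier])]
      }
      assigned <- c(assigned, pick)
      avail[pick] <- FALSE
      frontier <- frontier[frontier != pick]
      nb <- neighbors_of(pick)
      frontier <- unique(c(frontier, nb[avail[nb]]))
    }
    state[assigned] <- STATE_CLASSES[[cls]]
  }
  new_landscape(strata, state = state, suitability = surface,
                cell_area = cell_area)
}

#' Construct a landscape object
#'
#' Bundles the stratum layout, per-cell state class, class age, forest-edge
#' mask and suitability surface into the container the simulator operates on.
#'
#' @param strata list from [base_strata()] / [threshold_susceptibility()].
#' @param state integer matrix of [STATE_CLASSES] codes (default all
#'   uninvaded).
#' @param age integer matrix of in-class ages (default 0).
#' @param suitability optional numeric matrix.
#' @param cell_area cell area in ha.
#' @return An object of class `bg_landscape`.
#' @export
new_landscape <- function(strata, state = NULL, age = NULL,
                          suitability = NULL, cell_area = 0.25) {
  nr <- nrow(strata$stratum); nc <- ncol(strata$stratum)
  if (is.null(state)) state <- matrix(STATE_CLASSES[["uninvaded"]], nr, nc)
  if (is.null(age)) age <- matrix(0L, nr, nc)
  storage.mode(state) <- "integer"
  storage.mode(age) <- "integer"
  # non-simulated cells carry no state
  state[strata$stratum == STRATA[["excluded"]]] <- STATE_CLASSES[["uninvaded"]]
  structure(
    list(nrow = nr, ncol = nc, cell_area = cell_area,
         stratum = strata$stratum, state = state, age = age,
         forest_edge = strata$forest_edge, suitability = suitability),
    class = "bg_landscape")
}

#' @export
print.bg_landscape <- function(x, ...) {
  cat(sprintf("<bg_landscape> %d x %d cells (%.2f ha each, %.1f ha simulated)\n",
              x$nrow, x$ncol, x$cell_area,
              sum(x$stratum != STRATA[["excluded"]]) * x$cell_area))
  a <- state_class_areas(x)
  cat("state-class areas (ha):\n")
  print(round(a, 2))
  invisible(x)
}

#' Landscape configuration
#'
#' Defaults describe a 20,000-ha desert (80,000 cells of 0.25 ha) with a
#' grassland-ecotone strip and an excluded forest block along one edge, and
#' target areas from the reference initialization table. When the grid is
#' smaller or larger than the default, target areas are scaled in proportion
#' to desert area so initialization stays feasible at any extent.
#'
#' @param ncol,desert_rows,ecotone_rows,forest_rows grid layout (cells).
#' @param cell_area cell area in ha.
#' @param correlation_length suitability autocorrelation scale (cells).
#' @param n_patches cluster seeds per cover class for initial placement.
#' @param ecotone_invadable logical; can buffelgrass invade the ecotone?
#' @param susceptible_ha named target susceptible areas (ha) by
#'   susceptibility level.
#' @param thresholds named suitability thresholds by susceptibility level.
#' @param cover_ha 3 x 4 matrix of initial cover-class target areas (ha),
#'   rows `low`/`moderate`/`high` initial-condition levels, columns the four
#'   cover classes.
#' @param scale_targets logical; when `TRUE` (default), `susceptible_ha` and
#'   `cover_ha` are interpreted as areas on the reference 20,000-ha desert
#'   and rescaled in proportion to the configured desert extent, so
#'   initialization stays feasible on any grid. Set `FALSE` to use the
#'   supplied areas verbatim.
#' @return A list of class `bg_landscape_config`.
#' @export
landscape_config <- function(ncol = 400L, desert_rows = 200L,
                             ecotone_rows = 5L, forest_rows = 5L,
                             cell_area = 0.25,
                             correlation_length = 15,
                             n_patches = 25L,
                             ecotone_invadable = TRUE,
                             susceptible_ha = c(low = 9735, moderate = 10845,
                                                high = 12013),
                             thresholds = c(low = 0.55, moderate = 0.50,
                                            high = 0.45),
                             cover_ha = NULL,
                             scale_targets = TRUE) {
  table1_cover <- rbind(
    low      = c(cover_lt1 = 173.9, cover_1_10 = 807.0,
                 cover_10_50 = 503, cover_gt50 = 121.8),
    moderate = c(cover_lt1 = 178.8, cover_1_10 = 818.3,
                 cover_10_50 = 503, cover_gt50 = 121.8),
    high     = c(cover_lt1 = 184.0, cover_1_10 = 829.5,
                 cover_10_50 = 503, cover_gt50 = 121.9))
  desert_ha <- desert_rows * ncol * cell_area
  scale <- if (isTRUE(scale_targets)) desert_ha / 20000 else 1
  cover_ha <- (cover_ha %||% table1_cover) * scale
  susceptible_ha <- susceptible_ha * scale
  structure(
    list(ncol = as.integer(ncol), desert_rows = as.integer(desert_rows),
         ecotone_rows = as.integer(ecotone_rows),
         forest_rows = as.integer(forest_rows),
         cell_area = cell_area, correlation_length = correlation_length,
         n_patches = as.integer(n_patches),
         ecotone_invadable = ecotone_invadable,
         susceptible_ha = susceptible_ha, thresholds = thresholds,
         cover_ha = cover_ha),
    class = "bg_landscape_config")
}

#' Build a complete initialized landscape
#'
#' Full pipeline: generate the suitability surface, calibrate it against the
#' configured target susceptible areas, threshold at the chosen
#' susceptibility level, and place clustered initial cover for the chosen
#' initial-condition level.
#'
#' @param config a [landscape_config()].
#' @param susceptibility,initial levels in `low` / `moderate` / `high`.
#' @param seed integer seed controlling surface and placement.
#' @return A `bg_landscape`.
#' @export
build_landscape <- function(config = landscape_config(),
                            susceptibility = "moderate",
                            initial = "moderate", seed = 1L) {
  susceptibility <- match.arg(susceptibility, c("low", "moderate", "high"))
  initial <- match.arg(initial, c("low", "moderate", "high"))
  strata <- base_strata(config$desert_rows, config$ecotone_rows,
                        config$forest_rows, config$ncol)
  dims <- dim(strata$stratum)
  surf <- generate_suitability_surface(dims, config$correlation_length,
                                       seed = derive_seed(seed, "surface"))
  surf <- calibrate_thresholds(surf, config$thresholds, config$susceptible_ha,
                               strata$desert_mask, config$cell_area)
  strata <- threshold_susceptibility(surf, config$thresholds[[susceptibility]],
                                     strata)
  assign_initial_cover(strata, surf, config$cover_ha[initial, ],
                       n_patches = config$n_patches,
                       seed = derive_seed(seed, "cover"),
                       cell_area = config$cell_area)
}
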