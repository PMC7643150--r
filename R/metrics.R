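## Summary statistics and sensitivity attribution: midpoint-weighted invaded
## area, state-class area accounting, ANOVA variance decomposition, and
## hierarchical partitioning of explained variance.

#' Midpoint cover weights
#'
#' Weight per state class used to collapse class areas into a single
#' invaded-area statistic: each cover class counts at its midpoint percent
#' cover (0.005, 0.055, 0.3, 0.75) and converted savanna at 1.0; uninvaded
#' and seedbank carry no cover.
#'
#' @return Named numeric vector over [STATE_CLASSES].
#' @export
cover_weights <- function() {
  c(uninvaded = 0, seedbank = 0, cover_lt1 = 0.005, cover_1_10 = 0.055,
    cover_10_50 = 0.3, cover_gt50 = 0.75, converted = 1.0)
}

#' Midpoint-weighted invaded area
#'
#' Sum over state classes of class area times midpoint cover weight.
#'
#' @param class_areas named numeric of areas (ha) per state class; classes
#'   not named are taken as 0.
#' @param weights weights as from [cover_weights()].
#' @return Invaded area in ha.
#' @export
invaded_area <- function(class_areas, weights = cover_weights()) {
  if (any(class_areas < 0)) stop("areas must be >= 0", call. = FALSE)
  unknown <- setdiff(names(class_areas), names(weights))
  if (length(unknown))
    stop("unknown state class: ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(class_areas * weights[names(class_areas)])
}

#' Per-class areas of a landscape
#'
#' Cell counts per state class over simulated (non-excluded) cells, times
#' the cell area. Always sums to the total simulated area.
#'
#' @param landscape a `bg_landscape`.
#' @return Named numeric vector (ha) over all state classes.
#' @export
state_class_areas <- function(landscape) {
  sim <- landscape$stratum != STRATA[["excluded"]]
  counts <- tabulate(landscape$state[sim] + 1L, nbins = length(STATE_CLASSES))
  stats::setNames(counts * landscape$cell_area, names(STATE_CLASSES))
}

#' ANOVA decomposition of a simulation experiment
#'
#' Attributes variance in a per-run response (e.g. end-of-run invaded area)
#' to categorical design factors via `stats::aov`, with interactions up to
#' `max_order`. Designs built by the scenario tools are balanced, so the
#' sequential sums of squares are order-independent.
#'
#' @param response numeric response, one value per run.
#' @param factors data frame of categorical factors, one row per run.
#' @param max_order highest interaction order to include.
#' @return Data frame with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value` (residual row included).
#' @export
anova_decomposition <- function(response, factors, max_order = 2L) {
  df <- as.data.frame(lapply(factors, factor))
  df$.response <- response
  rhs <- paste0("(", paste(names(factors), collapse = " + "), ")^", max_order)
  fit <- stats::aov(stats::as.formula(paste(".response ~", rhs)), data = df)
  if (stats::df.residual(fit) < 1)
    stop("no residual degrees of freedom: need >= 2 replicates per design cell",
         call. = FALSE)
  tab <- summary(fit)[[1]]
  out <- data.frame(term = trimws(rownames(tab)),
                    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                    statistic = tab$`F value`, p.value = tab$`Pr(>F)`,
                    row.names = NULL)
  out$term[out$term == "Residuals"] <- "residual"
  out
}

# R^2 of an additive linear model on a subset of categorical predictors
subset_r2 <- function(response, predictors, subset) {
  if (!length(subset)) return(0)
  d <- as.data.frame(lapply(predictors[subset], factor))
  d$.response <- response
  # noise-free designs fit perfectly; the summary warning is immaterial here
  suppressWarnings(summary(stats::lm(.response ~ ., data = d))$r.squared)
}

#' Hierarchical partitioning of explained variance
#'
#' Attributes the full model's goodness of fit (R-squared of a linear model
#' on categorical encodings) to individual predictors. The independent
#' contribution of predictor *i* is the average, over all orderings of the
#' predictors, of the R-squared increment from adding *i*; computed by
#' subset enumeration with the standard factorial weights, so the
#' independent contributions sum exactly to the full-model R-squared. The
#' joint contribution is `R2({i})` minus the independent contribution.
#'
#' @param response numeric response, one value per run.
#' @param predictors data frame of categorical predictors (at most 8; the
#'   enumeration is over all `2^k` subsets).
#' @return A `bg_partition`: list with `independent`, `joint`, `r2_full`,
#'   and `share_pct` (independent contributions as percentages summing to
#'   100).
#' @export
hierarchical_partition <- function(response, predictors) {
  k <- ncol(predictors)
  if (k < 1 || k > 8)
    stop("hierarchical partitioning supports 1 to 8 predictors", call. = FALSE)
  nms <- names(predictors)
  n_sub <- 2^k
  r2 <- numeric(n_sub) # subset indexed by bitmask + 1
  for (mask in 0:(n_sub - 1))
    r2[mask + 1] <- subset_r2(response, predictors, which(bitwAnd(mask, 2^(0:(k - 1))) > 0))
  indep <- stats::setNames(numeric(k), nms)
  for (i in seq_len(k)) {
    bit <- 2^(i - 1)
    for (mask in 0:(n_sub - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(0:(k - 1))) > 0)
      w <- factorial(s) * factorial(k - s - 1) / factorial(k)
      indep[i] <- indep[i] + w * (r2[mask + bit + 1] - r2[mask + 1])
    }
  }
  single <- vapply(seq_len(k), function(i) r2[2^(i - 1) + 1], numeric(1))
  structure(
    list(independent = indep,
         joint = stats::setNames(single - indep, nms),
         r2_full = r2[n_sub],
         share_pct = 100 * indep / sum(indep)),
    class = "bg_partition")
}

#' @export
print.bg_partition <- function(x, ...) {
  cat(sprintf("<bg_partition> full-model R^2 = %.4f\n", x$r2_full))
  print(data.frame(independent = round(x$independent, 4),
                   joint = round(x$joint, 4),
                   share_pct = round(x$share_pct, 1)))
  invisible(x)
}
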