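# Shared fixtures and independent oracles, built in code.

# small landscape with every desert cell susceptible (no calibration noise)
test_landscape <- function(nr = 5, nc = 5, state = NULL,
                           ecotone_rows = 0, forest_rows = 0) {
  strata <- base_strata(nr, ecotone_rows, forest_rows, nc)
  surf <- matrix(0.5, nrow(strata$stratum), ncol(strata$stratum))
  strata <- threshold_susceptibility(surf, 0, strata)
  ls <- new_landscape(strata, suitability = surf)
  if (!is.null(state)) {
    storage.mode(state) <- "integer"
    ls$state[seq_len(nr), seq_len(nc)] <- state
  }
  ls
}

# independent flood-fill oracle: 8-connected component of flammable cells
# containing the ignition (breadth-first on an explicit queue)
flood_fill_component <- function(flammable, start_r, start_c) {
  nr <- nrow(flammable); nc <- ncol(flammable)
  if (!flammable[start_r, start_c]) return(integer(0))
  seen <- matrix(FALSE, nr, nc)
  queue <- list(c(start_r, start_c))
  seen[start_r, start_c] <- TRUE
  while (length(queue)) {
    cell <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      r <- cell[1] + di; c <- cell[2] + dj
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          flammable[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  which(seen)
}

# all permutations of 1:k (used by the hierarchical-partitioning oracle)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

# brute-force hierarchical partitioning: average R^2 increments over every
# explicit ordering of the predictors
hp_orderings_oracle <- function(response, predictors) {
  k <- ncol(predictors)
  r2 <- function(subset) {
    if (!length(subset)) return(0)
    d <- as.data.frame(lapply(predictors[subset], factor))
    d$.y <- response
    summary(stats::lm(.y ~ ., data = d))$r.squared
  }
  indep <- numeric(k)
  perms <- all_perms(k)
  for (p in perms) {
    for (pos in seq_len(k)) {
      before <- p[seq_len(pos - 1)]
      indep[p[pos]] <- indep[p[pos]] + r2(c(before, p[pos])) - r2(before)
    }
  }
  stats::setNames(indep / length(perms), names(predictors))
}

total_sim_area <- function(ls) sum(ls$stratum != STRATA[["excluded"]]) * ls$cell_area
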