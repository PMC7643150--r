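test_that("ignition is uniform over simulated cells and deterministic by seed", {
  one <- test_landscape(1, 1)
  expect_equal(unname(ignite(one, seed = 1)), c(1, 1))
  ls <- test_landscape(3, 3)
  expect_identical(ignite(ls, seed = 5), ignite(ls, seed = 5))
  # chi-square goodness of fit against the uniform over 9 cells
  hits <- table(factor(vapply(1:2700, function(i) {
    ig <- ignite(ls, seed = 10000 + i)
    (ig[["col"]] - 1) * 3 + ig[["row"]]
  }, numeric(1)), levels = 1:9))
  expect_gt(stats::chisq.test(hits)$p.value, 1e-4)
  # excluded forest cells are never ignition points
  lsf <- test_landscape(3, 3, forest_rows = 2)
  rows <- vapply(1:200, function(i) ignite(lsf, seed = i)[["row"]], numeric(1))
  expect_true(all(rows <= 3))
})

test_that("fires need flammable fuel and single isolated cells burn alone", {
  ls <- test_landscape(5, 5) # all uninvaded
  ev <- spread_fire(ls, c(3, 3), seed = 1)
  expect_equal(ev$area_ha, 0)
  expect_length(ev$burned, 0)
  st <- matrix(STATE_CLASSES[["uninvaded"]], 5, 5)
  st[3, 3] <- STATE_CLASSES[["converted"]]
  ls2 <- test_landscape(5, 5, st)
  ev2 <- spread_fire(ls2, c(3, 3), spread_prob = 1, seed = 1)
  expect_equal(ev2$area_ha, 0.25)
  expect_equal(ev2$burned, which(st == STATE_CLASSES[["converted"]]))
})

test_that("certain spread equals the flood-fill component of the ignition", {
  set.seed(77)
  for (case in 1:6) {
    st <- matrix(STATE_CLASSES[["uninvaded"]], 12, 12)
    blob <- matrix(stats::runif(144) < 0.4, 12, 12)
    st[blob] <- STATE_CLASSES[["cover_gt50"]] # spread weight 1
    ls <- test_landscape(12, 12, st)
    start <- which(blob, arr.ind = TRUE)[1, ]
    ev <- spread_fire(ls, start, spread_prob = 1, max_steps = 10000, seed = case)
    oracle <- flood_fill_component(blob, start[1], start[2])
    expect_setequal(ev$burned, oracle)
  }
})

test_that("burned sets stay flammable, 8-connected, and contain the ignition", {
  set.seed(31)
  flam_codes <- c(STATE_CLASSES[["cover_10_50"]], STATE_CLASSES[["cover_gt50"]],
                  STATE_CLASSES[["converted"]])
  for (case in 1:10) {
    st <- matrix(sample(unname(STATE_CLASSES), 100, replace = TRUE), 10, 10)
    ls <- test_landscape(10, 10, st)
    ign <- c(sample(1:10, 1), sample(1:10, 1))
    ev <- spread_fire(ls, ign, spread_prob = 0.7, seed = 500 + case)
    if (length(ev$burned)) {
      expect_true(all(ls$state[ev$burned] %in% flam_codes))
      ign_idx <- (ign[2] - 1) * 10 + ign[1]
      expect_true(ign_idx %in% ev$burned)
      # connectedness: the burned set is contained in, and reachable within,
      # the flammable component of the ignition
      flam <- matrix(ls$state %in% flam_codes, 10, 10)
      expect_true(all(ev$burned %in% flood_fill_component(flam, ign[1], ign[2])))
    }
    expect_equal(ev$area_ha, 0.25 * length(ev$burned))
  }
})

test_that("fire effects convert burned >50% cover and leave the rest configurable", {
  st <- matrix(STATE_CLASSES[["uninvaded"]], 4, 4)
  st[1, 1] <- STATE_CLASSES[["cover_gt50"]]
  st[2, 2] <- STATE_CLASSES[["converted"]]
  st[3, 3] <- STATE_CLASSES[["cover_10_50"]]
  ls <- test_landscape(4, 4, st)
  ls$age[3, 3] <- 5L
  burned <- c((1 - 1) * 4 + 1, (2 - 1) * 4 + 2, (3 - 1) * 4 + 3)
  ev <- structure(list(year = 1L, ignition = c(row = 1L, col = 1L),
                       burned = burned, area_ha = 0.75,
                       reached_forest_edge = FALSE),
                  class = "bg_fire_event")
  out <- apply_fire_effects(ls, ev)
  expect_identical(out$state[1, 1], STATE_CLASSES[["converted"]])
  expect_identical(out$state[2, 2], STATE_CLASSES[["converted"]])
  expect_identical(out$state[3, 3], STATE_CLASSES[["cover_10_50"]])
  expect_identical(out$age[3, 3], 5L) # default: class and age retained
  reset <- apply_fire_effects(ls, ev, "reset_age")
  expect_identical(reset$age[3, 3], 0L)
  promoted <- apply_fire_effects(ls, ev, "promote")
  expect_identical(promoted$state[3, 3], STATE_CLASSES[["cover_gt50"]])
  # empty burned set: no-op
  ev0 <- ev; ev0$burned <- integer(0)
  expect_identical(apply_fire_effects(ls, ev0)$state, ls$state)
})

test_that("burn metrics separate cumulative from landscape burned area", {
  mk <- function(year, cells, edge = FALSE)
    structure(list(year = year, ignition = c(row = 1L, col = 1L),
                   burned = cells, area_ha = 0.25 * length(cells),
                   reached_forest_edge = edge), class = "bg_fire_event")
  patch <- 1:10
  m <- fire_metrics(list(mk(1, patch), mk(2, integer(0)), mk(3, patch)))
  expect_equal(m$years_with_fire, 2)
  expect_equal(m$cumulative_burned_ha, 5.0) # 10 cells burned in 2 years
  expect_equal(m$landscape_burned_ha, 2.5) # union is the same 10 cells
  expect_equal(m$fires_to_forest_edge, 0)
  m2 <- fire_metrics(list(mk(1, 1:4, edge = TRUE), mk(2, 3:8)))
  expect_equal(m2$fires_to_forest_edge, 1)
  expect_equal(m2$landscape_burned_ha, 0.25 * 8)
  expect_lte(m2$landscape_burned_ha, m2$cumulative_burned_ha)
  empty <- fire_metrics(list(mk(1, integer(0))))
  expect_equal(unlist(empty), c(years_with_fire = 0, cumulative_burned_ha = 0,
                                landscape_burned_ha = 0,
                                fires_to_forest_edge = 0))
})

test_that("landscape burned equals cumulative exactly when nothing re-burns", {
  mk <- function(cells) structure(
    list(year = 1L, ignition = c(row = 1L, col = 1L), burned = cells,
         area_ha = 0.25 * length(cells), reached_forest_edge = FALSE),
    class = "bg_fire_event")
  disjoint <- fire_metrics(list(mk(1:5), mk(6:9)))
  expect_equal(disjoint$landscape_burned_ha, disjoint$cumulative_burned_ha)
  overlap <- fire_metrics(list(mk(1:5), mk(5:9)))
  expect_lt(overlap$landscape_burned_ha, overlap$cumulative_burned_ha)
})

test_that("fuel table rejects flammable low-cover classes", {
  expect_error(fuel_table(c(cover_lt1 = 0.5)), "cannot carry fire")
  w <- fuel_table()
  expect_equal(unname(w[c("uninvaded", "seedbank", "cover_lt1", "cover_1_10")]),
               rep(0, 4))
})
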