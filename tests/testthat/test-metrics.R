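make_ts <- function(hours, live, dead, prolif) {
  d <- data.frame(hour = hours, live = live, dead = dead,
                  proliferative = prolif, quiescent = live - prolif,
                  births = cumsum(c(0, pmax(0, diff(live + dead)))),
                  deaths = dead, aborts = 0)
  class(d) <- c("ca_timeseries", class(d))
  d
}

test_that("fold, viability and proliferating fraction follow their definitions", {
  ts <- make_ts(0:4, live = c(100, 120, 150, 150, 140),
                dead = c(0, 0, 0, 5, 15), prolif = c(100, 110, 120, 90, 70))
  expect_equal(fold_proliferation(ts, 0), 1)
  expect_equal(fold_proliferation(ts, 2), 1.5)
  expect_equal(viable_fraction(ts, 0), 1)
  expect_equal(viable_fraction(ts, 4), 140 / 155)
  expect_equal(proliferating_fraction(ts, 4), 0.5)
  expect_error(fold_proliferation(make_ts(0, 0, 0, 0), 0), "live")
  expect_error(fold_proliferation(ts, 7), "not in the time series")
})

test_that("a static population keeps fold at 1 and fractions in range", {
  sc <- tiny_scaffold(12, 12, 4)
  p <- tiny_params(c_initial = 30, doubling = doubling_dist(1e5, 0),
                   p_death = 0, horizon = 48)
  ts <- run_simulation(p, sc, snapshot_days = numeric(0))$timeseries
  expect_true(all(fold_proliferation(ts, ts$hour) == 1))
  expect_true(all(viable_fraction(ts, ts$hour) == 1))
})

test_that("viability only rises through births, never through dead revival", {
  # live/(live+dead) can increase in an hour only if that hour had births
  # (dead is non-decreasing and no dead cell revives); whenever divisions
  # pause, viability is non-increasing
  sc <- mid_scaffold()
  for (seed in 1:20) {
    p <- sim_params(c_initial = 150, capacity = 300, p_abort = 1,
                    reentry = FALSE, cd_min = 10, cd_max = 30, p_death = 0.2,
                    horizon = 240, seed = seed)
    ts <- run_simulation(p, sc, snapshot_days = numeric(0))$timeseries
    v <- viable_fraction(ts, ts$hour)
    up <- diff(v) > 1e-12
    expect_true(all(diff(ts$births)[up] > 0))
    expect_true(all(diff(ts$dead) >= 0))
  }
})

test_that("saturated capacity with p_abort = 1 and terminal quiescence empties the cycling pool", {
  sc <- tiny_scaffold(12, 12, 4)
  p <- sim_params(c_initial = 100, capacity = 100, p_abort = 1,
                  doubling = doubling_dist(96, 0), p_death = 0,
                  reentry = FALSE, m_c = 1000, horizon = 120, seed = 2)
  ts <- run_simulation(p, sc, snapshot_days = numeric(0))$timeseries
  expect_equal(proliferating_fraction(ts, 120), 0)
  expect_equal(viable_fraction(ts, 120), 1)
})

test_that("cluster labelling matches a brute-force flood fill", {
  expect_equal(cluster_stats(data.frame(x = 3L, y = 3L, z = 1L,
                                        phase = "PROLIFERATIVE"),
                             tiny_scaffold(10, 10, 3))$sizes, 1L)
  two <- data.frame(x = c(2L, 3L), y = c(2L, 3L), z = c(1L, 2L),
                    phase = "PROLIFERATIVE")
  cs2 <- cluster_stats(two, tiny_scaffold(10, 10, 3))
  expect_equal(cs2$n_clusters, 1L)
  expect_equal(cs2$sizes, 2L)

  sc <- build_scaffold(grid_dims(20, 20, 20),
                       pore_spec(c(8, 8, 0, 4, 4, 20)))
  withr::local_seed(5)
  for (rep in 1:5) {
    hyd <- which(!sc$pore_mask, arr.ind = TRUE) - 1L
    occ <- hyd[sample(nrow(hyd), 500), ]
    snap <- data.frame(x = occ[, 1], y = occ[, 2], z = occ[, 3],
                       phase = sample(c("PROLIFERATIVE", "QUIESCENT", "DEAD"),
                                      500, TRUE))
    cs <- cluster_stats(snap, sc)
    oracle <- flood_fill_labels(snap)
    # same partition up to label names
    expect_equal(cs$n_clusters, max(oracle))
    expect_true(all(table(cs$labels, oracle) %in%
                      c(0, tabulate(oracle))))
    expect_equal(sum(cs$sizes), nrow(snap))
    expect_equal(sort(cs$sizes), sort(unname(tabulate(oracle))))
  }
  expect_error(cluster_stats(data.frame(x = 50L, y = 0L, z = 0L,
                                        phase = "DEAD"), sc), "exceed")
})

test_that("interior cells of a solid block are detected", {
  # 3x3x3 solid cube: exactly the centre cell is interior
  g <- expand.grid(x = 1:3, y = 1:3, z = 1:3)
  snap <- data.frame(x = g$x, y = g$y, z = g$z, phase = "PROLIFERATIVE")
  snap$phase[snap$x == 2 & snap$y == 2 & snap$z == 2] <- "QUIESCENT"
  cs <- cluster_stats(snap, tiny_scaffold(10, 10, 10))
  expect_equal(cs$n_clusters, 1L)
  expect_equal(cs$interior_quiescent_fraction, 1)
})

test_that("biased movement pulls the population toward the pores", {
  sc <- mid_scaffold()
  delta <- function(mode, seed) {
    p <- sim_params(c_initial = 150, capacity = 600, movement_mode = mode,
                    L_p = 15, alpha = 0.1, beta = 1.5, horizon = 264,
                    seed = seed)
    sim <- run_simulation(p, sc, snapshot_days = c(0, 11))
    mean_pore_distance(sim$snapshots$h264, sc) -
      mean_pore_distance(sim$snapshots$h0, sc)
  }
  db <- vapply(1:20, function(s) delta("biased", s), numeric(1))
  dr <- vapply(1:20, function(s) delta("random", 100 + s), numeric(1))
  expect_lt(mean(db), 0)
  expect_lt(stats::t.test(db)$p.value, 0.01)    # clear drift toward pores
  expect_gt(stats::t.test(dr)$p.value, 0.01)    # no detectable drift
  expect_lt(mean(db), mean(dr))
})

test_that("consistency analysis reports shrinking ensemble noise", {
  sc <- tiny_scaffold(15, 15, 6)
  p <- tiny_params(c_initial = 40, capacity = 160, horizon = 96, seed = 5)
  one <- consistency_analysis(p, 1, sc)
  expect_equal(unlist(one[1, -1]), c(sd_fold = 0, sd_viability = 0,
                                     sd_ki67 = 0))
  expect_true(is.na(attr(one, "recommended_n")))
  expect_error(consistency_analysis(p, c(5, 2), sc), "increasing")

  # CLT: the SE of the ensemble mean scales ~ n^(-1/2)
  tab <- consistency_analysis(p, c(10, 20, 40, 80, 160), sc)
  se <- tab$sd_fold / sqrt(tab$n)
  fit <- stats::lm(log(se) ~ log(tab$n))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 0.5), 0.15)
})
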