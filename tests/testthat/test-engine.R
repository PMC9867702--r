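test_that("compiled engine matches the naive reference state-for-state", {
  # pore-free 6x6x3 lattice, 200 steps, both movement modes, several seeds
  cases <- expand.grid(seed = c(1, 7, 42), mode = c("random", "biased"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    sc <- tiny_scaffold()
    p <- tiny_params(seed = cases$seed[k], movement_mode = cases$mode[k])
    eng <- run_simulation(p, sc, snapshot_days = numeric(0),
                          record_states = TRUE)
    ref <- naive_run_simulation(p, sc)
    expect_equal(eng$timeseries, ref$timeseries, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_states_equal(eng$states, ref$states)
  }
})

test_that("engine/reference equivalence holds with pores and pore bias", {
  sc <- pored_scaffold()
  p <- tiny_params(seed = 5, movement_mode = "biased", L_p = 6, beta = 2)
  eng <- run_simulation(p, sc, snapshot_days = numeric(0),
                        record_states = TRUE)
  ref <- naive_run_simulation(p, sc)
  expect_states_equal(eng$states, ref$states)
})

test_that("runs are deterministic given the seed", {
  sc <- mid_scaffold()
  p <- sim_params(c_initial = 200, capacity = 600, horizon = 72, seed = 9)
  a <- run_simulation(p, sc)
  b <- run_simulation(p, sc)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$cells, b$cells)
})

test_that("counts are conserved and dead cells retain their sites", {
  sc <- mid_scaffold()
  for (seed in c(2, 13, 77)) {
    p <- sim_params(c_initial = 150, capacity = 400, p_abort = 0.9,
                    cd_min = 12, cd_max = 30, p_death = 0.1,
                    horizon = 240, seed = seed)
    sim <- run_simulation(p, sc, snapshot_days = c(0, 10))
    ts <- sim$timeseries
    expect_equal(ts$live + ts$dead, p$c_initial + ts$births)
    expect_true(all(diff(ts$dead) >= 0))
    expect_equal(ts$proliferative + ts$quiescent, ts$live)
    expect_equal(ts$live[1], p$c_initial)
    expect_equal(ts$dead[1], 0)
    # every cell (incl. dead) occupies a distinct site
    cells <- sim$cells
    expect_equal(nrow(unique(cells[, c("x", "y", "z")])), nrow(cells))
  }
})

test_that("no cell ever occupies a pore site", {
  sc <- mid_scaffold()
  for (seed in 1:20) {
    p <- sim_params(c_initial = 120, capacity = 500, m_c = 4,
                    movement_mode = if (seed %% 2) "biased" else "random",
                    horizon = 48, seed = seed)
    sim <- run_simulation(p, sc, snapshot_days = c(0, 1, 2))
    for (snap in c(sim$snapshots, list(sim$cells))) {
      cls <- vapply(seq_len(nrow(snap)), function(i)
        site_class(sc, c(snap$x[i], snap$y[i], snap$z[i])), character(1))
      expect_true(all(cls == "HYDROGEL"))
    }
  }
})

test_that("capacity bounds the live population when p_abort = 1", {
  sc <- mid_scaffold()
  for (seed in 1:20) {
    p <- sim_params(c_initial = 150, capacity = 220, p_abort = 1,
                    p_death = 0, horizon = 240, seed = seed)
    ts <- run_simulation(p, sc, snapshot_days = numeric(0))$timeseries
    expect_lte(max(ts$live), 220)
  }
})

test_that("a lone cell divides at the first tick its clock reaches the doubling time", {
  # hand-simulated oracle: desync off, movement off, ample space;
  # clock hits DT at tick ceiling(DT), live goes 1 -> 2 there
  sc <- tiny_scaffold(10, 10, 4)
  p <- tiny_params(c_initial = 1, capacity = 100, p_abort = 0,
                   desync = FALSE, m_c = 1000, p_death = 0, horizon = 40)
  sim <- run_simulation(p, sc, snapshot_days = numeric(0),
                        record_states = TRUE)
  dt <- sim$states[[1]]$doubling_time[1]
  ts <- sim$timeseries
  expect_equal(min(ts$hour[ts$live == 2]), ceiling(dt))
  # daughter lands at Chebyshev distance 1 of the parent
  st <- sim$states[[ceiling(dt) + 1]]
  cheb <- max(abs(st[2, c("x", "y", "z")] - st[1, c("x", "y", "z")]))
  expect_equal(cheb, 1)
})

test_that("an empty population stays empty but time advances", {
  p <- tiny_params(c_initial = 0, horizon = 24)
  sim <- run_simulation(p, tiny_scaffold(), snapshot_days = numeric(0))
  expect_equal(nrow(sim$timeseries), 25)
  expect_true(all(sim$timeseries$live == 0))
  expect_true(all(sim$timeseries$births == 0))
})

test_that("division falls back through Moore orders and quiesces when walled in", {
  # 3x3x1 lattice completely full: no vacancy anywhere -> parent quiesces
  sc <- tiny_scaffold(3, 3, 1)
  p <- tiny_params(c_initial = 9, capacity = 100, p_abort = 0,
                   desync = FALSE, doubling = doubling_dist(5, 0),
                   m_c = 1000, p_death = 0, reentry = FALSE, horizon = 8)
  sim <- run_simulation(p, sc, snapshot_days = numeric(0))
  ts <- sim$timeseries
  expect_equal(ts$births[nrow(ts)], 0)
  expect_equal(ts$quiescent[nrow(ts)], 9)
})

test_that("unbiased interior probabilities are exactly 1/6 and feasibility masks work", {
  sc <- mid_scaffold()
  p <- sim_params(movement_mode = "random")
  cells <- data.frame(x = 5L, y = 5L, z = 5L, phase = "PROLIFERATIVE")
  pr <- move_probabilities(sc, cells, c(5, 5, 5), p)
  expect_identical(unname(pr), rep(1 / 6, 6))
  # corner cell: 3 feasible directions
  cells2 <- data.frame(x = 0L, y = 0L, z = 0L, phase = "PROLIFERATIVE")
  pr2 <- move_probabilities(sc, cells2, c(0, 0, 0), p)
  expect_equal(sum(pr2 > 0), 3)
  expect_equal(sum(pr2), 1)
  expect_identical(unname(pr2[c("left", "down", "backward")]), c(0, 0, 0))
})

test_that("movement probabilities normalise on random occupancy configurations", {
  sc <- tiny_scaffold(15, 15, 8)
  withr::local_seed(99)
  p_rand <- sim_params(movement_mode = "random")
  p_bias <- sim_params(movement_mode = "biased", alpha = 0.3, beta = 1.1,
                       L_c = 2, L_p = 6)
  for (k in 1:500) {
    n <- sample(1:40, 1)
    idx <- sample(15 * 15 * 8, n) - 1L
    cells <- data.frame(x = idx %% 15L, y = (idx %/% 15L) %% 15L,
                        z = idx %/% (15L * 15L),
                        phase = sample(c("PROLIFERATIVE", "QUIESCENT", "DEAD"),
                                       n, replace = TRUE))
    i <- sample(n, 1)
    pos <- c(cells$x[i], cells$y[i], cells$z[i])
    for (p in list(p_rand, p_bias)) {
      pr <- move_probabilities(sc, cells, pos, p)
      expect_true(all(pr >= 0))
      s <- sum(pr)
      expect_true(abs(s - 1) < 1e-12 || s == 0)
    }
  }
})

test_that("cell attraction tilts probabilities toward occupied directions", {
  sc <- tiny_scaffold(20, 20, 8)
  p <- sim_params(movement_mode = "biased", alpha = 0.5, beta = 0,
                  L_c = 3)
  cells <- data.frame(
    x = c(10L, 12L, 13L, 12L), y = c(10L, 10L, 10L, 11L), z = rep(4L, 4),
    phase = "PROLIFERATIVE")
  pr <- move_probabilities(sc, cells, c(10, 10, 4), p)
  expect_gt(pr[["right"]], 1 / 6)
  expect_gt(1 / 6, pr[["left"]])
  # direct formula: N_right = 3, others 0 -> w = (2.5,1,1,1,1,1)
  expect_equal(unname(pr), c(2.5, 1, 1, 1, 1, 1) / 7.5)
})

test_that("biased mode with alpha = beta = 0 reduces to the random walk", {
  sc <- tiny_scaffold(30, 30, 10)
  p0 <- sim_params(movement_mode = "biased", alpha = 0, beta = 0)
  cells <- data.frame(x = 15L, y = 15L, z = 5L, phase = "PROLIFERATIVE")
  pr <- move_probabilities(sc, cells, c(15, 15, 5), p0)
  expect_identical(unname(pr), rep(1 / 6, 6))
  # chi-square on 10,000 sampled moves of an unobstructed interior cell
  withr::local_seed(4)
  draws <- sample.int(6, 10000, replace = TRUE, prob = pr)
  expect_gt(stats::chisq.test(tabulate(draws, 6))$p.value, 0.01)
})

test_that("case-2 style slowdown reduces per-cell displacement", {
  sc <- mid_scaffold()
  disp <- function(m_c, seed) {
    p <- sim_params(c_initial = 120, capacity = 600, m_c = m_c,
                    horizon = 264, seed = seed)
    sim <- run_simulation(p, sc, snapshot_days = c(0, 11))
    a <- sim$snapshots$h0
    b <- sim$snapshots$h264[seq_len(nrow(a)), ] # initial cells keep ids
    mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
  }
  d15 <- mean(vapply(1:3, function(s) disp(15, s), numeric(1)))
  d20 <- mean(vapply(1:3, function(s) disp(20, s), numeric(1)))
  expect_lt(d20, d15)
})

test_that("calibrated-scale growth is sigmoidal with a day-7-to-11 plateau", {
  # quarter lattice with c_initial and capacity scaled by hydrogel ratio
  for (seed in c(8, 21)) {
    p <- quarter_params(seed = seed)
    ts <- run_simulation(p, quarter_scaffold(),
                         snapshot_days = numeric(0))$timeseries
    expect_gt(ts$live[ts$hour == 96], ts$live[1])
    expect_gt(ts$live[ts$hour == 168], ts$live[ts$hour == 96])
    expect_lt(abs(ts$live[ts$hour == 264] - ts$live[ts$hour == 240]) /
                ts$live[ts$hour == 240], 0.05)
  }
})

test_that("ensembles aggregate runs and are seed-stable", {
  sc <- tiny_scaffold(12, 12, 4)
  p <- tiny_params(c_initial = 20, capacity = 80, horizon = 48, seed = 3)
  e1 <- run_ensemble(p, 4, sc)
  expect_equal(e1$n_runs, 4)
  # n = 1 gives identically zero SDs
  e0 <- run_ensemble(p, 1, sc)
  expect_true(all(e0$sd$live == 0))
  # member i equals a lone run at seed + i - 1
  solo <- run_simulation(update_params(p, seed = 5), sc,
                         snapshot_days = numeric(0))
  expect_identical(e1$runs[[3]]$timeseries, solo$timeseries)
  expect_error(run_ensemble(p, 0, sc), "n_runs")
  # two independent small ensembles agree within sampling error
  e2 <- run_ensemble(update_params(p, seed = 1000), 4, sc)
  n <- nrow(e1$mean)
  se <- sqrt(e1$sd$live[n]^2 / 4 + e2$sd$live[n]^2 / 4)
  expect_lt(abs(e1$mean$live[n] - e2$mean$live[n]), max(3 * se, 1e-9))
})
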