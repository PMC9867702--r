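#' Doubling-time distribution
#'
#' Per-cell doubling times are drawn from a Normal distribution; the
#' experimentally measured values for the encapsulated cells are
#' mu = 96 h, sigma = 6 h (roughly three times slower than 2D culture).
#'
#' @param mu mean doubling time in hours (> 0).
#' @param sigma standard deviation in hours (>= 0).
#' @return list of class `"doubling_dist"`.
#' @export
doubling_dist <- function(mu = 96, sigma = 6) {
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(mu = mu, sigma = sigma), class = "doubling_dist")
}

#' Sample per-cell doubling times
#'
#' Normal draws truncated at zero by rejection (resampling), so there is no
#' atom at zero and every returned value is strictly positive.
#'
#' @param n number of draws.
#' @param dist a [doubling_dist()].
#' @return numeric vector of `n` positive doubling times (hours).
#' @export
sample_doubling_time <- function(n, dist = doubling_dist()) {
  stopifnot(inherits(dist, "doubling_dist"))
  out <- dist$mu + dist$sigma * stats::rnorm(n)
  while (any(bad <- out <= 0))
    out[bad] <- dist$mu + dist$sigma * stats::rnorm(sum(bad))
  out
}

#' Sample per-cell quiescence-death thresholds
#'
#' The time a cell tolerates in quiescence before it becomes exposed to
#' death (the stochastic threshold C_d) is realised per cell as a uniform
#' draw on a calibrated range.
#'
#' @param n number of draws.
#' @param cd_min,cd_max range bounds in hours, `0 < cd_min <= cd_max`.
#' @return numeric vector of thresholds (hours).
#' @export
sample_death_threshold <- function(n, cd_min, cd_max) {
  if (!(cd_min > 0)) stop("cd_min must be > 0")
  if (cd_min > cd_max) stop("cd_min must be <= cd_max")
  cd_min + stats::runif(n) * (cd_max - cd_min)
}

#' Seed the initial cell population
#'
#' Places `c_initial` cells on distinct uniformly-sampled hydrogel sites
#' (rejection sampling over the ascending hydrogel-site list, matching the
#' engine's draw protocol). All cells start proliferative; cycle clocks are
#' desynchronised uniformly on `[0, doubling_time)` unless `desync = FALSE`.
#'
#' @param scaffold a [build_scaffold()] object.
#' @param c_initial number of cells, `0 <= c_initial <= n_hydrogel`.
#' @param params a [sim_params()] object (supplies the doubling distribution,
#'   death-threshold range and movement schedule).
#' @param desync desynchronise initial cycle clocks (default `TRUE`).
#' @return data frame with one row per cell: `id, x, y, z, phase,
#'   doubling_time, cycle_clock, quiescence_clock, death_threshold,
#'   next_move_at`. Coordinates are 0-based; `phase` is one of
#'   `"PROLIFERATIVE"`, `"QUIESCENT"`, `"DEAD"`.
#' @export
seed_cells <- function(scaffold, c_initial, params = sim_params(),
                       desync = params$desync) {
  stopifnot(inherits(scaffold, "ca_scaffold"))
  c_initial <- as.integer(c_initial)
  if (c_initial < 0) stop("c_initial must be >= 0")
  if (c_initial > scaffold$n_hydrogel)
    stop("c_initial exceeds the number of hydrogel sites")
  nx <- scaffold$dims[["nx"]]; ny <- scaffold$dims[["ny"]]
  hyd <- which(!scaffold$pore_mask) - 1L # ascending 0-based linear indices
  taken <- logical(length(hyd) + scaffold$n_pore)
  n <- c_initial
  x <- y <- z <- integer(n)
  dtv <- cyc <- thr <- nmv <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      s <- hyd[runif_int(length(hyd)) + 1L]
      if (!taken[s + 1L]) break
    }
    taken[s + 1L] <- TRUE
    x[i] <- s %% nx
    y[i] <- (s %/% nx) %% ny
    z[i] <- s %/% (nx * ny)
    dtv[i] <- sample_doubling_time(1, params$doubling)
    cyc[i] <- if (desync) stats::runif(1) * dtv[i] else 0
    thr[i] <- sample_death_threshold(1, params$cd_min, params$cd_max)
    nmv[i] <- params$m_c + runif_int(params$m_jitter_max + 1L)
  }
  data.frame(id = seq_len(n), x = x, y = y, z = z,
             phase = rep("PROLIFERATIVE", n), doubling_time = dtv,
             cycle_clock = cyc, quiescence_clock = numeric(n),
             death_threshold = thr, next_move_at = nmv,
             stringsAsFactors = FALSE)
}

# uniform integer on 0..n-1 consuming exactly one draw (engine protocol)
runif_int <- function(n) min(floor(stats::runif(1) * n), n - 1)

phase_labels <- c("PROLIFERATIVE", "QUIESCENT", "DEAD")
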