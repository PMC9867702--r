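# Deliberately naive pure-R reference implementation of the hourly update.
# It follows the engine's documented RNG-draw protocol (see src/engine.cpp)
# so trajectories are comparable draw-for-draw, but shares no simulation
# code with the compiled path: occupancy is a plain 3D array, neighbourhood
# shells come from moore_neighborhood(), movement weights and pore distances
# are recomputed from scratch in R. Intended for state-for-state oracle
# tests on tiny lattices only.

ref_fy_permute <- function(v) {
  n <- length(v)
  if (n > 1) {
    for (i in n:2) {
      j <- runif_int(i) + 1L
      tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
    }
  }
  v
}

ref_sample_dt <- function(mu, sigma) {
  repeat {
    v <- mu + sigma * stats::rnorm(1)
    if (v > 0) return(v)
  }
}

# 1-based direction index: 1 +x, 2 -x, 3 +y, 4 -y, 5 +z, 6 -z
ref_dominant <- function(dx, dy, dz) {
  ax <- abs(dx); ay <- abs(dy); az <- abs(dz)
  if (ax == 0 && ay == 0 && az == 0) return(0L)
  if (ax >= ay && ax >= az) return(if (dx > 0) 1L else 2L)
  if (ay >= az) return(if (dy > 0) 3L else 4L)
  if (dz > 0) 5L else 6L
}

# brute-force nearest pore site: scan every pore site, strict < keeps the
# first minimiser in ascending linear-index order
ref_pore_distance <- function(pore_sites, pos) {
  if (nrow(pore_sites) == 0) return(list(d = Inf, dir = 0L))
  best <- Inf; bp <- NULL
  for (i in seq_len(nrow(pore_sites))) {
    dd <- sum((pore_sites[i, ] - pos)^2)
    if (dd < best) { best <- dd; bp <- pore_sites[i, ] }
  }
  list(d = sqrt(best),
       dir = ref_dominant(bp[1] - pos[1], bp[2] - pos[2], bp[3] - pos[3]))
}

REF_OFF <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))

#' Naive reference simulation (oracle)
#'
#' A slow, straightforward re-implementation of [run_simulation()] in plain
#' R, used as the independent oracle in the package's equivalence tests.
#' With the same seed it reproduces the compiled engine's trajectory
#' state-for-state. Do not use on realistic lattice sizes.
#'
#' @inheritParams run_simulation
#' @return list with `timeseries`, `states` (per-hour cell tables) and
#'   `cells` (final table), shaped like the corresponding [run_simulation()]
#'   fields.
#' @keywords internal
naive_run_simulation <- function(params, scaffold) {
  stopifnot(inherits(params, "ca_params"), inherits(scaffold, "ca_scaffold"))
  dims <- scaffold$dims
  nx <- dims[["nx"]]; ny <- dims[["ny"]]; nz <- dims[["nz"]]
  set.seed(params$seed)

  occ <- array(0L, dim = c(nx, ny, nz))
  occ[scaffold$pore_mask] <- -1L
  pore_sites <- which(scaffold$pore_mask, arr.ind = TRUE) - 1L
  biased <- params$movement_mode == "biased"

  cells <- seed_cells(scaffold, params$c_initial, params, params$desync)
  ph <- match(cells$phase, phase_labels) - 1L
  x <- cells$x; y <- cells$y; z <- cells$z
  dtv <- cells$doubling_time; cyc <- cells$cycle_clock
  qcl <- cells$quiescence_clock; thr <- cells$death_threshold
  nmv <- cells$next_move_at
  for (i in seq_along(x)) occ[x[i] + 1, y[i] + 1, z[i] + 1] <- i
  live <- length(x); births <- 0L; deaths <- 0L; aborts <- 0L

  vacant_shell <- function(i, k) {
    nb <- moore_neighborhood(c(x[i], y[i], z[i]), k, dims)
    if (nrow(nb) == 0) return(nb)
    keep <- logical(nrow(nb))
    for (r in seq_len(nrow(nb)))
      keep[r] <- occ[nb[r, 1] + 1, nb[r, 2] + 1, nb[r, 3] + 1] == 0L
    nb[keep, , drop = FALSE]
  }

  weights <- function(i) {
    w <- numeric(6); feas <- logical(6)
    for (d in 1:6) {
      t1 <- c(x[i], y[i], z[i]) + REF_OFF[d, ]
      feas[d] <- all(t1 >= 0) && t1[1] < nx && t1[2] < ny && t1[3] < nz &&
        occ[t1[1] + 1, t1[2] + 1, t1[3] + 1] == 0L
    }
    if (!biased) return(ifelse(feas, 1, 0))
    N <- numeric(6)
    L <- params$L_c
    for (dz in -L:L) for (dy in -L:L) for (dx in -L:L) {
      if (dx == 0 && dy == 0 && dz == 0) next
      t1 <- c(x[i] + dx, y[i] + dy, z[i] + dz)
      if (any(t1 < 0) || t1[1] >= nx || t1[2] >= ny || t1[3] >= nz) next
      o <- occ[t1[1] + 1, t1[2] + 1, t1[3] + 1]
      if (o > 0 && ph[o] != 2L) {
        d <- ref_dominant(dx, dy, dz)
        if (d > 0) N[d] <- N[d] + 1
      }
    }
    pd <- ref_pore_distance(pore_sites, c(x[i], y[i], z[i]))
    phi <- numeric(6)
    if (pd$dir > 0 && pd$d <= params$L_p)
      phi[pd$dir] <- 1 - pd$d / params$L_p
    ifelse(feas, 1 + params$alpha * N + params$beta * phi, 0)
  }

  state_table <- function() {
    data.frame(id = seq_along(x), x = x, y = y, z = z,
               phase = phase_labels[ph + 1], doubling_time = dtv,
               cycle_clock = cyc, quiescence_clock = qcl,
               death_threshold = thr, next_move_at = nmv,
               stringsAsFactors = FALSE)
  }
  ts_row <- function(t) {
    c(hour = t, live = live, dead = deaths,
      proliferative = sum(ph == 0L), quiescent = sum(ph == 1L),
      births = births, deaths = deaths, aborts = aborts)
  }

  ts <- matrix(0, nrow = params$horizon + 1, ncol = 8)
  colnames(ts) <- c("hour", "live", "dead", "proliferative", "quiescent",
                    "births", "deaths", "aborts")
  ts[1, ] <- ts_row(0)
  states <- vector("list", params$horizon + 1)
  names(states) <- paste0("t", 0:params$horizon)
  states[[1]] <- state_table()

  for (t in seq_len(params$horizon)) {
    n0 <- length(x)
    # 1. clocks
    for (i in seq_len(n0)) {
      if (ph[i] == 0L) cyc[i] <- cyc[i] + 1
      else if (ph[i] == 1L) qcl[i] <- qcl[i] + 1
    }
    # 2. death
    for (i in ref_fy_permute(which(ph[seq_len(n0)] == 1L))) {
      if (qcl[i] > thr[i] && stats::runif(1) < params$p_death) {
        ph[i] <- 2L; live <- live - 1L; deaths <- deaths + 1L
      }
    }
    # 3. division
    elig <- which(ph[seq_len(n0)] == 0L & cyc[seq_len(n0)] >= dtv[seq_len(n0)])
    for (i in ref_fy_permute(elig)) {
      if (live >= params$capacity && stats::runif(1) < params$p_abort) {
        ph[i] <- 1L; qcl[i] <- 0; aborts <- aborts + 1L
        next
      }
      site <- NULL
      for (k in 1:3) {
        vac <- vacant_shell(i, k)
        if (nrow(vac) > 0) {
          site <- vac[runif_int(nrow(vac)) + 1L, ]
          break
        }
      }
      if (!is.null(site)) {
        x <- c(x, site[1]); y <- c(y, site[2]); z <- c(z, site[3])
        ph <- c(ph, 0L)
        dtv <- c(dtv, ref_sample_dt(params$doubling$mu, params$doubling$sigma))
        cyc <- c(cyc, 0); qcl <- c(qcl, 0)
        thr <- c(thr, params$cd_min +
                   stats::runif(1) * (params$cd_max - params$cd_min))
        nmv <- c(nmv, t + params$m_c + runif_int(params$m_jitter_max + 1L))
        occ[site[1] + 1, site[2] + 1, site[3] + 1] <- length(x)
        live <- live + 1L; births <- births + 1L
        cyc[i] <- 0
      } else {
        ph[i] <- 1L; qcl[i] <- 0
      }
    }
    # 4. movement
    due <- which(ph != 2L & t >= nmv)
    for (i in ref_fy_permute(due)) {
      w <- weights(i)
      tot <- sum(w)
      if (tot > 0) {
        u <- stats::runif(1) * tot
        cum <- 0; dir <- 6L
        for (d in 1:6) {
          cum <- cum + w[d]
          if (u < cum) { dir <- d; break }
        }
        t1 <- c(x[i], y[i], z[i]) + REF_OFF[dir, ]
        occ[x[i] + 1, y[i] + 1, z[i] + 1] <- 0L
        occ[t1[1] + 1, t1[2] + 1, t1[3] + 1] <- i
        x[i] <- t1[1]; y[i] <- t1[2]; z[i] <- t1[3]
      }
      nmv[i] <- t + params$m_c + runif_int(params$m_jitter_max + 1L)
    }
    # 5. re-entry
    if (params$reentry) {
      for (i in ref_fy_permute(which(ph == 1L & qcl <= thr))) {
        has_vac <- FALSE
        for (k in 1:3) if (nrow(vacant_shell(i, k)) > 0) { has_vac <- TRUE; break }
        if (!has_vac) next
        if (stats::runif(1) >= params$p_abort) {
          ph[i] <- 0L; cyc[i] <- 0; qcl[i] <- 0
        }
      }
    }
    ts[t + 1, ] <- ts_row(t)
    states[[t + 1]] <- state_table()
  }

  list(timeseries = as.data.frame(ts), states = states,
       cells = state_table())
}
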