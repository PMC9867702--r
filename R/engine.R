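#' Run a single simulation
#'
#' Seeds the population and advances the cellular automaton one hour at a
#' time for `params$horizon` hours. Each hour applies, in this order:
#' clock increments, quiescence death, division (capacity rule, daughter
#' placed on the nearest vacant Moore shell of orders 1-3), movement of due
#' cells (random or biased walk along the six axis directions), and
#' quiescence re-entry. Each sub-step visits cells in a fresh random
#' permutation. The run is fully determined by `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param scaffold a [build_scaffold()] object; default is the standard
#'   190 x 190 x 30 lattice with four 50 x 50 x 30 pores.
#' @param snapshot_days days at which to record voxel snapshots
#'   (default `c(0, 4, 7, 11)`, clipped to the horizon).
#' @param record_states record the full cell table after every hour
#'   (debugging / oracle comparisons; keep lattices tiny).
#' @return object of class `"ca_sim"`: list with
#'   \describe{
#'     \item{timeseries}{data frame `hour, live, dead, proliferative,
#'       quiescent, births, deaths, aborts` (counts; births/deaths/aborts
#'       cumulative), class `"ca_timeseries"`.}
#'     \item{snapshots}{named list (`"h<hour>"`) of cell tables
#'       `id, x, y, z, phase`.}
#'     \item{cells}{final full cell table.}
#'     \item{states}{per-hour cell tables when `record_states = TRUE`.}
#'     \item{params, scaffold}{the inputs, for provenance.}
#'   }
#' @export
#' @examples
#' sc <- build_scaffold(grid_dims(30, 30, 8), NULL)
#' p <- sim_params(c_initial = 50, capacity = 200, horizon = 48, seed = 7)
#' sim <- run_simulation(p, sc)
#' tail(sim$timeseries, 2)
run_simulation <- function(params, scaffold = NULL,
                           snapshot_days = c(0, 4, 7, 11),
                           record_states = FALSE) {
  stopifnot(inherits(params, "ca_params"))
  if (is.null(scaffold)) scaffold <- build_scaffold()
  stopifnot(inherits(scaffold, "ca_scaffold"))
  if (params$c_initial > scaffold$n_hydrogel)
    stop("c_initial exceeds the number of hydrogel sites")
  snap_hours <- unique(as.integer(round(snapshot_days * 24)))
  snap_hours <- snap_hours[snap_hours >= 0 & snap_hours <= params$horizon]
  set.seed(params$seed)
  res <- cpp_run(scaffold$dims[["nx"]], scaffold$dims[["ny"]],
                 scaffold$dims[["nz"]], scaffold$pores,
                 params$c_initial, params$capacity, params$p_abort,
                 params$doubling$mu, params$doubling$sigma,
                 params$cd_min, params$cd_max, params$p_death,
                 params$m_c, params$m_jitter_max, params$L_c, params$L_p,
                 params$alpha, params$beta,
                 params$movement_mode == "biased", params$desync,
                 params$reentry, params$horizon,
                 as.integer(snap_hours), record_states)
  ts <- as.data.frame(res$timeseries)
  class(ts) <- c("ca_timeseries", class(ts))
  snaps <- lapply(res$snapshots, function(m) {
    d <- as.data.frame(m)
    d$phase <- phase_labels[d$phase + 1]
    d
  })
  states <- NULL
  if (record_states) states <- lapply(res$states, decode_cells)
  structure(list(timeseries = ts, snapshots = snaps,
                 cells = decode_cells(res$cells), states = states,
                 params = params, scaffold = scaffold),
            class = "ca_sim")
}

decode_cells <- function(df) {
  df <- as.data.frame(df)
  df$phase <- phase_labels[df$phase + 1]
  df
}

#' @export
print.ca_sim <- function(x, ...) {
  n <- nrow(x$timeseries)
  last <- x$timeseries[n, ]
  cat(sprintf("<ca_sim> %d h | live %d (P %d / Q %d) | dead %d | seed %d\n",
              last$hour, last$live, last$proliferative, last$quiescent,
              last$dead, x$params$seed))
  invisible(x)
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` simulations with seeds `params$seed + 0 .. n_runs - 1` and
#' returns pointwise ensemble means and standard deviations of every count
#' column, plus the individual runs.
#'
#' @param params a [sim_params()] object (its `seed` is the ensemble base).
#' @param n_runs number of runs (the reference reproduction uses 100,
#'   motivated by consistency analysis; see [consistency_analysis()]).
#' @param scaffold optional [build_scaffold()] object.
#' @param snapshot_days days at which each run stores voxel snapshots;
#'   default none (keeps ensembles light).
#' @return object of class `"ca_ensemble"`: list with `mean` and `sd`
#'   data frames (per-hour), `runs` (list of `"ca_sim"`), `n_runs`,
#'   `params`.
#' @export
run_ensemble <- function(params, n_runs, scaffold = NULL,
                         snapshot_days = numeric(0)) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1) stop("n_runs must be >= 1")
  if (is.null(scaffold)) scaffold <- build_scaffold()
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    pi <- update_params(params, seed = params$seed + i - 1L)
    runs[[i]] <- run_simulation(pi, scaffold, snapshot_days = snapshot_days)
  }
  cols <- c("live", "dead", "proliferative", "quiescent", "births",
            "deaths", "aborts")
  arr <- vapply(runs, function(r) as.matrix(r$timeseries[, cols]),
                matrix(0, nrow(runs[[1]]$timeseries), length(cols)))
  mn <- apply(arr, c(1, 2), mean)
  sdv <- if (n_runs > 1) apply(arr, c(1, 2), stats::sd) else mn * 0
  colnames(mn) <- colnames(sdv) <- cols
  hour <- runs[[1]]$timeseries$hour
  structure(list(mean = data.frame(hour = hour, mn),
                 sd = data.frame(hour = hour, sdv),
                 runs = runs, n_runs = n_runs, params = params),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  n <- nrow(x$mean)
  cat(sprintf("<ca_ensemble> n = %d runs | final live %.1f +/- %.1f | dead %.1f\n",
              x$n_runs, x$mean$live[n], x$sd$live[n], x$mean$dead[n]))
  invisible(x)
}

#' Movement direction probabilities for one cell
#'
#' Evaluates the six-direction movement law at a given occupied position.
#' In random mode every feasible direction (in-bounds vacant hydrogel
#' target) has equal probability; with all six feasible each is exactly 1/6.
#' In biased mode the weight of a feasible direction i is
#' `1 + alpha * N_i + beta * Phi_i`, where `N_i` counts live cells within
#' Chebyshev radius `L_c` whose dominant displacement axis is direction i,
#' and `Phi_i = max(0, 1 - d/L_p)` for the direction of the nearest pore at
#' Euclidean distance `d <= L_p` (0 for the other directions). Probabilities
#' are the normalised weights; with no feasible direction all six are 0 and
#' the cell stays put.
#'
#' @param scaffold a [build_scaffold()] object.
#' @param cells a cell table (as from [seed_cells()] or a snapshot): columns
#'   `x, y, z, phase` at least; the queried position must hold a cell.
#' @param pos 0-based `(x, y, z)` of the cell to evaluate.
#' @param params a [sim_params()] object (mode, alpha, beta, L_c, L_p).
#' @return named numeric vector of six probabilities
#'   (right, left, up, down, forward, backward).
#' @export
move_probabilities <- function(scaffold, cells, pos, params) {
  stopifnot(inherits(scaffold, "ca_scaffold"), inherits(params, "ca_params"))
  pos <- check_pos(pos, scaffold$dims)
  occ <- occupancy_codes(scaffold, cells)
  ph <- match(cells$phase, phase_labels) - 1L
  if (anyNA(ph)) ph <- as.integer(cells$phase)
  cpp_move_probs(occ, scaffold$dims[["nx"]], scaffold$dims[["ny"]],
                 scaffold$dims[["nz"]], scaffold$pores, ph,
                 pos[1], pos[2], pos[3],
                 params$movement_mode == "biased",
                 params$alpha, params$beta, params$L_c, params$L_p)
}

# linear occupancy vector: -1 pore, 0 empty, row index of cell otherwise
occupancy_codes <- function(scaffold, cells) {
  nx <- scaffold$dims[["nx"]]; ny <- scaffold$dims[["ny"]]
  occ <- integer(scaffold$n_total)
  occ[which(scaffold$pore_mask)] <- -1L
  if (nrow(cells) > 0) {
    idx <- cells$x + nx * (cells$y + ny * cells$z) + 1L
    if (any(occ[idx] != 0)) stop("cells collide or sit on pore sites")
    occ[idx] <- seq_len(nrow(cells))
  }
  occ
}
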