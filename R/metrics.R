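ts_at <- function(series, t) {
  i <- match(round(t), series$hour)
  if (anyNA(i)) stop("hour ", t[which(is.na(i))[1]], " not in the time series")
  i
}

#' Fold proliferation (MTT analogue)
#'
#' Live-cell count at hour `t` relative to hour 0. The MTT assay reports
#' metabolically active cells, mapped here to the live (proliferative plus
#' quiescent) population.
#'
#' @param series a `ca_timeseries` data frame (from [run_simulation()]).
#' @param t hour(s) at which to evaluate.
#' @return numeric fold value(s); exactly 1 at `t = 0`.
#' @export
fold_proliferation <- function(series, t) {
  if (series$live[1] <= 0) stop("live(0) must be > 0")
  series$live[ts_at(series, t)] / series$live[1]
}

#' Viable fraction (live/dead analogue)
#'
#' `live / (live + dead)` at hour `t`; dead cells accumulate (they are
#' stained in place in vitro and permanently occupy their site in silico).
#'
#' @inheritParams fold_proliferation
#' @return fraction(s) in `[0, 1]`.
#' @export
viable_fraction <- function(series, t) {
  i <- ts_at(series, t)
  tot <- series$live[i] + series$dead[i]
  if (any(tot <= 0)) stop("empty population: live + dead = 0")
  series$live[i] / tot
}

#' Proliferating fraction (Ki-67 analogue)
#'
#' Fraction of live cells in the proliferative phase. Ki-67 marks all
#' active cell-cycle phases and is absent in G0, so quiescent cells do not
#' count.
#'
#' @inheritParams fold_proliferation
#' @return fraction(s) in `[0, 1]`.
#' @export
proliferating_fraction <- function(series, t) {
  i <- ts_at(series, t)
  if (any(series$live[i] <= 0)) stop("no live cells at the requested hour")
  series$proliferative[i] / series$live[i]
}

#' Voxel cluster statistics
#'
#' Labels connected components of occupied sites (live and dead cells;
#' dead cells remain part of aggregates) under 26-connectivity, i.e. sites
#' touching even at corners belong to the same cluster.
#'
#' @param snapshot cell table with columns `x, y, z` (0-based) and `phase`;
#'   typically an entry of `run_simulation()$snapshots`.
#' @param scaffold the [build_scaffold()] object the snapshot came from.
#' @return list of class `"cluster_stats"`:
#'   `n_clusters`, `sizes` (per-cluster site counts), `labels` (per-row
#'   cluster id), `mean_pore_distance` (per-cluster mean Euclidean distance
#'   to the nearest pore), `interior_quiescent_fraction` (fraction of
#'   quiescent cells among cells whose 26 in-bounds neighbours are all
#'   occupied; `NaN` when no interior cells exist).
#' @export
cluster_stats <- function(snapshot, scaffold) {
  stopifnot(inherits(scaffold, "ca_scaffold"))
  need <- c("x", "y", "z")
  if (!all(need %in% names(snapshot))) stop("snapshot needs x, y, z columns")
  dims <- scaffold$dims
  if (nrow(snapshot) > 0 &&
      (max(snapshot$x) >= dims[["nx"]] || max(snapshot$y) >= dims[["ny"]] ||
       max(snapshot$z) >= dims[["nz"]] || min(snapshot[, need]) < 0))
    stop("snapshot coordinates exceed scaffold dimensions")
  n <- nrow(snapshot)
  if (n == 0) {
    return(structure(list(n_clusters = 0L, sizes = integer(0),
                          labels = integer(0),
                          mean_pore_distance = numeric(0),
                          interior_quiescent_fraction = NaN),
                     class = "cluster_stats"))
  }
  nx <- dims[["nx"]]; ny <- dims[["ny"]]
  lin <- snapshot$x + nx * (snapshot$y + ny * snapshot$z)
  if (anyDuplicated(lin)) stop("snapshot has multiply-occupied sites")
  # half the 26 offsets; the other half follows by symmetry
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[off$dx != 0 | off$dy != 0 | off$dz != 0, ]
  off <- off[off$dz > 0 | (off$dz == 0 & (off$dy > 0 |
                                            (off$dy == 0 & off$dx > 0))), ]
  edges <- integer(0)
  n_occ_nb <- integer(n)
  for (r in seq_len(nrow(off))) {
    tx <- snapshot$x + off$dx[r]; ty <- snapshot$y + off$dy[r]
    tz <- snapshot$z + off$dz[r]
    ok <- tx >= 0 & tx < nx & ty >= 0 & ty < ny & tz >= 0 & tz < dims[["nz"]]
    m <- match(tx + nx * (ty + ny * tz), lin)
    hit <- ok & !is.na(m)
    n_occ_nb <- n_occ_nb + hit
    n_occ_nb[m[hit]] <- n_occ_nb[m[hit]] + 1L
    if (any(hit)) edges <- c(edges, rbind(which(hit), m[hit]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  labels <- comp$membership
  sizes <- as.integer(comp$csize)
  # number of in-bounds 26-neighbour sites per cell
  win <- function(v, lim) pmin(v + 1, lim - 1) - pmax(v - 1, 0) + 1
  inb26 <- as.integer(win(snapshot$x, nx) * win(snapshot$y, ny) *
                        win(snapshot$z, dims[["nz"]]) - 1)
  interior <- n_occ_nb == inb26 & inb26 > 0
  iq <- if (any(interior) && "phase" %in% names(snapshot))
    mean(snapshot$phase[interior] == "QUIESCENT") else NaN
  pd <- distance_to_nearest_pore(scaffold,
                                 as.matrix(snapshot[, c("x", "y", "z")]))
  mpd <- as.numeric(tapply(pd$distance, labels, mean))
  structure(list(n_clusters = comp$no, sizes = sizes, labels = labels,
                 mean_pore_distance = mpd,
                 interior_quiescent_fraction = iq),
            class = "cluster_stats")
}

#' Mean distance to the nearest pore
#'
#' Population-mean Euclidean distance from cell positions to the nearest
#' pore site; the "crawling toward the pores" signature decreases this over
#' the culture period in biased-movement mode.
#'
#' @param snapshot cell table with `x, y, z` (and `phase` when
#'   `live_only = TRUE`).
#' @param scaffold a [build_scaffold()] object.
#' @param live_only restrict to live (non-dead) cells.
#' @return mean distance in lattice units (`NaN` for an empty selection).
#' @export
mean_pore_distance <- function(snapshot, scaffold, live_only = TRUE) {
  if (live_only && "phase" %in% names(snapshot))
    snapshot <- snapshot[snapshot$phase != "DEAD", , drop = FALSE]
  if (nrow(snapshot) == 0) return(NaN)
  mean(distance_to_nearest_pore(
    scaffold, as.matrix(snapshot[, c("x", "y", "z")]))$distance)
}

#' Ensemble-size consistency analysis
#'
#' Reruns ensembles of increasing size and reports the across-run standard
#' deviation of the day-11 (end-of-horizon) fold, viability and
#' proliferating fraction. The recommended size is the smallest `n` whose
#' SDs all change by less than `tol` relative to the next larger `n`
#' (the reference reproduction settled on n = 100).
#'
#' @param params a [sim_params()] object.
#' @param n_grid increasing ensemble sizes to probe.
#' @param scaffold optional [build_scaffold()] object.
#' @param tol relative-change criterion (default 0.10).
#' @return data frame `n, sd_fold, sd_viability, sd_ki67` with attribute
#'   `recommended_n` (`NA` when no size qualifies).
#' @export
consistency_analysis <- function(params, n_grid, scaffold = NULL, tol = 0.10) {
  n_grid <- as.integer(n_grid)
  if (length(n_grid) == 0 || is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be non-empty and strictly increasing")
  if (is.null(scaffold)) scaffold <- build_scaffold()
  tend <- params$horizon
  rows <- lapply(n_grid, function(n) {
    ens <- run_ensemble(params, n, scaffold)
    m <- vapply(ens$runs, function(r) c(
      fold = fold_proliferation(r$timeseries, tend),
      viability = viable_fraction(r$timeseries, tend),
      ki67 = proliferating_fraction(r$timeseries, tend)), numeric(3))
    if (n > 1) apply(m, 1, stats::sd) else c(fold = 0, viability = 0, ki67 = 0)
  })
  out <- data.frame(n = n_grid, do.call(rbind, rows))
  names(out) <- c("n", "sd_fold", "sd_viability", "sd_ki67")
  rec <- NA_integer_
  if (length(n_grid) > 1) {
    for (i in seq_len(length(n_grid) - 1)) {
      a <- unlist(out[i, -1]); b <- unlist(out[i + 1, -1])
      rel <- abs(b - a) / ifelse(abs(a) > 0, abs(a), 1)
      if (all(rel < tol)) { rec <- n_grid[i]; break }
    }
  }
  attr(out, "recommended_n") <- rec
  out
}
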