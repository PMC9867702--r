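# shared fixtures: everything is generated in code, no data files

# tiny pore-free lattice for oracle comparisons
tiny_scaffold <- function(nx = 6, ny = 6, nz = 3) {
  build_scaffold(grid_dims(nx, ny, nz), NULL)
}

# small lattice with one central pore column
pored_scaffold <- function() {
  build_scaffold(grid_dims(8, 8, 4), pore_spec(c(3, 3, 0, 2, 2, 4)))
}

# mid-size porous lattice for property sweeps
mid_scaffold <- function() {
  build_scaffold(grid_dims(40, 40, 10), pore_spec(c(15, 15, 0, 10, 10, 10)))
}

# parameters scaled for tiny oracle runs
tiny_params <- function(...) {
  p <- sim_params(c_initial = 4, capacity = 12, p_abort = 0.7,
                  doubling = doubling_dist(20, 4), cd_min = 6, cd_max = 18,
                  p_death = 0.2, m_c = 3, m_jitter_max = 2, L_c = 2,
                  L_p = 5, alpha = 0.4, beta = 1.2, horizon = 200, seed = 1)
  update_params(p, ...)
}

# parameters at the calibrated scale, shrunk to the quarter lattice
quarter_params <- function(...) {
  p <- sim_params()
  r <- quarter_scaffold()$n_hydrogel / build_scaffold()$n_hydrogel
  p <- update_params(p, c_initial = round(p$c_initial * r),
                     capacity = round(p$capacity * r))
  update_params(p, ...)
}

expect_states_equal <- function(a, b, tol = 1e-9) {
  expect_equal(length(a), length(b))
  flat <- function(s) do.call(rbind, lapply(s, function(d) {
    rownames(d) <- NULL
    d
  }))
  expect_equal(flat(a), flat(b), tolerance = tol, ignore_attr = TRUE)
}

# brute-force flood fill, 26-connectivity, independent of igraph
flood_fill_labels <- function(snapshot) {
  n <- nrow(snapshot)
  key <- paste(snapshot$x, snapshot$y, snapshot$z)
  idx <- seq_len(n)
  names(idx) <- key
  labels <- integer(n)
  lab <- 0L
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[off$dx != 0 | off$dy != 0 | off$dz != 0, ]
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labels[i] != 0L) next
      labels[i] <- lab
      nb <- paste(snapshot$x[i] + off$dx, snapshot$y[i] + off$dy,
                  snapshot$z[i] + off$dz)
      hit <- idx[nb[nb %in% key]]
      stack <- c(stack, hit[labels[hit] == 0L])
    }
  }
  labels
}
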