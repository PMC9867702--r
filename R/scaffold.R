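#' Lattice dimensions
#'
#' Extents of the simulated scaffold subdomain in lattice sites. Coordinates
#' throughout the package are 0-based integers `(x, y, z)`; `z` is the thin
#' axis of the printed construct.
#'
#' @param nx,ny,nz positive integer extents. Default `190 x 190 x 30`,
#'   the simulated subdomain of the printed scaffold.
#' @return an integer vector of class `"grid_dims"` with names `nx, ny, nz`.
#' @export
#' @examples
#' grid_dims(10, 10, 3)
grid_dims <- function(nx = 190L, ny = 190L, nz = 30L) {
  d <- c(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz))
  if (anyNA(d) || any(d < 1L)) stop("lattice extents must be integers >= 1")
  structure(d, class = "grid_dims")
}

#' Default symmetric four-pore layout
#'
#' The printed scaffold carries four square pores of width 50 x 50 spanning
#' the full thickness. Their in-plane placement is the unique symmetric
#' 2 x 2 arrangement with equal margins and gap on a 190-wide lattice:
#' x (and y) ranges `[30, 80)` and `[110, 160)` (30 + 50 + 30 + 50 + 30 = 190).
#'
#' @param dims a [grid_dims()] object.
#' @return an integer matrix with one row per pore box and columns
#'   `x0, y0, z0, wx, wy, wz` (0-based origin, half-open widths).
#' @export
default_pores <- function(dims = grid_dims()) {
  if (dims[["nx"]] < 160L || dims[["ny"]] < 160L)
    stop("default four-pore layout needs an in-plane extent of at least 160; ",
         "supply pore boxes explicitly for smaller lattices")
  m <- rbind(
    c(30L, 30L, 0L, 50L, 50L, dims[["nz"]]),
    c(110L, 30L, 0L, 50L, 50L, dims[["nz"]]),
    c(30L, 110L, 0L, 50L, 50L, dims[["nz"]]),
    c(110L, 110L, 0L, 50L, 50L, dims[["nz"]])
  )
  colnames(m) <- c("x0", "y0", "z0", "wx", "wy", "wz")
  m
}

#' Specify pore boxes
#'
#' @param boxes numeric matrix (or vector for a single box) with columns
#'   `x0, y0, z0, wx, wy, wz`: 0-based origin and widths; boxes are half-open
#'   `[x0, x0 + wx)` along each axis.
#' @return validated integer matrix of pore boxes.
#' @export
pore_spec <- function(boxes) {
  if (is.null(boxes) || (is.matrix(boxes) && nrow(boxes) == 0)) {
    m <- matrix(integer(0), ncol = 6)
    colnames(m) <- c("x0", "y0", "z0", "wx", "wy", "wz")
    return(m)
  }
  if (!is.matrix(boxes)) boxes <- matrix(boxes, ncol = 6, byrow = TRUE)
  storage.mode(boxes) <- "integer"
  if (ncol(boxes) != 6) stop("pore boxes need 6 columns (x0,y0,z0,wx,wy,wz)")
  if (any(boxes[, 4:6] < 1)) stop("pore widths must be >= 1")
  colnames(boxes) <- c("x0", "y0", "z0", "wx", "wy", "wz")
  boxes
}

#' Build a porous scaffold lattice
#'
#' Classifies every lattice site as hydrogel or pore. Pore sites can never
#' be occupied by cells (cells do not enter the open channels in vitro).
#' Boundaries are reflecting: there is no wraparound and out-of-bounds moves
#' are infeasible.
#'
#' @param dims a [grid_dims()] object.
#' @param pores a [pore_spec()] matrix; `NULL` for a pore-free lattice.
#' @return an object of class `"ca_scaffold"`: list with `dims`, `pores`,
#'   `pore_mask` (logical array, `TRUE` = pore) and site counts
#'   `n_total`, `n_pore`, `n_hydrogel`.
#' @export
#' @examples
#' sc <- build_scaffold(grid_dims(10, 10, 3), NULL)
#' sc$n_hydrogel # 300
build_scaffold <- function(dims = grid_dims(), pores = default_pores(dims)) {
  stopifnot(inherits(dims, "grid_dims"))
  pores <- pore_spec(pores)
  nx <- dims[["nx"]]; ny <- dims[["ny"]]; nz <- dims[["nz"]]
  mask <- array(FALSE, dim = c(nx, ny, nz))
  if (nrow(pores) > 0) {
    for (b in seq_len(nrow(pores))) {
      x1 <- pores[b, "x0"] + pores[b, "wx"]
      y1 <- pores[b, "y0"] + pores[b, "wy"]
      z1 <- pores[b, "z0"] + pores[b, "wz"]
      if (any(pores[b, 1:3] < 0) || x1 > nx || y1 > ny || z1 > nz)
        stop("pore box ", b, " exceeds lattice bounds")
      xs <- (pores[b, "x0"] + 1):x1
      ys <- (pores[b, "y0"] + 1):y1
      zs <- (pores[b, "z0"] + 1):z1
      if (any(mask[xs, ys, zs]))
        stop("pore boxes overlap (box ", b, ")")
      mask[xs, ys, zs] <- TRUE
    }
  }
  n_pore <- sum(mask)
  structure(list(
    dims = dims, pores = pores, pore_mask = mask,
    n_total = nx * ny * nz, n_pore = n_pore,
    n_hydrogel = nx * ny * nz - n_pore
  ), class = "ca_scaffold")
}

#' @export
print.ca_scaffold <- function(x, ...) {
  cat(sprintf("<ca_scaffold> %d x %d x %d lattice; %d pore box(es)\n",
              x$dims[["nx"]], x$dims[["ny"]], x$dims[["nz"]], nrow(x$pores)))
  cat(sprintf("  sites: %d total = %d hydrogel + %d pore\n",
              x$n_total, x$n_hydrogel, x$n_pore))
  invisible(x)
}

check_pos <- function(pos, dims) {
  pos <- as.integer(pos)
  if (length(pos) != 3 || anyNA(pos)) stop("pos must be 3 integers (x,y,z)")
  if (any(pos < 0) || pos[1] >= dims[["nx"]] || pos[2] >= dims[["ny"]] ||
      pos[3] >= dims[["nz"]])
    stop("position out of lattice bounds: (", paste(pos, collapse = ","), ")")
  pos
}

#' Site classification
#'
#' @param scaffold a [build_scaffold()] object.
#' @param pos 0-based `(x, y, z)` coordinate.
#' @return `"PORE"` or `"HYDROGEL"`.
#' @export
site_class <- function(scaffold, pos) {
  pos <- check_pos(pos, scaffold$dims)
  if (scaffold$pore_mask[pos[1] + 1, pos[2] + 1, pos[3] + 1]) "PORE" else "HYDROGEL"
}

#' Moore-neighbourhood shell
#'
#' Sites at Chebyshev distance exactly `order` from `pos`, clipped to the
#' lattice; `pos` itself is excluded. Daughter placement searches these
#' shells nearest-first (order 1, then 2, then 3).
#'
#' @param pos 0-based `(x, y, z)` coordinate.
#' @param order shell order, one of 1, 2, 3.
#' @param dims a [grid_dims()] object.
#' @return integer matrix with columns `x, y, z`, one row per in-bounds site.
#' @export
moore_neighborhood <- function(pos, order, dims) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  pos <- check_pos(pos, dims)
  k <- as.integer(order)
  out <- matrix(integer(0), ncol = 3)
  # enumeration order matches the engine: dz outer, dy, dx inner
  for (dz in -k:k) for (dy in -k:k) for (dx in -k:k) {
    if (max(abs(dx), abs(dy), abs(dz)) != k) next
    p <- pos + c(dx, dy, dz)
    if (any(p < 0) || p[1] >= dims[["nx"]] || p[2] >= dims[["ny"]] ||
        p[3] >= dims[["nz"]]) next
    out <- rbind(out, p)
  }
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Six axis neighbours with direction labels
#'
#' Direction convention: right/left = +x/-x, up/down = +y/-y,
#' forward/backward = +z/-z.
#'
#' @param pos 0-based `(x, y, z)` coordinate.
#' @param dims a [grid_dims()] object.
#' @return data frame with `direction`, `x`, `y`, `z`, `feasible`
#'   (`FALSE` when the step leaves the lattice).
#' @export
six_neighbors <- function(pos, dims) {
  pos <- check_pos(pos, dims)
  off <- rbind(right = c(1, 0, 0), left = c(-1, 0, 0),
               up = c(0, 1, 0), down = c(0, -1, 0),
               forward = c(0, 0, 1), backward = c(0, 0, -1))
  tgt <- sweep(off, 2, pos, "+")
  feas <- tgt[, 1] >= 0 & tgt[, 1] < dims[["nx"]] &
    tgt[, 2] >= 0 & tgt[, 2] < dims[["ny"]] &
    tgt[, 3] >= 0 & tgt[, 3] < dims[["nz"]]
  data.frame(direction = rownames(off), x = tgt[, 1], y = tgt[, 2],
             z = tgt[, 3], feasible = unname(feas),
             stringsAsFactors = FALSE)
}

#' Euclidean distance to the nearest pore site
#'
#' Minimum Euclidean distance from a hydrogel site to any pore lattice site,
#' with the dominant axis of the displacement to that site reported as a
#' direction label. Ties between pore boxes are broken by the first box in
#' the scaffold's pore list; ties between axes by the priority x > y > z.
#'
#' @param scaffold a [build_scaffold()] object.
#' @param pos 0-based `(x, y, z)` coordinate (may be a matrix of rows).
#' @return list with `distance` (numeric, `Inf` when the lattice has no
#'   pores) and `direction` (one of the six labels, or `NA`).
#' @export
distance_to_nearest_pore <- function(scaffold, pos) {
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 3)
  for (i in seq_len(nrow(pos))) check_pos(pos[i, ], scaffold$dims)
  if (nrow(scaffold$pores) == 0) {
    return(list(distance = rep(Inf, nrow(pos)),
                direction = rep(NA_character_, nrow(pos))))
  }
  storage.mode(pos) <- "integer"
  r <- cpp_pore_distance(scaffold$pores, pos)
  labs <- c("right", "left", "up", "down", "forward", "backward")
  dir <- ifelse(r$direction >= 0, labs[r$direction + 1], NA_character_)
  list(distance = r$distance, direction = dir)
}
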