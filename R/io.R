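#' Load a run configuration
#'
#' Reads a JSON run configuration with up to three top-level blocks:
#' `params` (any [sim_params()] field; `doubling` as `{"mu": .., "sigma": ..}`),
#' `scaffold` (`dims` = 3 integers, `pores` = list of 6-number boxes or
#' `"default"` / `"none"`) and `output` (`snapshot_days`, `ensemble_n`).
#' Missing fields take the package defaults; unknown keys are rejected.
#'
#' @param path JSON file.
#' @return list of class `"run_config"` with `params` (a `"ca_params"`),
#'   `scaffold` (a `"ca_scaffold"`), `snapshot_days`, `ensemble_n`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known_top <- c("params", "scaffold", "output")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))

  pdefaults <- sim_params()
  pl <- cfg$params
  if (!is.null(pl)) {
    bad <- setdiff(names(pl), names(pdefaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    if (!is.null(pl$doubling)) {
      d <- pl$doubling
      bad <- setdiff(names(d), c("mu", "sigma"))
      if (length(bad)) stop("unknown doubling field(s): ",
                            paste(bad, collapse = ", "))
      pl$doubling <- doubling_dist(if (is.null(d$mu)) 96 else d$mu,
                                   if (is.null(d$sigma)) 6 else d$sigma)
    }
    params <- do.call(update_params, c(list(pdefaults), pl))
  } else params <- pdefaults

  sl <- cfg$scaffold
  dims <- grid_dims()
  pores <- NULL
  if (!is.null(sl)) {
    bad <- setdiff(names(sl), c("dims", "pores"))
    if (length(bad)) stop("unknown scaffold field(s): ",
                          paste(bad, collapse = ", "))
    if (!is.null(sl$dims)) dims <- grid_dims(sl$dims[1], sl$dims[2], sl$dims[3])
    if (!is.null(sl$pores)) {
      pores <- sl$pores
      if (identical(pores, "default")) pores <- default_pores(dims)
      else if (identical(pores, "none")) pores <- pore_spec(NULL)
      else pores <- pore_spec(if (is.matrix(pores)) pores
                              else do.call(rbind, pores))
    }
  }
  if (is.null(pores)) pores <- default_pores(dims)
  scaffold <- build_scaffold(dims, pores)

  snapshot_days <- c(0, 4, 7, 11)
  ensemble_n <- 100L
  ol <- cfg$output
  if (!is.null(ol)) {
    bad <- setdiff(names(ol), c("snapshot_days", "ensemble_n"))
    if (length(bad)) stop("unknown output field(s): ",
                          paste(bad, collapse = ", "))
    if (!is.null(ol$snapshot_days)) snapshot_days <- ol$snapshot_days
    if (!is.null(ol$ensemble_n)) ensemble_n <- as.integer(ol$ensemble_n)
  }
  structure(list(params = params, scaffold = scaffold,
                 snapshot_days = snapshot_days, ensemble_n = ensemble_n),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes a [load_config()]-compatible JSON file; `save -> load` round-trips
#' to an identical configuration.
#'
#' @param config a `"run_config"` object (or the list returned by
#'   [load_config()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  p <- config$params
  pl <- p[setdiff(names(p), "doubling")]
  pl$doubling <- list(mu = p$doubling$mu, sigma = p$doubling$sigma)
  out <- list(
    params = pl,
    scaffold = list(dims = as.integer(config$scaffold$dims),
                    pores = unname(apply(config$scaffold$pores, 1,
                                         as.integer, simplify = FALSE))),
    output = list(snapshot_days = config$snapshot_days,
                  ensemble_n = config$ensemble_n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Snapshot voxel codes
#'
#' Maps a cell snapshot onto the full lattice as 8-bit state codes:
#' 0 empty, 64 pore, 128 quiescent, 192 dead, 255 proliferative.
#'
#' @param snapshot cell table with `x, y, z, phase`.
#' @param scaffold a [build_scaffold()] object.
#' @return integer 3D array `(nx, ny, nz)`.
#' @export
snapshot_to_codes <- function(snapshot, scaffold) {
  d <- scaffold$dims
  a <- array(0L, dim = c(d[["nx"]], d[["ny"]], d[["nz"]]))
  a[scaffold$pore_mask] <- 64L
  if (nrow(snapshot) > 0) {
    code <- c(PROLIFERATIVE = 255L, QUIESCENT = 128L, DEAD = 192L)
    idx <- cbind(snapshot$x + 1L, snapshot$y + 1L, snapshot$z + 1L)
    a[idx] <- code[snapshot$phase]
  }
  a
}

# --- minimal baseline TIFF (no R TIFF writer is available offline) -------
# Uncompressed 8-bit grayscale, little-endian, one strip per page, one page
# per z-slice. Only the baseline tags needed by common readers are written.

tiff_tag <- function(id, type, count, value) {
  # type 3 = SHORT, 4 = LONG
  val <- if (type == 3) writeBin(c(as.integer(value), 0L), raw(),
                                 size = 2, endian = "little")[1:4]
  else writeBin(as.integer(value), raw(), size = 4, endian = "little")
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    val)
}

#' Write a multi-page 8-bit grayscale TIFF
#'
#' @param path output file.
#' @param codes integer array `(nx, ny, nz)` of 0..255 values, e.g. from
#'   [snapshot_to_codes()]; one TIFF page per z-slice, rows = y, columns = x.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(path, codes) {
  stopifnot(length(dim(codes)) == 3)
  nx <- dim(codes)[1]; ny <- dim(codes)[2]; nz <- dim(codes)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42L)
  page_bytes <- nx * ny
  n_entries <- 9L
  ifd_bytes <- 2 + n_entries * 12 + 4
  # layout: header(8) then per page: [pixel data][IFD]
  first_ifd <- 8 + page_bytes
  u32(first_ifd)
  for (z in seq_len(nz)) {
    off_data <- 8 + (z - 1) * (page_bytes + ifd_bytes)
    # pixel data, row-major rows = y
    slice <- t(codes[, , z]) # rows = y, cols = x
    writeBin(as.raw(as.vector(t(slice))), con)
    # IFD
    u16(n_entries)
    tags <- c(tiff_tag(256, 4, 1, nx),          # ImageWidth
              tiff_tag(257, 4, 1, ny),          # ImageLength
              tiff_tag(258, 3, 1, 8),           # BitsPerSample
              tiff_tag(259, 3, 1, 1),           # Compression: none
              tiff_tag(262, 3, 1, 1),           # Photometric: BlackIsZero
              tiff_tag(273, 4, 1, off_data),    # StripOffsets
              tiff_tag(277, 3, 1, 1),           # SamplesPerPixel
              tiff_tag(278, 4, 1, ny),          # RowsPerStrip
              tiff_tag(279, 4, 1, page_bytes))  # StripByteCounts
    writeBin(tags, con)
    next_ifd <- if (z < nz) 8 + z * (page_bytes + ifd_bytes) + page_bytes else 0
    u32(next_ifd)
  }
  invisible(path)
}

#' Count pages of a TIFF file
#'
#' Follows the IFD chain of a little-endian TIFF; used to verify snapshot
#' exports (one page per z-slice).
#'
#' @param path TIFF file.
#' @return integer page count.
#' @export
tiff_page_count <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II") stop("not a little-endian TIFF")
  u16 <- function(o) readBin(raw[(o + 1):(o + 2)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(o) readBin(raw[(o + 1):(o + 4)], "integer", size = 4,
                             endian = "little")
  off <- u32(4)
  n <- 0L
  while (off != 0) {
    n <- n + 1L
    ne <- u16(off)
    off <- u32(off + 2 + ne * 12)
  }
  n
}

#' Write run outputs to a directory
#'
#' Writes `timeseries.csv`, `metrics.csv` (per recorded day), one
#' `snapshot_dayK.csv` and `snapshot_dayK.tiff` per stored snapshot, and
#' `run_meta.json` (full parameters, seed, package version, timestamp),
#' then returns a manifest of files with MD5 checksums.
#'
#' @param result a `"ca_sim"` from [run_simulation()].
#' @param out_dir output directory (created if needed).
#' @return data frame `file, md5`, invisibly; also written as
#'   `manifest.csv`.
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "ca_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ts <- result$timeseries
  utils::write.csv(ts, file.path(out_dir, "timeseries.csv"),
                   row.names = FALSE)
  days <- unique(c(0, ts$hour[ts$hour %% 24 == 0] / 24))
  safe <- function(f, t) tryCatch(f(ts, t), error = function(e) NA_real_)
  met <- data.frame(
    day = days,
    fold = vapply(days * 24, function(t) safe(fold_proliferation, t),
                  numeric(1)),
    viability = vapply(days * 24, function(t) safe(viable_fraction, t),
                       numeric(1)),
    ki67 = vapply(days * 24, function(t) safe(proliferating_fraction, t),
                  numeric(1)))
  utils::write.csv(met, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  for (nm in names(result$snapshots)) {
    day <- as.integer(sub("^h", "", nm)) / 24
    snap <- result$snapshots[[nm]]
    utils::write.csv(snap, file.path(out_dir, sprintf("snapshot_day%g.csv",
                                                      day)),
                     row.names = FALSE)
    write_tiff_stack(file.path(out_dir, sprintf("snapshot_day%g.tiff", day)),
                     snapshot_to_codes(snap, result$scaffold))
  }
  p <- result$params
  meta <- list(params = c(p[setdiff(names(p), "doubling")],
                          list(doubling = list(mu = p$doubling$mu,
                                               sigma = p$doubling$sigma))),
               scaffold = list(dims = as.integer(result$scaffold$dims),
                               pores = unname(apply(result$scaffold$pores, 1,
                                                    as.integer,
                                                    simplify = FALSE))),
               seed = p$seed,
               package_version = as.character(utils::packageVersion("bioprintCA")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
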