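#' Simulation parameters
#'
#' All tunable quantities of the cellular-automaton model. Defaults are the
#' package's calibrated base case for 4%/4% gelatin/alginate bioink (free
#' parameters fitted to the packaged in-vitro fold/viability/Ki-67 time
#' courses; see the methods vignette). Time unit is hours, space unit is
#' lattice sites.
#'
#' @param c_initial initial cell count seeded on the lattice (C_initial).
#' @param capacity scaffold carrying capacity C: above it, division attempts
#'   abort with probability `p_abort`.
#' @param p_abort abort probability P0 at capacity, in `[0, 1]`.
#' @param doubling a [doubling_dist()] (mu = 96 h, sigma = 6 h measured).
#' @param cd_min,cd_max quiescence-death threshold range C_d (hours): each
#'   cell draws its own tolerance uniformly from this range.
#' @param p_death per-hour death probability P_d once the quiescence spell
#'   exceeds the cell's threshold.
#' @param m_c movement period in hours (15 h base bioink; 20 h for the
#'   stiffer 4%/5% formulation).
#' @param m_jitter_max movement desynchronisation: a uniform integer on
#'   `[0, m_jitter_max]` hours is added to each rescheduled move.
#' @param L_c cell-attraction Chebyshev range (sites) for biased movement.
#' @param L_p pore-attraction Euclidean range (sites) for biased movement.
#' @param alpha,beta biased-movement weights for neighbouring cells and
#'   pores; calibrated with `alpha < beta` (cells are attracted more to the
#'   pores than to nearby cells).
#' @param movement_mode `"biased"` or `"random"`.
#' @param desync desynchronise initial cycle clocks uniformly on
#'   `[0, doubling_time)` (`TRUE`) or start all at 0 (`FALSE`).
#' @param reentry allow quiescent cells to re-enter the cycle while their
#'   quiescence spell is still below their death threshold.
#' @param dt time step in hours; the model is defined for `dt = 1`.
#' @param horizon simulated hours (264 = 11 days).
#' @param seed RNG seed recorded with every run.
#' @return list of class `"ca_params"`.
#' @export
sim_params <- function(c_initial = 3338L,
                       capacity = 9836L,
                       p_abort = 0.9896,
                       doubling = doubling_dist(96, 6),
                       cd_min = 71,
                       cd_max = 109,
                       p_death = 0.0164,
                       m_c = 15,
                       m_jitter_max = 4L,
                       L_c = 3L,
                       L_p = 10,
                       alpha = 0.07,
                       beta = 0.52,
                       movement_mode = c("biased", "random"),
                       desync = TRUE,
                       reentry = TRUE,
                       dt = 1,
                       horizon = 264L,
                       seed = 1L) {
  movement_mode <- match.arg(movement_mode)
  p <- list(c_initial = as.integer(c_initial), capacity = as.integer(capacity),
            p_abort = p_abort, doubling = doubling, cd_min = cd_min,
            cd_max = cd_max, p_death = p_death, m_c = m_c,
            m_jitter_max = as.integer(m_jitter_max), L_c = as.integer(L_c),
            L_p = L_p, alpha = alpha, beta = beta,
            movement_mode = movement_mode, desync = isTRUE(desync),
            reentry = isTRUE(reentry), dt = dt,
            horizon = as.integer(horizon), seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "ca_params")
}

validate_params <- function(p) {
  stopifnot(inherits(p$doubling, "doubling_dist"))
  if (p$dt != 1) stop("the model is defined for dt = 1 h")
  if (p$c_initial < 0) stop("c_initial must be >= 0")
  if (p$capacity < 1) stop("capacity must be >= 1")
  for (nm in c("p_abort", "p_death")) {
    v <- p[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  if (!(p$cd_min > 0) || p$cd_min > p$cd_max)
    stop("need 0 < cd_min <= cd_max")
  if (p$m_c <= 0) stop("m_c must be > 0")
  if (p$m_jitter_max < 0) stop("m_jitter_max must be >= 0")
  if (p$L_c < 1) stop("L_c must be >= 1")
  if (p$L_p <= 0) stop("L_p must be > 0")
  if (p$alpha < 0 || p$beta < 0) stop("alpha and beta must be >= 0")
  if (p$horizon < 1) stop("horizon must be >= 1 hour")
  invisible(p)
}

#' Update a parameter set
#'
#' @param params a [sim_params()] object.
#' @param ... named fields to replace (same names as [sim_params()]).
#' @return the modified `"ca_params"` object, revalidated.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "ca_params"))
  mods <- list(...)
  bad <- setdiff(names(mods), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  params$c_initial <- as.integer(params$c_initial)
  params$capacity <- as.integer(params$capacity)
  params$horizon <- as.integer(params$horizon)
  params$seed <- as.integer(params$seed)
  params$m_jitter_max <- as.integer(params$m_jitter_max)
  params$L_c <- as.integer(params$L_c)
  validate_params(params)
  params
}

#' @export
print.ca_params <- function(x, ...) {
  cat("<ca_params>\n")
  cat(sprintf("  C_initial %d | C %d | P0 %.4g | Cd [%g, %g] h | Pd %.4g\n",
              x$c_initial, x$capacity, x$p_abort, x$cd_min, x$cd_max,
              x$p_death))
  cat(sprintf("  doubling N(%g, %g) h | m_c %g h (+U{0..%d}) | %s movement\n",
              x$doubling$mu, x$doubling$sigma, x$m_c, x$m_jitter_max,
              x$movement_mode))
  cat(sprintf("  L_c %d | L_p %g | alpha %.3g | beta %.3g | horizon %d h | seed %d\n",
              x$L_c, x$L_p, x$alpha, x$beta, x$horizon, x$seed))
  invisible(x)
}
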