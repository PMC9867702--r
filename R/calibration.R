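#' Packaged in-vitro calibration dataset
#'
#' Day-indexed fold-proliferation (MTT), viability (live/dead) and Ki-67
#' observations for the base-case 4%/4% gelatin/alginate bioprinted
#' construct, as packaged fixtures. Viability and Ki-67 SDs are the
#' reported ones; fold SDs are set to 5% of the mean (error bars were
#' graphical only). The day-0 viability of 0.76 reflects printing damage,
#' which is outside the post-printing model, and is excluded from the
#' calibration objective.
#'
#' @param path CSV file with columns `day, metric, mean, sd, n`; defaults
#'   to the packaged base-case fixture.
#' @return data frame of class `"invitro_data"`.
#' @export
in_vitro_base <- function(path = system.file("extdata", "invitro_base.csv",
                                             package = "bioprintCA")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "metric", "mean", "sd", "n")
  if (!identical(names(d)[seq_along(need)], need))
    stop("in-vitro dataset must have columns: ", paste(need, collapse = ", "))
  if (any(d$day < 0) || any(d$sd <= 0)) stop("days must be >= 0 and sds > 0")
  if (!all(d$metric %in% c("fold", "viability", "ki67")))
    stop("unknown metric in dataset")
  class(d) <- c("invitro_data", class(d))
  d
}

sim_metric <- function(runs, metric, day) {
  t <- day * 24
  vals <- vapply(runs, function(r) switch(
    metric,
    fold = fold_proliferation(r$timeseries, t),
    viability = viable_fraction(r$timeseries, t),
    ki67 = proliferating_fraction(r$timeseries, t),
    stop("metric '", metric, "' not produced by the simulation")),
    numeric(1))
  mean(vals)
}

#' Weighted least-squares calibration objective
#'
#' Sum over observations of `((ensemble mean - observed mean) / sd)^2`,
#' i.e. inverse-variance-weighted squared residuals using the printed SDs.
#' Day-0 viability (printing damage) is excluded: the model starts
#' post-printing with every cell alive.
#'
#' @param params a [sim_params()] object to score.
#' @param data an [in_vitro_base()]-style dataset.
#' @param n_runs ensemble size used for the model means (>= 2).
#' @param scaffold optional [build_scaffold()] object.
#' @return non-negative objective value, with the per-observation residual
#'   table in attribute `"residuals"`.
#' @export
calibration_objective <- function(params, data, n_runs = 5,
                                  scaffold = NULL) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  obs <- data[!(data$metric == "viability" & data$day == 0), , drop = FALSE]
  if (nrow(obs) == 0) {
    out <- 0
    attr(out, "residuals") <- data.frame()
    return(out)
  }
  if (max(obs$day) * 24 > params$horizon)
    stop("dataset has observations beyond the simulation horizon")
  ens <- run_ensemble(params, n_runs, scaffold)
  obs$model <- vapply(seq_len(nrow(obs)), function(i)
    sim_metric(ens$runs, obs$metric[i], obs$day[i]), numeric(1))
  obs$residual <- (obs$model - obs$mean) / obs$sd
  out <- sum(obs$residual^2)
  attr(out, "residuals") <- obs
  out
}

#' Default calibration search space
#'
#' Per-parameter bounds for the free parameters. The movement period is
#' pinned at the base-bioink value m_c = 15 h; the cell-attraction weight
#' stays below the pore-attraction weight (`alpha < beta`), as concluded
#' from the in-vitro cluster observations. The initial-count range is
#' centred on the seeding-density scale argument (case-1 bioink at
#' 1.5e6 cells/mL maps to 2000 lattice cells, so the base 2-2.5e6 cells/mL
#' maps to roughly 3000). `cd_span` parameterises `cd_max = cd_min +
#' cd_span`.
#'
#' @return named list of `c(lower, upper)` bounds; integer parameters are
#'   rounded when sampled.
#' @export
default_search_space <- function() {
  list(c_initial = c(2400, 3600),
       capacity = c(6500, 10800),
       p_abort = c(0.9, 1.0),
       cd_min = c(24, 96),
       cd_span = c(0, 96),
       p_death = c(0.001, 0.05),
       alpha = c(0, 0.5),
       beta = c(0.5, 2.0),
       L_c = c(2, 4),
       L_p = c(6, 15),
       m_c = c(15, 15))
}

space_integer <- c("c_initial", "capacity", "L_c", "L_p")

#' Latin-hypercube sample of a search space
#'
#' One stratified uniform draw per parameter and candidate: stratum order
#' is permuted per parameter, positions are uniform within strata.
#'
#' @param space a [default_search_space()]-style list of bounds.
#' @param n number of candidates.
#' @return data frame, one row per candidate.
#' @keywords internal
lhs_sample <- function(space, n) {
  out <- lapply(names(space), function(nm) {
    b <- space[[nm]]
    if (!(is.numeric(b) && length(b) == 2 && b[1] <= b[2]))
      stop("infeasible bounds for ", nm)
    u <- (sample.int(n) - stats::runif(n)) / n
    v <- b[1] + u * (b[2] - b[1])
    if (nm %in% space_integer) v <- round(v)
    v
  })
  names(out) <- names(space)
  as.data.frame(out)
}

candidate_params <- function(row, base) {
  update_params(base,
                c_initial = row$c_initial, capacity = row$capacity,
                p_abort = row$p_abort, cd_min = row$cd_min,
                cd_max = row$cd_min + row$cd_span, p_death = row$p_death,
                alpha = row$alpha, beta = row$beta, L_c = row$L_c,
                L_p = row$L_p, m_c = row$m_c)
}

#' Quarter-lattice search scaffold
#'
#' The reduced 95 x 95 x 30 quadrant of the standard scaffold (one pore at
#' `[30, 80)` in x and y), used to keep the calibration search cheap.
#' Extensive parameters (`c_initial`, `capacity`) are scaled by the
#' hydrogel-site ratio when candidates are evaluated on it.
#'
#' @return a `"ca_scaffold"` object.
#' @export
quarter_scaffold <- function() {
  build_scaffold(grid_dims(95, 95, 30),
                 pore_spec(c(30, 30, 0, 50, 50, 30)))
}

#' Calibrate free parameters to an in-vitro dataset
#'
#' Seeded random search: a Latin-hypercube sample of `budget` candidates is
#' scored with small search ensembles (`n_runs_search`) on a reduced
#' scaffold, the top `rescore_top` candidates are re-scored with
#' `n_runs_rescore` runs, and the best re-scored candidate is returned on
#' the full-lattice scale. Fully reproducible given `seed`.
#'
#' @param data an [in_vitro_base()]-style dataset.
#' @param space parameter bounds, see [default_search_space()].
#' @param budget number of candidates (>= 1).
#' @param n_runs_search ensemble size per candidate during search.
#' @param seed RNG seed for the whole procedure.
#' @param base a [sim_params()] template supplying the non-searched fields.
#' @param search_scaffold scaffold used during the search
#'   (default [quarter_scaffold()]).
#' @param full_scaffold the target scaffold the returned parameters refer
#'   to (default the standard 190 x 190 x 30 lattice).
#' @param rescore_top,n_runs_rescore re-scoring of the leaders.
#' @return list of class `"ca_calibration"`: `params` (best fit, full
#'   scale), `objective`, `residuals`, `history` (all candidates and search
#'   scores), `seed`, `budget`, `n_runs_search`, `n_runs_rescore`.
#' @export
calibrate_model <- function(data, space = default_search_space(),
                            budget = 200, n_runs_search = 5, seed = 1,
                            base = sim_params(),
                            search_scaffold = quarter_scaffold(),
                            full_scaffold = build_scaffold(),
                            rescore_top = 5, n_runs_rescore = 25) {
  if (budget < 1) stop("budget must be >= 1")
  set.seed(seed)
  ratio <- search_scaffold$n_hydrogel / full_scaffold$n_hydrogel
  score_one <- function(row, i) {
    p <- candidate_params(row, base)
    ps <- update_params(p,
                        c_initial = max(1, round(p$c_initial * ratio)),
                        capacity = max(1, round(p$capacity * ratio)),
                        seed = seed + i * 1000L)
    calibration_objective(ps, data, n_runs_search, search_scaffold)
  }
  # stage 1: global Latin-hypercube sweep (~70% of the budget)
  n1 <- if (budget >= 10) ceiling(0.7 * budget) else budget
  cand <- lhs_sample(space, n1)
  scores <- vapply(seq_len(n1), function(i) score_one(cand[i, ], i),
                   numeric(1))
  # stage 2: local refinement around the current leaders (noisy scores make
  # the flat optimum hard to pin down in one pass); boxes are +/- 15% of
  # each parameter range, clipped to the bounds
  n2 <- budget - n1
  if (n2 > 0) {
    leaders <- utils::head(order(scores), 3)
    for (k in seq_len(n2)) {
      centre <- cand[leaders[(k - 1) %% length(leaders) + 1], ]
      local_space <- lapply(names(space), function(nm) {
        b <- space[[nm]]
        w <- 0.15 * (b[2] - b[1])
        c(max(b[1], centre[[nm]] - w), min(b[2], centre[[nm]] + w))
      })
      names(local_space) <- names(space)
      row <- lhs_sample(local_space, 1)
      cand <- rbind(cand, row)
      scores <- c(scores, score_one(row, n1 + k))
    }
  }
  ord <- order(scores)
  top <- utils::head(ord, rescore_top)
  rescore <- vapply(seq_along(top), function(k) {
    i <- top[k]
    p <- candidate_params(cand[i, ], base)
    ps <- update_params(p,
                        c_initial = max(1, round(p$c_initial * ratio)),
                        capacity = max(1, round(p$capacity * ratio)),
                        seed = seed + 500000L + k * 1000L)
    calibration_objective(ps, data, n_runs_rescore, search_scaffold)
  }, numeric(1))
  best_i <- top[which.min(rescore)]
  best <- candidate_params(cand[best_i, ], base)
  best <- update_params(best, seed = as.integer(seed))
  final_obj <- calibration_objective(
    update_params(best,
                  c_initial = max(1, round(best$c_initial * ratio)),
                  capacity = max(1, round(best$capacity * ratio)),
                  seed = seed + 900000L),
    data, n_runs_rescore, search_scaffold)
  cand$score <- scores
  structure(list(params = best, objective = as.numeric(final_obj),
                 residuals = attr(final_obj, "residuals"),
                 history = cand, seed = seed, budget = budget,
                 n_runs_search = n_runs_search,
                 n_runs_rescore = n_runs_rescore),
            class = "ca_calibration")
}

#' @export
print.ca_calibration <- function(x, ...) {
  cat(sprintf("<ca_calibration> budget %d | objective %.2f | seed %d\n",
              x$budget, x$objective, x$seed))
  print(x$params)
  invisible(x)
}

#' Run a validation scenario
#'
#' Holds every calibrated parameter fixed and changes exactly what the
#' corresponding experiment changed: `"case1"` lowers the initial cell
#' density (`c_initial = 2000`, the 1.5e6 cells/mL bioink); `"case2"` slows
#' movement in the stiffer 4%/5% gelatin/alginate bioink (`m_c = 20` h).
#'
#' @param base calibrated [sim_params()].
#' @param scenario `"case1"` or `"case2"`.
#' @param n_runs ensemble size.
#' @param scaffold optional [build_scaffold()] object.
#' @param days measurement days (defaults: case1 `c(0, 3, 7, 10)`, case2
#'   `c(0, 4, 7, 11)`).
#' @return list with `scenario`, `params`, `days`, `fold` (ensemble-mean
#'   fold at each day), `fold_sd`, and the underlying `"ca_ensemble"`.
#' @export
run_scenario <- function(base, scenario, n_runs = 10, scaffold = NULL,
                         days = NULL) {
  stopifnot(inherits(base, "ca_params"))
  if (!scenario %in% c("case1", "case2"))
    stop("unknown scenario: ", scenario)
  p <- switch(scenario,
              case1 = update_params(base, c_initial = 2000L),
              case2 = update_params(base, m_c = 20))
  if (is.null(days))
    days <- if (scenario == "case1") c(0, 3, 7, 10) else c(0, 4, 7, 11)
  ens <- run_ensemble(p, n_runs, scaffold)
  f <- vapply(ens$runs, function(r)
    fold_proliferation(r$timeseries, days * 24), numeric(length(days)))
  f <- matrix(f, nrow = length(days))
  list(scenario = scenario, params = p, days = days,
       fold = rowMeans(f),
       fold_sd = apply(f, 1, stats::sd),
       ensemble = ens)
}
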