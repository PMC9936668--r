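#' RMSE cost of a parameter set against normalized-EMG targets
#'
#' Root-mean-square error between the model's normalized force-time
#' integrals for a set of stimulation patterns and the target normalized EMG
#' values for those patterns.
#'
#' @param params a [ding_params()] object.
#' @param patterns data.frame with `frequency` and `mpr` columns (one row
#'   per pattern; `mpr == frequency` is a constant pattern).
#' @param targets numeric target normalized EMG, one per pattern.
#' @param stim_s pattern duration, seconds.
#' @param dt_ms integrator step, ms.
#' @return the RMSE.
#' @export
pso_cost <- function(params, patterns, targets, stim_s = 30, dt_ms = 0.1) {
  if (!nrow(patterns)) stop("empty pattern set")
  stopifnot(length(targets) == nrow(patterns))
  pulses <- .pattern_pulses(patterns, stim_s)
  .pso_cost_fast(.ding_param_vec(params), pulses, targets, stim_s, dt_ms)
}

# pulse-onset vectors (seconds) for the rows of a pattern table
.pattern_pulses <- function(patterns, stim_s) {
  lapply(seq_len(nrow(patterns)), function(i)
    make_burst_train(patterns$frequency[i], patterns$mpr[i],
                     c(0, stim_s))$onsets)
}

# RMSE of normalized force-time integrals against targets, on precomputed
# pulse vectors (hot path of the swarm)
.pso_cost_fast <- function(pvec, pulses, targets, stim_s, dt_ms) {
  ref_p <- (seq_len(floor(stim_s * 20)) - 1) / 20
  ref <- .ding_simulate_c(ref_p * 1000, pvec, dt_ms,
                          (max(ref_p) + 0.5) * 1000, FALSE)$fti
  if (!is.finite(ref) || ref <= 0) return(Inf)
  fn <- vapply(pulses, function(p)
    .ding_simulate_c(p * 1000, pvec, dt_ms, (max(p) + 0.5) * 1000,
                     FALSE)$fti, numeric(1)) / ref
  sqrt(mean((fn - targets)^2))
}

#' Guide selection for the neighborhood swarm update
#'
#' The two guides of particle `i` follow the three-case neighborhood rule:
#' the neighborhood best is steered by the global best and the neighborhood
#' second best; the neighborhood second best by the neighborhood best and
#' third best; every other particle by the neighborhood best and second
#' best.  Ranking ties break by particle index (stable).
#'
#' @param i particle index.
#' @param costs numeric cost per particle.
#' @param neighborhoods integer neighborhood id per particle.
#' @return integer vector `c(best1, best2)` of guide particle indices.
#' @export
select_bests <- function(i, costs, neighborhoods) {
  global_best <- order(costs)[1]
  members <- which(neighborhoods == neighborhoods[i])
  ranked <- members[order(costs[members], members)]
  if (i == ranked[1]) c(global_best, ranked[2])
  else if (i == ranked[2]) c(ranked[1], ranked[3])
  else c(ranked[1], ranked[2])
}

#' One velocity-and-position update of the swarm
#'
#' For every particle except the global best (whose position is frozen):
#' `V = rand() * (P_best1 - P) - rand() * (P_best2 - P)` with `rand()`
#' uniform on (0, 1.496), drawn per dimension, and `P <- P + V` clipped to
#' the unit box (positions are bound-scaled internally).  The
#' `velocity_sign` toggle switches the second term to the conventional
#' attractive form `+ rand() * (P_best2 - P)`.
#'
#' @param positions particles-by-dimensions matrix in \[0, 1\].
#' @param costs numeric cost per particle.
#' @param neighborhoods integer neighborhood id per particle.
#' @param velocity_sign `"printed"` (subtract the second attraction) or
#'   `"conventional"` (add it).
#' @return updated position matrix.
#' @export
step_swarm <- function(positions, costs, neighborhoods,
                       velocity_sign = c("printed", "conventional")) {
  velocity_sign <- match.arg(velocity_sign)
  sgn <- if (velocity_sign == "printed") -1 else 1
  np <- nrow(positions); nd <- ncol(positions)
  global_best <- order(costs)[1]
  new_pos <- positions
  for (i in seq_len(np)) {
    if (i == global_best) next
    g <- select_bests(i, costs, neighborhoods)
    r1 <- stats::runif(nd, 0, 1.496)
    r2 <- stats::runif(nd, 0, 1.496)
    v <- r1 * (positions[g[1], ] - positions[i, ]) +
      sgn * r2 * (positions[g[2], ] - positions[i, ])
    new_pos[i, ] <- pmin(pmax(positions[i, ] + v, 0), 1)
  }
  new_pos
}

.pso_unscale <- function(x, lower, upper) lower + x * (upper - lower)

#' Fit the force-fatigue model by neighborhood particle swarm optimization
#'
#' 100 particles in 20 fixed neighborhoods of 5, 50 iterations per run,
#' uniform-in-bounds initialization, the three-case guide rule of
#' [select_bests()], and a frozen global best.  Patterns are split 50/50
#' into training and testing groups per run; training error drives the
#' swarm, and the final model is the run with the lowest total (all-pattern)
#' error.  Parameters are scaled to the unit box internally so the shared
#' random coefficients act uniformly across the eight heterogeneous scales.
#'
#' @param targets data.frame with `frequency`, `mpr`, and `target` (mean
#'   normalized EMG) for every pattern of the design.
#' @param split_seed,init_seed integer seeds for the train/test splits and
#'   the particle initialization/updates.
#' @param runs number of independent runs.
#' @param n_particles,n_neighborhoods,n_iter swarm geometry and length.
#' @param stim_s,dt_ms simulation length (s) and step (ms) for the cost.
#' @param velocity_sign see [step_swarm()].
#' @param fixed optional named numeric vector pinning a subset of the eight
#'   parameters to known values (those dimensions are not searched).
#' @param tau_c,R0 driver kinetics constants.
#' @param cost_fn optional replacement cost, `function(param_vector)` over
#'   the eight unscaled parameters (used to exercise the optimizer on
#'   surrogate surfaces); when supplied the muscle model is not run.
#' @return list with `params` (best [ding_params()]), `train_rmse`,
#'   `test_rmse`, `total_rmse`, `best_run`, and per-run `history` of the
#'   swarm-minimum cost.
#' @export
run_pso <- function(targets, split_seed = 1, init_seed = 2, runs = 5,
                    n_particles = 100, n_neighborhoods = 20, n_iter = 50,
                    stim_s = 30, dt_ms = 0.1,
                    velocity_sign = c("printed", "conventional"),
                    fixed = NULL, tau_c = 20, R0 = 2, cost_fn = NULL) {
  velocity_sign <- match.arg(velocity_sign)
  b <- .ding_bounds
  nd <- nrow(b)
  free <- if (is.null(fixed)) rep(TRUE, nd) else !(b$param %in% names(fixed))
  neighborhoods <- rep(seq_len(n_neighborhoods),
                       each = n_particles / n_neighborhoods)
  npat <- nrow(targets)

  make_params <- function(x) {
    v <- .pso_unscale(x, b$lower, b$upper)
    if (!is.null(fixed)) v[!free] <- fixed[b$param[!free]]
    ding_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
                tau_c = tau_c, R0 = R0, check = FALSE)
  }
  pulses <- .pattern_pulses(targets, stim_s)
  eval_cost <- function(x, rows) {
    cst <- if (!is.null(cost_fn))
      cost_fn(.pso_unscale(x, b$lower, b$upper))
    else
      .pso_cost_fast(.ding_param_vec(make_params(x)), pulses[rows],
                     targets$target[rows], stim_s, dt_ms)
    if (!is.finite(cst)) Inf else cst
  }

  run_results <- vector("list", runs)
  for (run in seq_len(runs)) {
    train_rows <- .with_seed(.sub_seed(split_seed, "split", run),
                             sort(sample.int(npat, npat %/% 2)))
    test_rows <- setdiff(seq_len(npat), train_rows)
    .with_seed(.sub_seed(init_seed, "swarm", run), {
      pos <- matrix(stats::runif(n_particles * nd), n_particles, nd)
      history <- numeric(n_iter)
      costs <- apply(pos, 1, eval_cost, rows = train_rows)
      for (iter in seq_len(n_iter)) {
        bad <- !is.finite(costs)
        if (any(bad)) {
          warning("re-initializing ", sum(bad), " non-finite-cost particles")
          pos[bad, ] <- stats::runif(sum(bad) * nd)
          costs[bad] <- apply(pos[bad, , drop = FALSE], 1, eval_cost,
                              rows = train_rows)
        }
        history[iter] <- min(costs)
        pos <- step_swarm(pos, costs, neighborhoods, velocity_sign)
        moved <- which(seq_len(n_particles) != order(costs)[1])
        costs[moved] <- apply(pos[moved, , drop = FALSE], 1, eval_cost,
                              rows = train_rows)
      }
      best <- order(costs)[1]
      run_results[[run]] <- list(
        x = pos[best, ], train_rmse = costs[best],
        test_rmse = eval_cost(pos[best, ], test_rows),
        total_rmse = eval_cost(pos[best, ], seq_len(npat)),
        history = history, train_rows = train_rows)
    })
  }
  totals <- vapply(run_results, `[[`, numeric(1), "total_rmse")
  best_run <- which.min(totals)
  br <- run_results[[best_run]]
  list(params = make_params(br$x), train_rmse = br$train_rmse,
       test_rmse = br$test_rmse, total_rmse = br$total_rmse,
       best_run = best_run,
       history = lapply(run_results, `[[`, "history"),
       runs = run_results)
}
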