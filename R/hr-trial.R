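#' Simulate a full heart-rate trial of the bradycardia model
#'
#' Chains the three model stages over the trial protocol: the stochastic
#' ganglion synapse ([simulate_icns()]), per-cell ACh release, and the
#' coupled sinoatrial network ([simulate_san()]).  Stimulation amplitude is
#' represented by the ACh synapse density: the number of the 100 pacemaker
#' cells (a seeded random subset) whose afferent carries the VNS-evoked
#' events.  The cells targeted by intrinsically firing ICNS cells receive
#' intrinsic-evoked ACh regardless of the density mask.  Heart rate is the
#' mean peripheral firing rate, normalized with the same baseline and
#' analysis windows used for in vivo-style ECG quantification.
#'
#' @param condition a [vns_condition()].
#' @param density integer in \[0, 100\]: number of pacemaker cells receiving
#'   VNS-evoked ACh.
#' @param seed integer seed; repeated runs differ only through it.
#' @param filtering logical; `FALSE` bypasses the ganglion synapse so every
#'   pulse releases ACh (the filtering-knockout perturbation).
#' @param protocol a [trial_protocol()].
#' @param params a [san_network_params()] list.
#' @param intrinsic logical; include intrinsic ICNS firing.
#' @return list with `hr_baseline`, `hr_stim`, `hr_norm`, `series`, and the
#'   masks used.
#' @export
run_hr_trial <- function(condition, density, seed, filtering = TRUE,
                         protocol = trial_protocol(),
                         params = san_network_params(), intrinsic = TRUE) {
  n <- params$nrow * params$ncol
  stopifnot(density >= 0, density <= n)
  train <- if (condition$amplitude > 0 && condition$mpr > 0)
    condition_train(condition, protocol) else NULL
  icns <- simulate_icns(train, protocol$total_s,
                        seed = .sub_seed(seed, "icns"), filtering = filtering,
                        n_cells = n,
                        intrinsic_cells = if (intrinsic) NULL else integer(0))
  mask <- .with_seed(.sub_seed(seed, "mask"),
                     sort(sample.int(n, density)))
  events <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- icns$intrinsic_events[[i]]
    if (i %in% mask) ev <- c(ev, icns$stim_events[[i]])
    events[[i]] <- ev
  }
  san <- simulate_san(events, protocol$total_s, seed = .sub_seed(seed, "san"),
                      params = params)
  ser <- network_hr_series(san, protocol$total_s)
  bw <- protocol$baseline_window; aw <- protocol$analysis_window
  base_ok <- ser$time >= bw[1] & ser$time < bw[2] & !is.na(ser$bpm)
  stim_ok <- ser$time >= aw[1] & ser$time < aw[2] & !is.na(ser$bpm)
  hr_baseline <- if (any(base_ok)) mean(ser$bpm[base_ok]) else NA_real_
  hr_stim <- if (any(stim_ok)) mean(ser$bpm[stim_ok]) else 0
  list(hr_baseline = hr_baseline, hr_stim = hr_stim,
       hr_norm = hr_stim / hr_baseline, series = ser,
       density_mask = mask, intrinsic_cells = icns$intrinsic_cells)
}

#' Mean modeled HR_norm across constant frequencies
#'
#' Convenience wrapper: mean normalized heart rate over `n_runs` seeded runs
#' of [run_hr_trial()] for each constant frequency at a given ACh density.
#'
#' @param density ACh synapse density in \[0, 100\].
#' @param frequencies constant frequencies, Hz.
#' @param n_runs seeded repeats per frequency.
#' @param seed base seed.
#' @param ... passed to [run_hr_trial()].
#' @return numeric vector of mean `hr_norm`, one per frequency.
#' @export
model_hr_curve <- function(density, frequencies, n_runs = 3, seed = 1, ...) {
  vapply(frequencies, function(f) {
    cond <- vns_condition(1.0, f)
    mean(vapply(seq_len(n_runs), function(r) {
      run_hr_trial(cond, density, seed = .sub_seed(seed, "curve", r * 1000 + f),
                   ...)$hr_norm
    }, numeric(1)))
  }, numeric(1))
}

#' Calibrate the ACh synapse density against a target HR_norm curve
#'
#' Finds the integer density in \[0, 100\] whose modeled HR_norm across the
#' constant-frequency grid best matches the target curve (minimum RMSE),
#' using bisection on the signed mean error; modeled HR_norm is monotone
#' non-increasing in density, which the search verifies at its endpoints.
#' Ties resolve to the lower density.
#'
#' @param targets target HR_norm values, one per frequency.
#' @param frequencies constant-frequency grid, Hz.
#' @param simulate_fn function(density) -> vector of modeled HR_norm per
#'   frequency; defaults to [model_hr_curve()] with the remaining arguments.
#' @param max_density upper bound of the search.
#' @param ... passed to [model_hr_curve()] when `simulate_fn` is NULL.
#' @return list with `density`, `rmse`, and the evaluated curve.
#' @export
calibrate_density <- function(targets, frequencies, simulate_fn = NULL,
                              max_density = 100, ...) {
  stopifnot(length(targets) == length(frequencies))
  if (is.null(simulate_fn))
    simulate_fn <- function(d) model_hr_curve(d, frequencies, ...)
  cache <- new.env(parent = emptyenv())
  eval_d <- function(d) {
    key <- as.character(d)
    if (is.null(cache[[key]])) cache[[key]] <- simulate_fn(d)
    cache[[key]]
  }
  err <- function(d) mean(eval_d(d) - targets)
  rmse <- function(d) sqrt(mean((eval_d(d) - targets)^2))
  e_lo <- err(0); e_hi <- err(max_density)
  if (e_lo < e_hi) {
    warning("modeled response not monotone in density; falling back to grid search")
    rs <- vapply(0:max_density, rmse, numeric(1))
    d <- which.min(rs) - 1L
    return(list(density = d, rmse = rs[d + 1L], curve = eval_d(d)))
  }
  lo <- 0L; hi <- as.integer(max_density)
  if (e_lo <= 0) hi <- lo else if (e_hi >= 0) lo <- hi
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (err(mid) > 0) lo <- mid else hi <- mid
  }
  cand <- sort(unique(pmax(0L, pmin(as.integer(max_density),
                                    c(lo - 1L, lo, hi, hi + 1L)))))
  rs <- vapply(cand, rmse, numeric(1))
  best <- cand[which(rs == min(rs))[1]]  # ties to lower density
  list(density = best, rmse = min(rs), curve = eval_d(best))
}
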