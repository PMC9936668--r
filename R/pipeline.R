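# tiny FNV-1a hash of a serialized object, to tag outputs with their config
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Default end-to-end run configuration
#'
#' Seeds, grids and scale controls for [reproduce_trends()].  The defaults
#' run a reduced-scale but complete pipeline; `n_animals`, protocol length,
#' swarm size and run counts can be raised toward the full study scale.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_animals cohort size.
#' @param rate_grid,amplitudes factorial design grids.
#' @param protocol a [trial_protocol()] (a shortened protocol speeds the
#'   cohort stage; quantification windows scale with it).
#' @param noise_sd recording noise, mV.
#' @param surface a [response_surface()].
#' @param do_hr_model,do_pso,do_knockout stage switches.
#' @param hr_runs seeded repeats per HR-model condition.
#' @param hr_frequencies constant-frequency grid for density calibration.
#' @param pso list of swarm controls
#'   (`runs`, `n_particles`, `n_iter`, `stim_s`, `dt_ms`).
#' @return a named list of class `vnsim_config`.
#' @export
vnsim_config <- function(seed = 1, n_animals = 4,
                         rate_grid = c(2, 5, 10, 20, 30, 40, 50, 100),
                         amplitudes = c(0.8, 1.0, 1.2),
                         protocol = trial_protocol(6, 12, 4, 3),
                         noise_sd = 0.02, surface = response_surface(),
                         do_hr_model = TRUE, do_pso = TRUE,
                         do_knockout = TRUE, hr_runs = 2,
                         hr_frequencies = c(5, 20, 50),
                         pso = list(runs = 2, n_particles = 40, n_iter = 25,
                                    stim_s = 5, dt_ms = 0.5)) {
  structure(as.list(environment()), class = "vnsim_config")
}

#' Run the full reproduction pipeline on synthetic data
#'
#' Chains every stage of the package on generated data with known ground
#' truth: design enumeration, cohort synthesis and quantification,
#' effect-size partition, ACh-density calibration of the heart-rate model
#' per amplitude, the ganglion-filtering knockout comparison, and the swarm
#' fit of the muscle model to the quantified EMG.  Simulated/quantified
#' pairs are scored by the fraction of conditions whose modeled mean lies
#' within one standard deviation of the synthetic cohort mean.
#'
#' @param config a [vnsim_config()].
#' @return a report list; every element is reproducible from the config
#'   (the report carries `config_hash`).
#' @export
reproduce_trends <- function(config = vnsim_config()) {
  cfg <- config
  design <- enumerate_design(cfg$rate_grid, cfg$amplitudes)
  rows <- generate_cohort(cfg$n_animals, design, cfg$surface,
                          seed = .sub_seed(cfg$seed, "cohort"),
                          noise_sd = cfg$noise_sd, protocol = cfg$protocol,
                          process = function(rec, gt) {
                            q <- quantify_trial(rec)
                            q$target_hr_norm <- gt$target_hr_norm
                            q$target_emg_sum <- gt$target_emg_sum
                            q
                          })
  quantified <- quantify_cohort(do.call(rbind, rows))

  agg <- stats::aggregate(
    cbind(hr_norm, emg_norm, effect_score) ~ amplitude + frequency + mpr,
    data = quantified, FUN = mean)
  sds <- stats::aggregate(
    cbind(hr_norm, emg_norm) ~ amplitude + frequency + mpr,
    data = quantified, FUN = stats::sd)

  effects <- list(
    hr_norm = variance_partition(quantified, "hr_norm"),
    emg_norm = variance_partition(quantified, "emg_norm"),
    effect_score = variance_partition(quantified, "effect_score"))

  report <- list(design = design, quantified = quantified,
                 condition_means = agg, condition_sds = sds,
                 effects = effects)

  if (cfg$do_hr_model) {
    densities <- numeric(0)
    agreement <- NULL
    for (amp in cfg$amplitudes) {
      targ <- vapply(cfg$hr_frequencies, function(f)
        surface_hr_norm(cfg$surface, vns_condition(amp, f)), numeric(1))
      cal <- calibrate_density(targ, cfg$hr_frequencies,
                               n_runs = cfg$hr_runs,
                               seed = .sub_seed(cfg$seed, "cal"),
                               protocol = cfg$protocol)
      densities[as.character(amp)] <- cal$density
      sd_ref <- mean(sds$hr_norm[sds$frequency %in% cfg$hr_frequencies],
                     na.rm = TRUE)
      agreement <- rbind(agreement, data.frame(
        amplitude = amp, frequency = cfg$hr_frequencies,
        target = targ, model = cal$curve,
        within_1sd = abs(cal$curve - targ) <= sd_ref))
    }
    report$densities <- densities
    report$hr_agreement <- agreement
    report$hr_within_1sd <- mean(agreement$within_1sd)
  }

  if (cfg$do_knockout) {
    ko <- lapply(cfg$hr_frequencies, function(f) {
      cond <- vns_condition(1.0, f)
      on <- run_hr_trial(cond, 50, seed = .sub_seed(cfg$seed, "ko", f),
                         filtering = TRUE, protocol = cfg$protocol)$hr_norm
      off <- run_hr_trial(cond, 50, seed = .sub_seed(cfg$seed, "ko", f),
                          filtering = FALSE, protocol = cfg$protocol)$hr_norm
      data.frame(frequency = f, filtered = on, unfiltered = off)
    })
    report$knockout <- do.call(rbind, ko)
  }

  if (cfg$do_pso) {
    emg_targets <- stats::aggregate(emg_norm ~ frequency + mpr,
                                    data = quantified[quantified$amplitude == 1, ],
                                    FUN = mean)
    names(emg_targets)[3] <- "target"
    fit <- run_pso(emg_targets,
                   split_seed = .sub_seed(cfg$seed, "split"),
                   init_seed = .sub_seed(cfg$seed, "init"),
                   runs = cfg$pso$runs, n_particles = cfg$pso$n_particles,
                   n_neighborhoods = max(2, cfg$pso$n_particles %/% 5),
                   n_iter = cfg$pso$n_iter, stim_s = cfg$pso$stim_s,
                   dt_ms = cfg$pso$dt_ms)
    report$pso <- fit[c("params", "train_rmse", "test_rmse", "total_rmse",
                        "best_run")]
  }

  report$config_hash <- .config_hash(unclass(cfg))
  report
}

#' Write the tabular pieces of a report to disk
#'
#' CSV for data.frames, JSON for scalar summaries; every file name carries
#' the configuration hash.
#'
#' @param report result of [reproduce_trends()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- report$config_hash
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, sprintf("%s_%s.csv", name, h))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(report$quantified, "quantified"),
             wr(report$condition_means, "condition_means"))
  for (nm in names(report$effects))
    paths <- c(paths, wr(report$effects[[nm]], paste0("effects_", nm)))
  if (!is.null(report$knockout)) paths <- c(paths, wr(report$knockout, "knockout"))
  if (!is.null(report$hr_agreement)) paths <- c(paths, wr(report$hr_agreement, "hr_agreement"))
  summ <- list(config_hash = h,
               hr_within_1sd = report$hr_within_1sd,
               densities = as.list(report$densities),
               pso_total_rmse = report$pso$total_rmse)
  p <- file.path(dir, sprintf("summary_%s.json", h))
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, p))
}
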