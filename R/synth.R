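#' Ground-truth response surface of the synthetic-trial generator
#'
#' Encodes the condition-dependent bradycardia the generator embeds in each
#' trial: `HR_norm(amp, mpr, f) = 1 - A(amp) * S(mpr_eff)` with saturation
#' `S(x) = x / (x + m50)` and the effective pulse rate
#' `mpr_eff = mpr * transmission fraction` of the ganglion synapse for the
#' pattern (see [train_transmission_fraction()]), so the surface is monotone
#' decreasing in MPR and amplitude and increasing in intra-burst frequency
#' at fixed MPR.  Amplitude gains are interpolated linearly through
#' `(0, 0)` and the supplied anchor points and held constant beyond the last.
#'
#' @param gains named numeric vector of amplitude gains; names are
#'   amplitudes in xBCT.  Must be non-decreasing in amplitude.
#' @param m50 MPR half-saturation, pulses/s.
#' @param baseline_bpm resting heart rate, BPM.
#' @param rsa_depth fractional depth of the respiration-linked HR
#'   oscillation.
#' @param rsa_rate_bpm respiratory rate, breaths per minute.
#' @param transient_tau_s time constant of the HR transient at stimulation
#'   onset and offset, seconds.
#' @return object of class `response_surface`.
#' @export
response_surface <- function(gains = c("0.8" = 0.10, "1" = 0.25,
                                       "1.2" = 0.45),
                             m50 = 20, baseline_bpm = 450, rsa_depth = 0.03,
                             rsa_rate_bpm = 60, transient_tau_s = 1.5) {
  amps <- as.numeric(names(gains))
  stopifnot(!anyNA(amps), all(diff(amps) > 0), all(gains >= 0),
            all(gains <= 1), m50 > 0, baseline_bpm > 0, rsa_depth >= 0)
  if (is.unsorted(gains))
    stop("amplitude gains must be non-decreasing (monotone response surface)")
  structure(list(amps = c(0, amps), gains = c(0, unname(gains)), m50 = m50,
                 baseline_bpm = baseline_bpm, rsa_depth = rsa_depth,
                 rsa_rate_bpm = rsa_rate_bpm,
                 transient_tau_s = transient_tau_s),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "<response_surface> baseline %g BPM, m50 %g pulses/s, gains %s\n",
    x$baseline_bpm, x$m50,
    paste(sprintf("%g@%gxBCT", x$gains[-1], x$amps[-1]), collapse = ", ")))
  invisible(x)
}

.surface_gain <- function(surface, amplitude) {
  stats::approx(surface$amps, surface$gains, xout = amplitude, rule = 2)$y
}

#' Ground-truth normalized heart rate for a condition
#'
#' @param surface a [response_surface()].
#' @param condition a [vns_condition()].
#' @param train optional realized [pulse_train()]; when supplied the synapse
#'   transmission fraction is evaluated on its actual inter-pulse intervals
#'   (required for random patterns).
#' @return the target HR_norm in (0, 1\].
#' @export
surface_hr_norm <- function(surface, condition, train = NULL) {
  if (condition$amplitude <= 0 || condition$mpr <= 0) return(1)
  frac <- if (is.null(train)) transmission_fraction(condition$frequency)
    else train_transmission_fraction(train)
  mpr_eff <- condition$mpr * frac
  1 - .surface_gain(surface, condition$amplitude) *
    mpr_eff / (mpr_eff + surface$m50)
}

#' Laryngeal recruitment gain versus stimulation amplitude
#'
#' Logistic recruitment of the evoked EMG with onset near 0.4xBCT and
#' near-saturation at 0.8xBCT, rebased so zero amplitude gives exactly 0.
#'
#' @param amplitude amplitude in xBCT.
#' @param midpoint,scale logistic midpoint and scale in xBCT.
#' @return gain in \[0, 1).
#' @export
recruitment_gain <- function(amplitude, midpoint = 0.6, scale = 0.067) {
  l <- function(a) 1 / (1 + exp(-(a - midpoint) / scale))
  l0 <- l(0)
  ifelse(amplitude <= 0, 0, (l(amplitude) - l0) / (1 - l0))
}

# per-pulse fatigue factors for a pulse onset sequence: accumulated drive D
# recovers with tau_rec and each pulse adds 1; the factor is
# f_rec + (1 - f_rec) * exp(-D / k)
.fatigue_factors <- function(onsets, f_rec = 0.6, k = 100, tau_rec_s = 2) {
  n <- length(onsets)
  fac <- numeric(n)
  d <- 0; t_prev <- -Inf
  for (i in seq_len(n)) {
    if (is.finite(t_prev)) d <- d * exp(-(onsets[i] - t_prev) / tau_rec_s)
    fac[i] <- f_rec + (1 - f_rec) * exp(-d / k)
    d <- d + 1
    t_prev <- onsets[i]
  }
  fac
}

# sampled unit-peak biphasic wavelet of a given duration
.wave_samples <- function(duration_s, fs) {
  u <- seq(0, 1, length.out = max(2, round(duration_s * fs)))
  w <- sin(2 * pi * u) * sin(pi * u)^2
  w / max(abs(w))
}

# band-limited gaussian noise (10 Hz - 1 kHz), matching the acquisition
# band-pass applied to in vivo signals
.band_noise <- function(n, sd, fs) {
  if (sd <= 0) return(numeric(n))
  x <- stats::rnorm(n, sd = sd)
  bf <- signal::butter(2, c(10, 1000) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Generate one synthetic trial recording with ground truth
#'
#' Builds a two-channel 5 kHz recording of a VNS trial.  The ECG channel
#' places a QRS-like 8 ms biphasic wavelet at beat times produced by an
#' integrate-to-threshold process driven by the heart-rate trajectory
#' (baseline x respiratory sinus arrhythmia x surface response during
#' stimulation, with an exponential transient).  The EMG channel contains a
#' per-pulse stimulus artifact (0-1 ms, scaled by amplitude) plus an evoked
#' biphasic wave (1.5-6 ms post-pulse) whose amplitude follows the
#' recruitment gain and a high-rate fatigue decline.  Band-limited Gaussian
#' noise is added to both channels.  Fully reproducible given the seed.
#'
#' @param condition a [vns_condition()].
#' @param surface a [response_surface()].
#' @param noise_sd noise standard deviation, mV (0 for noiseless trials).
#' @param seed integer seed.
#' @param protocol a [trial_protocol()].
#' @param vagotomized logical; a distal vagotomy abolishes both the HR
#'   response and the evoked EMG while stimulus artifacts remain.
#' @param fs sampling rate, Hz.
#' @param animal_id identifier stored with the recording.
#' @param qrs_mv QRS peak amplitude, mV.
#' @param emg_mv evoked-EMG peak amplitude at full recruitment, mV.
#' @param artifact_mv stimulus-artifact peak amplitude per xBCT, mV.
#' @param fatigue list of fatigue-emulation parameters
#'   (`f_rec`, `k`, `tau_rec_s`).
#' @return list with `recording` (class `trial_recording`: `ecg`, `emg`,
#'   `fs`, `trigger_times`, `condition`, `protocol`, `animal_id`) and
#'   `ground_truth` (beat times, per-pulse evoked amplitudes, target HR_norm
#'   and EMG sum, vagotomy flag).
#' @export
generate_trial <- function(condition, surface = response_surface(),
                           noise_sd = 0.02, seed = 1,
                           protocol = trial_protocol(), vagotomized = FALSE,
                           fs = 5000, animal_id = "A1", qrs_mv = 1,
                           emg_mv = 0.5, artifact_mv = 2,
                           fatigue = list(f_rec = 0.6, k = 100,
                                          tau_rec_s = 2)) {
  stopifnot(noise_sd >= 0)
  n <- round(protocol$total_s * fs)
  tt <- (seq_len(n) - 1) / fs
  train <- if (condition$amplitude > 0)
    condition_train(condition, protocol) else NULL
  triggers <- if (is.null(train)) numeric(0) else train$onsets

  target_hrn <- if (vagotomized || is.null(train)) 1
    else surface_hr_norm(surface, condition, train)

  # heart-rate trajectory (BPM)
  sw <- protocol$stim_window; tau <- surface$transient_tau_s
  resp <- rep(1, n)
  if (target_hrn < 1) {
    during <- tt >= sw[1] & tt < sw[2]
    resp[during] <- 1 - (1 - target_hrn) *
      (1 - exp(-(tt[during] - sw[1]) / tau))
    after <- tt >= sw[2]
    depth_end <- (1 - target_hrn) * (1 - exp(-diff(sw) / tau))
    resp[after] <- 1 - depth_end * exp(-(tt[after] - sw[2]) / tau)
  }
  rsa <- 1 + surface$rsa_depth *
    sin(2 * pi * surface$rsa_rate_bpm / 60 * tt)
  hr_traj <- surface$baseline_bpm * rsa * resp

  # integrate-to-threshold beat times
  phase <- cumsum(hr_traj / 60) / fs
  k <- seq_len(floor(phase[n]))
  bidx <- findInterval(k, phase) # last sample with phase < k
  frac <- (k - phase[bidx]) / (phase[pmin(bidx + 1, n)] - phase[bidx] + 1e-12)
  beat_times <- tt[bidx] + frac / fs
  beat_times <- beat_times[beat_times > 0.004 & beat_times < protocol$total_s - 0.004]

  .with_seed(seed, {
    ecg <- .band_noise(n, noise_sd, fs)
    qrs_len <- round(0.008 * fs)
    qrs <- qrs_mv * .wave_samples(0.008, fs)
    peak_off <- which.max(qrs) - 1L
    for (bt in beat_times) {
      i0 <- round(bt * fs) + 1L - peak_off
      ii <- i0:(i0 + qrs_len - 1L)
      sel <- ii >= 1 & ii <= n
      ecg[ii[sel]] <- ecg[ii[sel]] + qrs[sel]
    }

    emg <- .band_noise(n, noise_sd, fs)
    per_pulse <- numeric(length(triggers))
    if (length(triggers)) {
      art <- condition$amplitude * artifact_mv * .wave_samples(0.001, fs)
      wave <- .wave_samples(0.0045, fs)
      wave_start <- round(0.0015 * fs)
      if (!vagotomized)
        per_pulse <- emg_mv * recruitment_gain(condition$amplitude) *
          .fatigue_factors(triggers, fatigue$f_rec, fatigue$k,
                           fatigue$tau_rec_s)
      for (j in seq_along(triggers)) {
        i0 <- round(triggers[j] * fs) + 1L
        ii <- i0:(i0 + length(art) - 1L)
        sel <- ii >= 1 & ii <= n
        emg[ii[sel]] <- emg[ii[sel]] + art[sel]
        if (per_pulse[j] > 0) {
          jj <- (i0 + wave_start):(i0 + wave_start + length(wave) - 1L)
          sel <- jj >= 1 & jj <= n
          emg[jj[sel]] <- emg[jj[sel]] + per_pulse[j] * wave[sel]
        }
      }
    }

    recording <- structure(
      list(ecg = ecg, emg = emg, fs = fs, trigger_times = triggers,
           condition = condition, protocol = protocol,
           animal_id = animal_id),
      class = "trial_recording")
    ground_truth <- list(beat_times = beat_times, hr_trajectory = hr_traj,
                         per_pulse_emg_amplitude = per_pulse,
                         target_hr_norm = target_hrn,
                         target_emg_sum = sum(per_pulse),
                         vagotomized = vagotomized)
    list(recording = recording, ground_truth = ground_truth)
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> animal %s, %g s at %g Hz, %d pulses (%s %g Hz / %g pps, %.2g xBCT)\n",
    x$animal_id, x$protocol$total_s, x$fs, length(x$trigger_times),
    x$condition$pattern, x$condition$frequency, x$condition$mpr,
    x$condition$amplitude))
  invisible(x)
}

#' Generate a synthetic cohort across a design
#'
#' One trial per animal and design row, with per-animal randomized condition
#' order and per-animal log-normal jitter of the surface gains and EMG scale
#' (the "animal" factor).  Ground truth is retained per trial.  A `process`
#' callback (e.g. [quantify_trial()] on the recording) can reduce each trial
#' as it is generated, so full raw traces need not be held in memory.
#'
#' @param n_animals number of animals (>= 1).
#' @param design data.frame as from [enumerate_design()].
#' @param surface a [response_surface()].
#' @param seed integer seed.
#' @param animal_sigma log-normal sigma of the per-animal gain jitter.
#' @param emg_sigma log-normal sigma of the per-animal EMG scale.
#' @param noise_sd,protocol,vagotomized,... passed to [generate_trial()].
#' @param process optional `function(recording, ground_truth)`; its value is
#'   stored instead of the raw trial.
#' @return list of per-trial results plus attributes `animals` (per-animal
#'   surfaces/scales) and `order` (per-animal condition order).
#' @export
generate_cohort <- function(n_animals, design, surface = response_surface(),
                            seed = 1, animal_sigma = 0.15, emg_sigma = 0.2,
                            noise_sd = 0.02, protocol = trial_protocol(),
                            vagotomized = FALSE, process = NULL, ...) {
  stopifnot(n_animals >= 1)
  if (!nrow(design)) stop("empty design")
  animals <- .with_seed(.sub_seed(seed, "animals"), {
    lapply(seq_len(n_animals), function(a) {
      g <- surface$gains[-1] * exp(stats::rnorm(1, 0, animal_sigma))
      g <- pmin(g, 0.99)
      s <- surface
      s$gains <- c(0, g)
      list(surface = s,
           emg_scale = 0.5 * exp(stats::rnorm(1, 0, emg_sigma)))
    })
  })
  orders <- .with_seed(.sub_seed(seed, "orders"),
                       lapply(seq_len(n_animals),
                              function(a) sample.int(nrow(design))))
  out <- vector("list", n_animals * nrow(design))
  k <- 0
  for (a in seq_len(n_animals)) {
    for (row in orders[[a]]) {
      d <- design[row, ]
      cond <- vns_condition(d$amplitude, d$frequency, d$mpr,
                            pattern = d$pattern,
                            seed = if (d$pattern == "random")
                              .sub_seed(seed, "rpat", a) else NULL)
      tr <- generate_trial(cond, animals[[a]]$surface, noise_sd = noise_sd,
                           seed = .sub_seed(seed, "trial", a * 1000 + row),
                           protocol = protocol, vagotomized = vagotomized,
                           animal_id = sprintf("A%02d", a),
                           emg_mv = animals[[a]]$emg_scale, ...)
      k <- k + 1
      out[[k]] <- if (is.null(process)) tr
        else process(tr$recording, tr$ground_truth)
    }
  }
  attr(out, "animals") <- animals
  attr(out, "order") <- orders
  out
}

#' Generate a constant/random/constant session
#'
#' Three trials at 1.0xBCT: constant frequency at the MPR (C1), a random
#' pattern at the same MPR (R), then constant frequency again (C2).
#'
#' @param mpr mean pulse rate, pulses/s (the design used 10 and 20).
#' @param seed integer seed.
#' @param surface a [response_surface()].
#' @param ... passed to [generate_trial()].
#' @return named list of three `(recording, ground_truth)` pairs
#'   (`C1`, `R`, `C2`).
#' @export
generate_random_session <- function(mpr, seed, surface = response_surface(),
                                    ...) {
  conds <- list(
    C1 = vns_condition(1.0, mpr),
    R = vns_condition(1.0, frequency = 1000, mpr = mpr, pattern = "random",
                      seed = .sub_seed(seed, "rand")),
    C2 = vns_condition(1.0, mpr))
  out <- lapply(seq_along(conds), function(i)
    generate_trial(conds[[i]], surface,
                   seed = .sub_seed(seed, "session", i), ...))
  names(out) <- names(conds)
  out
}
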