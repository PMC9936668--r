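#' Detect QRS peaks in an ECG trace
#'
#' Positive QRS peaks found with an adaptive threshold (half the rolling 2 s
#' maximum of the trace) and a 50 ms refractory period.  A flat or all-zero
#' trace yields no beats.
#'
#' @param ecg numeric ECG samples, mV.
#' @param fs sampling rate, Hz.
#' @param refractory_s minimum spacing between accepted peaks, seconds.
#' @param threshold_frac fraction of the rolling maximum used as threshold.
#' @param window_s rolling-maximum window, seconds.
#' @return beat times in seconds.
#' @export
detect_beats <- function(ecg, fs = 5000, refractory_s = 0.05,
                         threshold_frac = 0.5, window_s = 2) {
  stopifnot(all(is.finite(ecg)))
  n <- length(ecg)
  if (n < 3 || max(ecg) <= 0) return(numeric(0))
  thr <- threshold_frac * .running_max_c(ecg, as.integer(round(window_s * fs)))
  x <- ecg
  cand <- which(x[-c(1, n)] > x[-c(n - 1, n)] & x[-c(1, n)] >= x[-c(1, 2)]) + 1L
  cand <- cand[x[cand] > thr[cand] & x[cand] > 0]
  if (!length(cand)) return(numeric(0))
  refr <- refractory_s * fs
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refr) {
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  (cand[keep] - 1) / fs
}

#' Instantaneous heart rate and normalized HR of a trial
#'
#' Instantaneous HR is derived from inter-beat (inter-QRS) intervals: each
#' interval contributes `60/RR` BPM at its midpoint, and the series value at
#' time `t` averages contributions whose midpoints fall within a centered
#' 0.5 s window (series stored at 1 ms steps).  `hr_baseline` averages the
#' series over the baseline window, `hr_stim` over the analysis window
#' (stimulation excluding the initial transient), and
#' `hr_norm = hr_stim / hr_baseline`; values below 1 indicate bradycardia.
#'
#' @param beats beat times in seconds.
#' @param protocol a [trial_protocol()].
#' @param window_s sliding window width, seconds.
#' @param step_s series step, seconds.
#' @return list with `hr_baseline`, `hr_stim`, `hr_norm`, `series`
#'   (data.frame `time`, `bpm`), and `valid` (FALSE when either analysis
#'   window lacks at least two beats).
#' @export
hr_metrics <- function(beats, protocol = trial_protocol(), window_s = 0.5,
                       step_s = 1e-3) {
  if (length(beats) >= 2) {
    rr <- diff(beats)
    mids <- beats[-length(beats)] + rr / 2
    rates <- 60 / rr
  } else {
    mids <- rates <- numeric(0)
  }
  ser <- .rate_series(mids, rates, protocol$total_s, window_s, step_s)
  bw <- protocol$baseline_window; aw <- protocol$analysis_window
  in_base <- beats >= bw[1] & beats < bw[2]
  in_stim <- beats >= aw[1] & beats < aw[2]
  valid <- sum(in_base) >= 2 && sum(in_stim) >= 2
  bsel <- ser$time >= bw[1] & ser$time < bw[2] & !is.na(ser$bpm)
  ssel <- ser$time >= aw[1] & ser$time < aw[2] & !is.na(ser$bpm)
  hr_baseline <- if (any(bsel)) mean(ser$bpm[bsel]) else NA_real_
  hr_stim <- if (any(ssel)) mean(ser$bpm[ssel]) else NA_real_
  list(hr_baseline = hr_baseline, hr_stim = hr_stim,
       hr_norm = hr_stim / hr_baseline, series = ser, valid = valid)
}

#' Remove stimulus artifacts from an EMG trace by template subtraction
#'
#' The template is the pulse-averaged signal from 1 ms before to 1 ms after
#' each stimulus trigger; it is subtracted at every trigger.  Samples outside
#' the peri-trigger windows are untouched.  When triggers are closer than the
#' window (inter-pulse interval < 2 ms) windows are truncated at the midpoint
#' between triggers, with a warning.
#'
#' @param emg numeric EMG samples, mV.
#' @param triggers stimulus trigger times, seconds.
#' @param fs sampling rate, Hz.
#' @param window_s template window around the trigger, seconds.
#' @return the cleaned EMG trace.
#' @export
subtract_artifact <- function(emg, triggers, fs = 5000,
                              window_s = c(-1e-3, 1e-3)) {
  if (!length(triggers)) stop("at least one trigger is required")
  n <- length(emg)
  idx0 <- round(triggers * fs) + 1L
  if (any(idx0 < 1 | idx0 > n)) stop("triggers outside the trace")
  rel <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  seg_idx <- outer(idx0, rel, `+`)
  ok <- seg_idx >= 1 & seg_idx <= n
  seg <- matrix(0, nrow(seg_idx), ncol(seg_idx))
  seg[ok] <- emg[seg_idx[ok]]
  # truncate overlapping windows at the midpoint between triggers
  if (length(triggers) > 1 && any(diff(triggers) < diff(window_s))) {
    warning("overlapping artifact windows truncated at trigger midpoints")
    lim_hi <- c((idx0[-1] + idx0[-length(idx0)]) %/% 2, n)
    lim_lo <- c(1L, lim_hi[-length(lim_hi)] + 1L)
    ok <- ok & seg_idx >= lim_lo & seg_idx <= lim_hi
  }
  template <- colSums(seg * ok) / pmax(colSums(ok), 1)
  cleaned <- emg
  sub <- matrix(rep(template, each = nrow(seg_idx)), nrow(seg_idx))
  cleaned[seg_idx[ok]] <- cleaned[seg_idx[ok]] - sub[ok]
  cleaned
}

#' Per-pulse average rectified EMG and trial sum
#'
#' For each stimulus pulse, the average rectified value (ARV) of the cleaned
#' EMG over a post-pulse window (default 1 to 6 ms; the upper edge is
#' configurable up to 8 ms depending on the evoked waveform).  `emg_sum` is
#' the ARV summed over all pulses of the trial.
#'
#' @param emg cleaned EMG samples, mV.
#' @param triggers pulse trigger times, seconds.
#' @param fs sampling rate, Hz.
#' @param window_s post-pulse analysis window `(start, end)`, seconds.
#' @return list with `emg_arv` (per pulse, mV) and `emg_sum`.
#' @export
emg_quantify <- function(emg, triggers, fs = 5000,
                         window_s = c(1e-3, 6e-3)) {
  stopifnot(length(triggers) >= 1, window_s[2] > window_s[1])
  n <- length(emg)
  rel <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  idx <- outer(round(triggers * fs) + 1L, rel, `+`)
  if (any(idx > n)) {
    warning("analysis window extends past the trace end; truncated")
  }
  ok <- idx >= 1 & idx <= n
  vals <- matrix(0, nrow(idx), ncol(idx))
  vals[ok] <- abs(emg[idx[ok]])
  arv <- rowSums(vals) / pmax(rowSums(ok), 1)
  list(emg_arv = arv, emg_sum = sum(arv))
}

#' Normalize a trial's summed EMG to the animal's reference response
#'
#' The reference is the summed per-pulse ARV of that animal's 1.0xBCT, 20 Hz
#' constant-frequency trial; the reference trial itself maps to exactly 1.
#'
#' @param emg_sum summed ARV of the trial.
#' @param reference_sum summed ARV of the reference trial (> 0).
#' @return normalized EMG (dimensionless).
#' @export
normalize_emg <- function(emg_sum, reference_sum) {
  if (!is.finite(reference_sum) || reference_sum <= 0)
    stop("reference EMG sum must be positive; animal cannot be normalized")
  emg_sum / reference_sum
}

#' Effect score balancing heart-rate and muscle responses
#'
#' `score = (1 - hr_norm) / (1 - hr_norm_ref) - emg_norm`.  Positive scores
#' indicate a relatively larger heart-rate (therapeutic proxy) response,
#' negative scores a larger muscle (side-effect proxy) response; the
#' reference condition itself scores exactly 0.
#'
#' @param hr_norm normalized heart rate of the trial.
#' @param hr_norm_ref normalized heart rate of the reference condition
#'   (must show bradycardia, i.e. be < 1).
#' @param emg_norm normalized EMG of the trial.
#' @return the effect score.
#' @export
effect_score <- function(hr_norm, hr_norm_ref, emg_norm) {
  if (any(hr_norm_ref >= 1))
    stop("reference hr_norm must be < 1 (reference must show bradycardia)")
  (1 - hr_norm) / (1 - hr_norm_ref) - emg_norm
}

#' Quantify a single synthetic trial recording
#'
#' Runs the full per-trial pipeline: beat detection, HR metrics, artifact
#' subtraction, and per-pulse EMG quantification.
#'
#' @param rec a `trial_recording` (see [generate_trial()]).
#' @param emg_window_s post-pulse EMG analysis window, seconds.
#' @return one-row data.frame with condition fields, HR metrics, `emg_sum`
#'   and `valid`.
#' @export
quantify_trial <- function(rec, emg_window_s = c(1e-3, 6e-3)) {
  beats <- detect_beats(rec$ecg, rec$fs)
  hr <- hr_metrics(beats, rec$protocol)
  if (length(rec$trigger_times)) {
    cleaned <- subtract_artifact(rec$emg, rec$trigger_times, rec$fs)
    em <- emg_quantify(cleaned, rec$trigger_times, rec$fs, emg_window_s)
    emg_sum <- em$emg_sum
  } else {
    emg_sum <- 0
  }
  cond <- rec$condition
  data.frame(animal = rec$animal_id, amplitude = cond$amplitude,
             frequency = cond$frequency, mpr = cond$mpr,
             pattern = cond$pattern,
             hr_baseline = hr$hr_baseline, hr_stim = hr$hr_stim,
             hr_norm = hr$hr_norm, emg_sum = emg_sum,
             valid = hr$valid, stringsAsFactors = FALSE)
}

#' Quantify a cohort of trials and derive normalized outcomes
#'
#' Applies per-animal EMG normalization (reference: the 1.0xBCT, 20 Hz
#' constant trial) and computes effect scores against the same reference.
#' Trials flagged invalid are excluded.
#'
#' @param rows data.frame of per-trial quantities as returned by
#'   [quantify_trial()] (one row per trial).
#' @param reference optional named numeric vector of per-animal reference
#'   EMG sums (names = animal ids); when `NULL` the references are taken
#'   from each animal's own reference trial.  Supplying pre-lesion
#'   references supports vagotomy analyses.
#' @param ref_amplitude,ref_frequency the reference condition.
#' @return the input rows (valid only) with `emg_norm` and `effect_score`
#'   columns added.
#' @export
quantify_cohort <- function(rows, reference = NULL, ref_amplitude = 1.0,
                            ref_frequency = 20) {
  rows <- rows[rows$valid, , drop = FALSE]
  out <- NULL
  for (an in unique(rows$animal)) {
    sub <- rows[rows$animal == an, , drop = FALSE]
    is_ref <- sub$pattern == "constant" & sub$amplitude == ref_amplitude &
      sub$frequency == ref_frequency
    ref_sum <- if (!is.null(reference)) reference[[as.character(an)]]
      else if (any(is_ref)) sub$emg_sum[is_ref][1] else NA_real_
    ref_hrn <- if (any(is_ref)) sub$hr_norm[is_ref][1] else NA_real_
    sub$emg_norm <- if (is.finite(ref_sum) && ref_sum > 0)
      sub$emg_sum / ref_sum else NA_real_
    sub$effect_score <- if (is.finite(ref_hrn) && ref_hrn < 1)
      effect_score(sub$hr_norm, ref_hrn, sub$emg_norm) else NA_real_
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out
}
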