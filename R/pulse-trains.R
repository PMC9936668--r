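#' Timed biphasic stimulation pulse train
#'
#' The common currency of every model in the package: an ordered set of pulse
#' onset times within a stimulation window, delivered as symmetric biphasic
#' charge-balanced pulses (300 us per phase by default), with amplitude
#' expressed as a multiple of the bradycardia threshold (BCT).
#'
#' @param onsets numeric vector of pulse onset times in seconds from trial
#'   start, strictly increasing.
#' @param window length-2 numeric, start and end of the stimulation window in
#'   seconds; all onsets must lie within it.
#' @param amplitude stimulation amplitude as a multiple of BCT.
#' @param phase_width_s single phase width in seconds.
#' @param amplitude_ma optional absolute amplitude in mA (metadata only).
#' @param polarity `"cathode-leading"` or `"anode-leading"`.
#' @return an object of class `pulse_train`.
#' @export
pulse_train <- function(onsets, window, amplitude = 1,
                        phase_width_s = 300e-6, amplitude_ma = NA_real_,
                        polarity = c("cathode-leading", "anode-leading")) {
  polarity <- match.arg(polarity)
  onsets <- as.numeric(onsets)
  stopifnot(length(window) == 2, window[2] > window[1], amplitude >= 0,
            phase_width_s > 0)
  if (length(onsets) > 1) {
    ipi <- diff(onsets)
    if (any(ipi <= 0))
      stop("pulse onsets must be strictly increasing")
    if (any(ipi < 2 * phase_width_s))
      stop("inter-pulse interval shorter than the pulse duration (2 phases)")
  }
  if (length(onsets) && (min(onsets) < window[1] || max(onsets) >= window[2]))
    stop("pulse onsets must lie within the stimulation window")
  structure(list(onsets = onsets, window = window, amplitude = amplitude,
                 phase_width_s = phase_width_s, amplitude_ma = amplitude_ma,
                 polarity = polarity),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses in [%g, %g) s, %.2g xBCT, %g us/phase\n",
              length(x$onsets), x$window[1], x$window[2], x$amplitude,
              x$phase_width_s * 1e6))
  invisible(x)
}

#' Trial timing protocol
#'
#' Trials run baseline / stimulation / recovery epochs back to back; heart
#' rate during stimulation is analyzed only after an initial transient
#' offset.  Defaults give the 70 s protocol (10 s baseline, 30 s stimulation,
#' 30 s recovery, 5 s analysis offset).
#'
#' @param baseline_s,stim_s,recovery_s epoch durations in seconds.
#' @param analysis_offset_s seconds of stimulation excluded from analysis to
#'   skip the transient heart-rate response.
#' @return an object of class `trial_protocol` with derived windows:
#'   `stim_window`, `baseline_window`, `analysis_window`, `total_s`.
#' @export
trial_protocol <- function(baseline_s = 10, stim_s = 30, recovery_s = 30,
                           analysis_offset_s = 5) {
  stopifnot(baseline_s > 0, stim_s > 0, recovery_s >= 0,
            analysis_offset_s >= 0, analysis_offset_s < stim_s)
  structure(list(
    baseline_s = baseline_s, stim_s = stim_s, recovery_s = recovery_s,
    analysis_offset_s = analysis_offset_s,
    total_s = baseline_s + stim_s + recovery_s,
    baseline_window = c(0, baseline_s),
    stim_window = c(baseline_s, baseline_s + stim_s),
    analysis_window = c(baseline_s + analysis_offset_s, baseline_s + stim_s)),
    class = "trial_protocol")
}

#' Stimulation condition
#'
#' A point in the factorial design: amplitude (xBCT), intra-burst frequency,
#' mean pulse rate (MPR, pulses per 1 s epoch), and pattern kind.
#'
#' @param amplitude multiple of BCT.
#' @param frequency intra-burst frequency, Hz.
#' @param mpr mean pulse rate, pulses per second; must not exceed `frequency`.
#' @param pattern one of `"constant"`, `"burst"`, `"random"`, `"duty50"`.
#' @param seed integer seed, required for random patterns.
#' @return an object of class `vns_condition`.
#' @export
vns_condition <- function(amplitude, frequency, mpr = frequency,
                          pattern = c("constant", "burst", "random", "duty50"),
                          seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(amplitude >= 0, frequency > 0, mpr > 0)
  if (mpr > frequency)
    stop("mean pulse rate cannot exceed the intra-burst frequency")
  if (pattern == "constant" && mpr != frequency)
    stop("constant patterns require mpr == frequency")
  if (pattern == "random" && is.null(seed))
    stop("random patterns require a seed")
  structure(list(amplitude = amplitude, frequency = frequency, mpr = mpr,
                 pattern = pattern, seed = seed),
            class = "vns_condition")
}

#' @export
print.vns_condition <- function(x, ...) {
  cat(sprintf("<vns_condition> %s, %g Hz / %g pulses/s at %.2g xBCT\n",
              x$pattern, x$frequency, x$mpr, x$amplitude))
  invisible(x)
}

#' Build the pulse train realizing a condition
#'
#' @param condition a [vns_condition()].
#' @param protocol a [trial_protocol()]; the train fills its stimulation
#'   window.
#' @return a [pulse_train()].
#' @export
condition_train <- function(condition, protocol = trial_protocol()) {
  w <- protocol$stim_window
  switch(condition$pattern,
    constant = make_constant_train(condition$frequency, w,
                                   amplitude = condition$amplitude),
    burst = make_burst_train(condition$frequency, condition$mpr, w,
                             amplitude = condition$amplitude),
    random = make_random_train(condition$mpr, condition$seed, w,
                               amplitude = condition$amplitude),
    duty50 = make_duty50_train(condition$mpr, w,
                               amplitude = condition$amplitude))
}

#' Constant-frequency pulse train
#'
#' Pulses at uniform spacing `1/frequency` starting at the window onset;
#' `floor(frequency * duration)` pulses in total.
#'
#' @param frequency pulse rate in Hz.
#' @param window length-2 stimulation window in seconds.
#' @param amplitude multiple of BCT.
#' @param phase_width_s phase width in seconds.
#' @return a [pulse_train()].
#' @export
make_constant_train <- function(frequency, window, amplitude = 1,
                                phase_width_s = 300e-6) {
  stopifnot(frequency > 0)
  if (frequency > 1 / (2 * phase_width_s))
    stop("frequency too high: inter-pulse interval shorter than the pulse")
  dur <- window[2] - window[1]
  n <- floor(frequency * dur)
  onsets <- window[1] + (seq_len(n) - 1) / frequency
  pulse_train(onsets, window, amplitude, phase_width_s)
}

#' Burst-patterned pulse train
#'
#' Concatenated 1 s epochs; each epoch opens with `mpr` pulses at the
#' intra-burst spacing `1/frequency` followed by silence to the epoch end.
#' With `mpr == frequency` this degenerates to the constant train.
#'
#' @param frequency intra-burst frequency, Hz.
#' @param mpr pulses per 1 s epoch.
#' @inheritParams make_constant_train
#' @return a [pulse_train()].
#' @export
make_burst_train <- function(frequency, mpr, window, amplitude = 1,
                             phase_width_s = 300e-6) {
  stopifnot(frequency > 0, mpr > 0)
  if (mpr > frequency)
    stop("mpr exceeds the intra-burst frequency: not a valid burst")
  if ((mpr - 1) / frequency >= 1)
    stop("burst of ", mpr, " pulses at ", frequency, " Hz does not fit in 1 s")
  n_epochs <- floor(window[2] - window[1])
  epoch <- (seq_len(mpr) - 1) / frequency
  onsets <- rep(window[1] + seq_len(n_epochs) - 1, each = mpr) + epoch
  pulse_train(onsets, window, amplitude, phase_width_s)
}

#' Random-pattern pulse train
#'
#' One 1 s epoch of `mpr` uniformly random pulse onsets (1 ms minimum
#' inter-pulse interval enforced by rejection sampling), tiled across the
#' stimulation window so every epoch repeats the same pattern.  Reproducible
#' from the seed.
#'
#' @param mpr pulses per 1 s epoch.
#' @param seed integer seed for the epoch draw.
#' @inheritParams make_constant_train
#' @param min_ipi_s minimum inter-pulse interval within the epoch, seconds.
#' @return a [pulse_train()].
#' @export
make_random_train <- function(mpr, seed, window, amplitude = 1,
                              phase_width_s = 300e-6, min_ipi_s = 1e-3) {
  stopifnot(mpr >= 1, mpr * min_ipi_s < 1)
  epoch <- local({
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    repeat {
      x <- sort(stats::runif(mpr, 0, 1 - min_ipi_s))
      if (mpr == 1 || all(diff(x) >= min_ipi_s)) return(x)
    }
  })
  n_epochs <- floor(window[2] - window[1])
  onsets <- rep(window[1] + seq_len(n_epochs) - 1, each = mpr) + epoch
  pulse_train(onsets, window, amplitude, phase_width_s)
}

#' 50 percent duty-cycle pulse train
#'
#' Each 1 s epoch holds `mpr` pulses compressed into its first 0.5 s at
#' spacing `0.5/mpr` s, followed by a 0.5 s pause.
#'
#' @inheritParams make_random_train
#' @return a [pulse_train()].
#' @export
make_duty50_train <- function(mpr, window, amplitude = 1,
                              phase_width_s = 300e-6) {
  stopifnot(mpr >= 1)
  if (0.5 / mpr < 2 * phase_width_s)
    stop("mpr too high for a 0.5 s burst of non-overlapping pulses")
  n_epochs <- floor(window[2] - window[1])
  epoch <- (seq_len(mpr) - 1) * 0.5 / mpr
  onsets <- rep(window[1] + seq_len(n_epochs) - 1, each = mpr) + epoch
  pulse_train(onsets, window, amplitude, phase_width_s)
}

#' Enumerate the factorial stimulation design
#'
#' All (intra-burst frequency, MPR) pairs with MPR <= frequency from the rate
#' grid, crossed with the amplitude grid.  Pairs with MPR == frequency are
#' constant-frequency patterns; the defaults give the 8 constant + 28 burst =
#' 36 temporal patterns and 108 amplitude-by-pattern conditions.
#'
#' @param rate_grid distinct rates in Hz (used both as intra-burst frequencies
#'   and MPRs).
#' @param amplitudes distinct amplitudes in xBCT.
#' @return a data.frame with columns `amplitude`, `frequency`, `mpr`,
#'   `pattern`.
#' @export
enumerate_design <- function(rate_grid = c(2, 5, 10, 20, 30, 40, 50, 100),
                             amplitudes = c(0.8, 1.0, 1.2)) {
  if (anyDuplicated(rate_grid)) stop("duplicate values in rate_grid")
  if (anyDuplicated(amplitudes)) stop("duplicate values in amplitudes")
  rate_grid <- sort(rate_grid)
  pairs <- expand.grid(mpr = rate_grid, frequency = rate_grid)
  pairs <- pairs[pairs$mpr <= pairs$frequency, ]
  out <- merge(data.frame(amplitude = amplitudes), pairs)
  out$pattern <- ifelse(out$mpr == out$frequency, "constant", "burst")
  out <- out[order(out$amplitude, out$frequency, out$mpr),
             c("amplitude", "frequency", "mpr", "pattern")]
  rownames(out) <- NULL
  out
}

#' Inter-pulse frequency statistics of a train
#'
#' Arithmetic and geometric means of the reciprocals of successive
#' inter-pulse intervals.
#'
#' @param train a [pulse_train()] with at least 2 pulses.
#' @return list with `mean_ipf` and `geom_mean_ipf`, in Hz.
#' @export
pattern_stats <- function(train) {
  if (length(train$onsets) < 2)
    stop("at least 2 pulses are required for inter-pulse statistics")
  ipf <- 1 / diff(train$onsets)
  list(mean_ipf = mean(ipf), geom_mean_ipf = exp(mean(log(ipf))))
}
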