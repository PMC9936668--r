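#' Frequency-dependent transmission probability of the vagal-to-ganglion synapse
#'
#' Probability that a preganglionic action potential triggers a postganglionic
#' event in an intrinsic cardiac nervous system (ICNS) cell, as a function of
#' the time since that cell's previous event:
#' `p(dt) = 1.028 - 2.183 * dt^-0.7146`, clamped to \[0, 1\] (`dt` in ms).
#' Short intervals transmit rarely; beyond roughly 444 ms every pulse
#' transmits.
#'
#' @param dt_ms time since the previous postganglionic event, in ms (> 0).
#' @param a,b,cc curve coefficients.
#' @return transmission probability in \[0, 1\], vectorized over `dt_ms`.
#' @export
success_probability <- function(dt_ms, a = 1.028, b = 2.183, cc = 0.7146) {
  if (any(dt_ms <= 0)) stop("dt_ms must be positive")
  pmin(pmax(a - b * dt_ms^(-cc), 0), 1)
}

#' Steady-state transmission fraction at a constant pulse interval
#'
#' Fraction of pulses transmitted by the ganglion synapse when pulses arrive
#' at a fixed rate, computed from the renewal process implied by
#' [success_probability()]: after each transmitted event the interval clock
#' resets, so the expected number of pulses per transmitted event is
#' `E[K] = sum_k k p_k prod_{j<k}(1 - p_j)` with `p_k = p(k/f)`.
#'
#' @param frequency_hz pulse rate, Hz.
#' @param max_terms series truncation (transmission probability clamps to 1
#'   well before this for all practical rates).
#' @return expected transmitted fraction in (0, 1\].
#' @export
transmission_fraction <- function(frequency_hz, max_terms = 1000) {
  stopifnot(all(frequency_hz > 0))
  vapply(frequency_hz, function(f) {
    k <- seq_len(max_terms)
    p <- success_probability(1000 * k / f)
    surv <- cumprod(1 - p)
    prob_k <- p * c(1, surv[-max_terms])
    ek <- sum(k * prob_k)
    # tail mass (pulses beyond max_terms) is negligible once p reaches 1
    1 / ek
  }, numeric(1))
}

#' Expected transmission fraction of an arbitrary pulse train
#'
#' Exact expectation of the transmitted fraction for a specific pulse-onset
#' sequence, by dynamic programming over the identity of the last transmitted
#' pulse.  For constant-frequency trains this converges to
#' [transmission_fraction()]; for random patterns it evaluates the synapse on
#' the realized inter-pulse intervals.
#'
#' @param train a [pulse_train()].
#' @param max_pulses cap on the number of pulses used (the per-pulse success
#'   probabilities reach periodic steady state within a few epochs).
#' @return expected transmitted fraction in (0, 1\].
#' @export
train_transmission_fraction <- function(train, max_pulses = 1500) {
  t_ms <- (train$onsets - train$onsets[1]) * 1000
  n <- min(length(t_ms), max_pulses)
  if (n < 1) stop("empty train")
  t_ms <- t_ms[seq_len(n)]
  # q[j]: probability the last transmitted event was pulse j (j = 0 encodes
  # "none yet", treated as infinitely long ago -> certain transmission)
  q <- numeric(n + 1)
  q[1] <- 1
  succ <- numeric(n)
  for (i in seq_len(n)) {
    p <- c(1, success_probability(pmax(t_ms[i] - t_ms[seq_len(i - 1)], 1e-9)))
    active <- seq_len(i)
    s <- sum(q[active] * p)
    q[active] <- q[active] * (1 - p)
    q[i + 1] <- s
    succ[i] <- s
  }
  mean(succ)
}

# phasic intrinsic ICNS rate profile: half-sine over each respiratory cycle,
# peaking at `peak` events per 50 ms bin
.intrinsic_rate <- function(t_s, peak = 0.6, resp_period_s = 1) {
  phase <- (t_s %% resp_period_s) / resp_period_s
  peak * sin(pi * phase)
}

#' Simulate the ICNS postganglionic cell population
#'
#' Each of `n_cells` phenomenological postganglionic cells receives the shared
#' preganglionic pulse train.  A pulse is transmitted when a uniform draw
#' falls below [success_probability()] evaluated at the time since the cell's
#' last event (stimulus-evoked or intrinsic); every event resets that clock.
#' Half of the cells additionally fire intrinsically: a Bernoulli draw per
#' 50 ms bin at a phasic, respiration-linked rate (half-sine over each 1 s
#' cycle, peak 0.6 events/bin).  With `filtering = FALSE` the synapse is
#' bypassed and every pulse is an event in every cell.
#'
#' @param train a [pulse_train()] (may be `NULL` for no stimulation).
#' @param duration_s simulation length in seconds.
#' @param seed integer seed; the simulation is reproducible given the seed.
#' @param filtering logical; `FALSE` removes the frequency-dependent synaptic
#'   filtering so each pulse causes an event.
#' @param n_cells number of postganglionic cells.
#' @param intrinsic_cells integer indices of intrinsically firing cells; by
#'   default a seeded random half of the population.
#' @param intrinsic_peak peak intrinsic rate, events per 50 ms bin.
#' @param resp_period_s respiratory cycle length, seconds.
#' @return list with per-cell numeric vectors `stim_events` and
#'   `intrinsic_events` (times in seconds) and the `intrinsic_cells` indices.
#' @export
simulate_icns <- function(train, duration_s, seed, filtering = TRUE,
                          n_cells = 100, intrinsic_cells = NULL,
                          intrinsic_peak = 0.6, resp_period_s = 1) {
  pulses <- if (is.null(train)) numeric(0) else train$onsets
  .with_seed(seed, {
    if (is.null(intrinsic_cells))
      intrinsic_cells <- sort(sample.int(n_cells, n_cells %/% 2))
    bin_w <- 0.05
    bins <- seq(0, duration_s - bin_w, by = bin_w)
    rate <- .intrinsic_rate(bins + bin_w / 2, intrinsic_peak, resp_period_s)
    stim_events <- vector("list", n_cells)
    intr_events <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      intr <- numeric(0)
      if (cell %in% intrinsic_cells) {
        fire <- stats::runif(length(bins)) < rate
        intr <- bins[fire] + stats::runif(sum(fire)) * bin_w
      }
      if (length(pulses) && !filtering) {
        stim_events[[cell]] <- pulses
        intr_events[[cell]] <- intr
        next
      }
      ev_t <- c(pulses, intr)
      ev_kind <- rep(c(TRUE, FALSE), c(length(pulses), length(intr)))
      o <- order(ev_t)
      ev_t <- ev_t[o]; ev_kind <- ev_kind[o]
      u <- stats::runif(length(ev_t))
      t0 <- -1e9
      keep <- logical(length(ev_t))
      for (k in seq_along(ev_t)) {
        if (ev_kind[k]) {
          p <- success_probability(max((ev_t[k] - t0) * 1000, 1e-9))
          if (u[k] < p) {
            keep[k] <- TRUE
            t0 <- ev_t[k]
          }
        } else {
          keep[k] <- TRUE
          t0 <- ev_t[k]
        }
      }
      stim_events[[cell]] <- ev_t[keep & ev_kind]
      intr_events[[cell]] <- ev_t[keep & !ev_kind]
    }
    list(stim_events = stim_events, intrinsic_events = intr_events,
         intrinsic_cells = intrinsic_cells)
  })
}

#' Acetylcholine release kinetics parameters
#'
#' Three-pool description of ACh handling at the ganglion-to-pacemaker
#' neuroeffector junction: each postganglionic event releases a fixed
#' fraction of the available presynaptic store into the junction; junction
#' and extra-junctional pools exchange first-order and both are hydrolysed.
#'
#' @param store_mM available presynaptic ACh concentration.
#' @param release_fraction fraction of the store released per event.
#' @param k_exchange junction/extra-junctional exchange rate, 1/s.
#' @param k_hydrolysis hydrolysis rate, 1/s (14, 5 and 30 are the documented
#'   reference values; 14 is the default).
#' @return list of kinetics parameters including the per-event junctional
#'   quantum (`quantum = release_fraction * store_mM`).
#' @export
ach_params <- function(store_mM = 0.075, release_fraction = 0.05,
                       k_exchange = 10, k_hydrolysis = 14) {
  if (k_exchange < 0 || k_hydrolysis < 0 || release_fraction < 0)
    stop("rates and release fraction must be non-negative")
  list(store_mM = store_mM, release_fraction = release_fraction,
       quantum = release_fraction * store_mM,
       k_exchange = k_exchange, k_hydrolysis = k_hydrolysis)
}

#' Junctional ACh concentration trace for an event sequence
#'
#' Linear two-pool kinetics (junction J, extra-junctional E) driven by
#' impulsive release: `dJ/dt = -k_H J - k_ex (J - E)`,
#' `dE/dt = -k_H E + k_ex (J - E)`, with `J += quantum` at each event.
#' Solved exactly via the eigenmodes `J + E` (decay `k_H`) and `J - E`
#' (decay `k_H + 2 k_ex`).
#'
#' @param events_s event times in seconds, within `[0, duration_s]`.
#' @param params an [ach_params()] list.
#' @param duration_s trace length, seconds.
#' @param dt_s sampling interval of the returned trace, seconds.
#' @return data.frame with `time` (s) and `junction_ach` (mM).
#' @export
simulate_ach <- function(events_s, params = ach_params(), duration_s,
                         dt_s = 1e-3) {
  if (length(events_s) && (min(events_s) < 0 || max(events_s) > duration_s))
    stop("event times must lie within the duration")
  kh <- params$k_hydrolysis
  kd <- params$k_hydrolysis + 2 * params$k_exchange
  tt <- seq(0, duration_s, by = dt_s)
  ev <- sort(events_s)
  s_amp <- d_amp <- numeric(length(ev))  # mode amplitudes just after event i
  s <- d <- 0; t_prev <- 0
  for (i in seq_along(ev)) {
    dt <- ev[i] - t_prev
    s <- s * exp(-kh * dt) + params$quantum
    d <- d * exp(-kd * dt) + params$quantum
    s_amp[i] <- s; d_amp[i] <- d
    t_prev <- ev[i]
  }
  idx <- findInterval(tt, ev)
  j <- numeric(length(tt))
  nz <- idx > 0
  el <- tt[nz] - ev[idx[nz]]
  j[nz] <- 0.5 * (s_amp[idx[nz]] * exp(-kh * el) +
                  d_amp[idx[nz]] * exp(-kd * el))
  data.frame(time = tt, junction_ach = j)
}
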