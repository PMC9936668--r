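#' Scale the ACh-gated potassium conductance to a different cell capacitance
#'
#' The maximum ACh-gated K conductance published for a larger pacemaker cell
#' is scaled in proportion to membrane capacitance; the reference values
#' (0.00864 uS at 32 pF, rescaled to 25 pF) give 0.00675 uS.
#'
#' @param g_ref_uS reference maximum conductance, uS.
#' @param cap_ref_pF reference cell capacitance, pF.
#' @param cap_pF target cell capacitance, pF.
#' @return scaled conductance in uS.
#' @export
kach_scaled_conductance <- function(g_ref_uS = 0.00864, cap_ref_pF = 32,
                                    cap_pF = 25) {
  stopifnot(g_ref_uS > 0, cap_ref_pF > 0, cap_pF > 0)
  g_ref_uS * cap_pF / cap_ref_pF
}

#' Reduced pacemaker cell parameters
#'
#' A two-variable conductance-based relaxation oscillator (instantaneous
#' inward current, delayed-rectifier K current, leak standing in for the slow
#' diastolic depolarization drive) operating in a Class-I (SNIC) regime, so
#' that an added ACh-gated K conductance slows firing gracefully down to
#' quiescence.  The applied current is calibrated so the unperturbed cell
#' fires at the network's target intrinsic rate of 389 beats per minute.
#' Units: mV, ms, nS, pF, pA.
#'
#' @param iapp applied (diastolic depolarization) current, pA.
#' @param ... overrides for individual parameters.
#' @return named list of cell parameters.
#' @export
san_cell_params <- function(iapp = 27.445, ...) {
  p <- list(gca = 4 / 3, eca = 120, gk = 8 / 3, ek = -84, gl = 2 / 3,
            el = -60, v1 = -1.2, v2 = 18, v3 = 12, v4 = 17.4, phi = 1 / 45,
            cap = 25, iapp = iapp)
  p[names(list(...))] <- list(...)
  p
}

#' Sinoatrial network parameters
#'
#' 10-by-10 grid of reduced pacemaker cells coupled by 6 nS gap junctions
#' between edge-sharing neighbors.  The ACh-gated K conductance is
#' `g_KACh = 6.75 nS` per cell (see [kach_scaled_conductance()]); its gating
#' by junctional ACh follows a Hill function whose midpoint and steepness are
#' calibration constants of the reduced cell (see the methods vignette).
#'
#' @param nrow,ncol grid dimensions.
#' @param g_gap_nS gap junction conductance, nS.
#' @param g_kach_nS maximum ACh-gated K conductance, nS.
#' @param hill_k Hill midpoint of the ACh gating, mM junctional ACh.
#' @param hill_n Hill coefficient of the ACh gating.
#' @param tau_bound_ms time constant of the receptor-bound ACh pool gating
#'   the channel (G-protein-coupled activation kinetics), ms.
#' @param cell a [san_cell_params()] list.
#' @param ach an [ach_params()] list.
#' @param dt_ms integrator step, ms.
#' @return named list of network parameters.
#' @export
san_network_params <- function(nrow = 10, ncol = 10, g_gap_nS = 6,
                               g_kach_nS = 1000 * kach_scaled_conductance(),
                               hill_k = 0.050, hill_n = 2,
                               tau_bound_ms = 400,
                               cell = san_cell_params(), ach = ach_params(),
                               dt_ms = 0.05) {
  stopifnot(nrow >= 1, ncol >= 1, g_gap_nS >= 0, g_kach_nS >= 0,
            hill_k > 0, hill_n > 0, dt_ms > 0)
  list(nrow = nrow, ncol = ncol, g_gap_nS = g_gap_nS, g_kach_nS = g_kach_nS,
       hill_k = hill_k, hill_n = hill_n, tau_bound_ms = tau_bound_ms,
       cell = cell, ach = ach, dt_ms = dt_ms)
}

# neighbor table of the grid: matrix of 0-based indices padded with 0 and a
# count vector, for the C integrator
.grid_neighbors <- function(nrow, ncol) {
  n <- nrow * ncol
  nb <- matrix(0L, n, 4)
  cnt <- integer(n)
  idx <- function(r, c) (r - 1L) * ncol + c
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    i <- idx(r, c)
    for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
      if (d[1] >= 1 && d[1] <= nrow && d[2] >= 1 && d[2] <= ncol) {
        cnt[i] <- cnt[i] + 1L
        nb[i, cnt[i]] <- idx(d[1], d[2]) - 1L
      }
    }
  }
  list(neighbors = nb, n_neighbors = cnt)
}

#' Indices of the peripheral cells of the pacemaker grid
#'
#' The firing rate of the cells on the network's periphery is read out as
#' heart rate.
#'
#' @param nrow,ncol grid dimensions.
#' @return integer vector of 1-based cell indices (36 cells for 10x10).
#' @export
san_periphery <- function(nrow = 10, ncol = 10) {
  r <- rep(seq_len(nrow), each = ncol)
  c <- rep(seq_len(ncol), times = nrow)
  which(r == 1 | r == nrow | c == 1 | c == ncol)
}

# single-cell limit cycle sampled at fine resolution, for random-phase
# initial conditions; cached per parameter set within a session
.limit_cycle_cache <- new.env(parent = emptyenv())

.san_limit_cycle <- function(cell) {
  key <- paste(unlist(cell), collapse = "_")
  if (!is.null(.limit_cycle_cache[[key]])) return(.limit_cycle_cache[[key]])
  nb <- list(neighbors = matrix(0L, 1, 4), n_neighbors = 0L)
  sim <- .san_network_c(3000, 0.02, -60, 0.1,
                        numeric(0), c(0L, 0L),
                        nb$neighbors, nb$n_neighbors,
                        cell, ach_params()[c("quantum", "k_exchange",
                                             "k_hydrolysis")] |>
                          c(list(hill_k = 1, hill_n = 1, tau_bound_ms = 400)),
                        0, 0, 0L, 0.02)
  tr <- sim$trace
  spk <- sim$spikes[[1]]
  if (length(spk) < 3) stop("reduced pacemaker cell failed to oscillate")
  t1 <- spk[length(spk) - 1]; t2 <- spk[length(spk)]
  seg <- tr[tr$time >= t1 & tr$time < t2, ]
  # recover w on the cycle by re-integrating w along the recorded V
  w <- numeric(nrow(seg)); w[1] <- 0.5 * (1 + tanh((seg$v[1] - cell$v3) / cell$v4))
  dt <- diff(seg$time)
  for (i in seq_len(nrow(seg) - 1)) {
    vi <- seg$v[i]
    winf <- 0.5 * (1 + tanh((vi - cell$v3) / cell$v4))
    tw <- 1 / (cell$phi * cosh((vi - cell$v3) / (2 * cell$v4)))
    w[i + 1] <- w[i] + dt[i] * (winf - w[i]) / tw
  }
  out <- data.frame(v = seg$v, w = w)
  .limit_cycle_cache[[key]] <- out
  out
}

#' Simulate the coupled sinoatrial pacemaker network
#'
#' Integrates the 10-by-10 gap-junction-coupled network of reduced pacemaker
#' cells with per-cell junctional ACh kinetics driven by the supplied event
#' times.  Cells start at independent random phases of the single-cell limit
#' cycle; the strong coupling synchronizes the grid within a few seconds.
#'
#' @param events_per_cell list (length = number of cells) of ACh release
#'   event times in seconds for each cell; `NULL` entries mean no events.
#' @param duration_s simulated time, seconds.
#' @param seed integer seed for the initial phases.
#' @param params a [san_network_params()] list.
#' @param record_cell optional 1-based cell index whose voltage and
#'   junctional ACh trace are recorded (at `record_dt_ms`).
#' @param record_dt_ms trace sampling step, ms.
#' @return list with `spikes` (per-cell spike times, seconds), `periphery`
#'   (indices), and optionally `trace`.
#' @export
simulate_san <- function(events_per_cell = NULL, duration_s, seed,
                         params = san_network_params(),
                         record_cell = NULL, record_dt_ms = 1) {
  n <- params$nrow * params$ncol
  if (is.null(events_per_cell)) events_per_cell <- vector("list", n)
  stopifnot(length(events_per_cell) == n)
  ev <- lapply(events_per_cell, function(e) if (is.null(e)) numeric(0) else sort(e) * 1000)
  lens <- vapply(ev, length, integer(1))
  offsets <- c(0L, cumsum(lens))
  times <- as.numeric(unlist(ev, use.names = FALSE))
  if (is.null(times)) times <- numeric(0)

  cyc <- .san_limit_cycle(params$cell)
  init <- .with_seed(seed, cyc[sample.int(nrow(cyc), n, replace = TRUE), ])
  nb <- .grid_neighbors(params$nrow, params$ncol)
  achc <- c(params$ach[c("quantum", "k_exchange", "k_hydrolysis")],
            list(hill_k = params$hill_k, hill_n = params$hill_n,
                 tau_bound_ms = params$tau_bound_ms))
  sim <- .san_network_c(duration_s * 1000, params$dt_ms,
                        init$v, init$w, times, offsets,
                        nb$neighbors, nb$n_neighbors,
                        params$cell, achc,
                        params$g_gap_nS, params$g_kach_nS,
                        if (is.null(record_cell)) -1L else record_cell - 1L,
                        record_dt_ms)
  spikes <- lapply(sim$spikes, function(s) s / 1000)
  out <- list(spikes = spikes,
              periphery = san_periphery(params$nrow, params$ncol))
  if (!is.null(record_cell)) out$trace <- sim$trace
  out
}

#' Instantaneous network firing rate from peripheral spikes
#'
#' Pools per-cell inter-spike-interval rates (placed at interval midpoints)
#' across the peripheral cells and averages them in a centered sliding
#' window, mirroring the instantaneous-heart-rate computation used for ECG.
#'
#' @param san result of [simulate_san()].
#' @param duration_s trace length, seconds.
#' @param window_s sliding window width, seconds.
#' @param step_s series step, seconds.
#' @return data.frame with `time` (s) and `bpm`.
#' @export
network_hr_series <- function(san, duration_s, window_s = 0.5,
                              step_s = 1e-3) {
  mids <- rates <- numeric(0)
  for (i in san$periphery) {
    s <- san$spikes[[i]]
    if (length(s) >= 2) {
      isi <- diff(s)
      mids <- c(mids, s[-length(s)] + isi / 2)
      rates <- c(rates, 60 / isi)
    }
  }
  .rate_series(mids, rates, duration_s, window_s, step_s)
}

# shared windowed-average machinery for instantaneous-rate series
.rate_series <- function(mids, rates, duration_s, window_s, step_s) {
  tt <- seq(0, duration_s, by = step_s)
  nbins <- length(tt)
  cnt <- numeric(nbins); sm <- numeric(nbins)
  if (length(mids)) {
    bin <- pmin(pmax(floor(mids / step_s) + 1, 1), nbins)
    cnt <- as.numeric(tabulate(bin, nbins))
    agg <- rowsum(rates, bin)
    sm[as.integer(rownames(agg))] <- agg[, 1]
  }
  w <- max(1, round(window_s / step_s))
  if (w %% 2 == 0) w <- w + 1
  tot_cnt <- .centered_rolling_sum(cnt, w)
  tot_sum <- .centered_rolling_sum(sm, w)
  bpm <- ifelse(tot_cnt >= 2, tot_sum / pmax(tot_cnt, 1), NA_real_)
  data.frame(time = tt, bpm = bpm)
}

#' Baseline firing statistics of the sinoatrial network
#'
#' Runs the network with intrinsic ICNS drive (and no stimulation), then
#' reports the mean peripheral firing rate and the relative peak-to-trough
#' fluctuation of the instantaneous rate attributable to the
#' respiration-linked intrinsic ACh release.  The fluctuation is measured on
#' the respiratory-cycle-averaged rate profile so that stochastic spike
#' timing noise averages out across cycles.
#'
#' @param duration_s simulated time, seconds.
#' @param seed integer seed.
#' @param params a [san_network_params()] list.
#' @param intrinsic logical; include intrinsic ICNS firing.
#' @param settle_s initial seconds discarded (network synchronization).
#' @param resp_period_s respiratory cycle, seconds.
#' @return list with `mean_bpm`, `fluctuation_pct` (peak-to-trough of the
#'   cycle-averaged profile as percent of the mean), and `series`.
#' @export
san_baseline_stats <- function(duration_s = 50, seed = 1,
                               params = san_network_params(),
                               intrinsic = TRUE, settle_s = 5,
                               resp_period_s = 1) {
  n <- params$nrow * params$ncol
  events <- vector("list", n)
  if (intrinsic) {
    icns <- simulate_icns(NULL, duration_s, seed = .sub_seed(seed, "icns"),
                          n_cells = n, resp_period_s = resp_period_s)
    for (i in seq_len(n)) events[[i]] <- icns$intrinsic_events[[i]]
  }
  san <- simulate_san(events, duration_s, seed = .sub_seed(seed, "san"),
                      params = params)
  ser <- network_hr_series(san, duration_s)
  keep <- ser$time >= settle_s & !is.na(ser$bpm)
  mean_bpm <- mean(ser$bpm[keep])
  # fold onto the respiratory cycle
  ph <- (ser$time[keep] %% resp_period_s)
  bins <- floor(ph / resp_period_s * 20)
  prof <- tapply(ser$bpm[keep], bins, mean)
  fluct <- 100 * (max(prof) - min(prof)) / mean_bpm
  list(mean_bpm = mean_bpm, fluctuation_pct = as.numeric(fluct),
       series = ser)
}
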