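.ding_bounds <- data.frame(
  param = c("A", "Km", "tau1", "tau2", "alpha_A", "alpha_Km", "alpha_tau1",
            "tau_fat"),
  lower = c(0.1, 0.01, 2, 5, -1, -1e-4, 0, 80),
  upper = c(110, 0.50, 200, 100, 1, 1e-4, 1e-3, 160),
  stringsAsFactors = FALSE)

#' Parameter bounds of the force-fatigue model
#'
#' Search ranges for the eight free parameters: scaling factor `A`
#' (force/ms), Ca-troponin sensitivity `Km`, force-decline time constants
#' `tau1`, `tau2` (ms), fatigue coefficients `alpha_A` (1/ms^2), `alpha_Km`
#' (1/(ms N)), `alpha_tau1` (1/N), and the fatigue recovery time constant
#' `tau_fat` (s).
#'
#' @return data.frame with `param`, `lower`, `upper`.
#' @export
ding_bounds <- function() .ding_bounds

#' Construct a force-fatigue parameter set
#'
#' @param A,Km,tau1,tau2,alpha_A,alpha_Km,alpha_tau1,tau_fat the eight free
#'   parameters (see [ding_bounds()] for units and ranges).
#' @param tau_c Ca-troponin driver time constant, ms (kinetics constant, not
#'   searched).
#' @param R0 doublet enhancement magnitude (kinetics constant).
#' @param check logical; reject values outside the bounds (fitting may pin
#'   values exactly at a bound).
#' @return named list of class `ding_params`.
#' @export
ding_params <- function(A, Km, tau1, tau2, alpha_A, alpha_Km, alpha_tau1,
                        tau_fat, tau_c = 20, R0 = 2, check = TRUE) {
  p <- list(A = A, Km = Km, tau1 = tau1, tau2 = tau2, alpha_A = alpha_A,
            alpha_Km = alpha_Km, alpha_tau1 = alpha_tau1, tau_fat = tau_fat,
            tau_c = tau_c, R0 = R0)
  if (check) {
    b <- .ding_bounds
    v <- unlist(p[b$param])
    bad <- v < b$lower - 1e-12 | v > b$upper + 1e-12
    if (any(bad))
      stop("parameters outside bounds: ", paste(b$param[bad], collapse = ", "))
  }
  structure(p, class = "ding_params")
}

#' Named reference parameter sets of the force-fatigue model
#'
#' `"pso_identified"` is the swarm-identified laryngeal set (fast-fatigable
#' behavior); `"ding2003"` is the published human-quadriceps set used for
#' model perturbation.
#'
#' @param name one of `"pso_identified"`, `"ding2003"`.
#' @return a [ding_params()] object.
#' @export
ding_param_set <- function(name = c("pso_identified", "ding2003")) {
  name <- match.arg(name)
  switch(name,
    pso_identified = ding_params(103, 0.50, 2.00, 100, -0.51, 9.97e-5,
                                 160e-7, 160),
    ding2003 = ding_params(3.009, 0.103, 50.957, 100, -4.0e-7, 1.9e-5,
                           2.1e-5, 127))
}

.ding_param_vec <- function(p)
  c(p$A, p$Km, p$tau1, p$tau2, p$alpha_A, p$alpha_Km, p$alpha_tau1,
    p$tau_fat, p$tau_c, p$R0)

#' Simulate muscle force for a pulse train
#'
#' Integrates the force-fatigue system: a Ca-troponin driver `CN` excited by
#' each pulse (with doublet enhancement for closely spaced pulses), a force
#' ODE saturating in `CN`, and first-order fatigue of `A`, `Km`, `tau1`
#' driven by the produced force.  The driver is advanced with its exact
#' exponential update; force and fatigue use fourth-order Runge-Kutta.  The
#' model is deterministic.
#'
#' @param train a [pulse_train()] or numeric vector of pulse times (s);
#'   times are taken relative to the first pulse's window.
#' @param params a [ding_params()] object.
#' @param dt_ms integrator step (<= 0.5 ms; larger steps alias the driver).
#' @param tail_s simulated time after the last pulse, seconds.
#' @param keep_trace logical; return the sampled force/parameter trace.
#' @return list with `fti` (force-time integral, force x ms), `final`
#'   state, and optionally `trace`.
#' @export
simulate_force <- function(train, params = ding_param_set(), dt_ms = 0.1,
                           tail_s = 0.5, keep_trace = FALSE) {
  if (dt_ms > 0.5) stop("dt_ms too coarse for the Ca-troponin driver")
  pulses_s <- if (inherits(train, "pulse_train"))
    train$onsets - train$window[1] else as.numeric(train)
  dur_ms <- if (length(pulses_s)) (max(pulses_s) + tail_s) * 1000
    else tail_s * 1000
  .ding_simulate_c(pulses_s * 1000, .ding_param_vec(params), dt_ms, dur_ms,
                   keep_trace)
}

#' Normalized force-time integral across pulse trains
#'
#' Force-time integral of each train divided by that of the 20 Hz constant
#' reference train of the same window length; the reference itself maps to
#' exactly 1.  Under the generator's assumption of a linear EMG-force
#' relationship this equals the normalized EMG.
#'
#' @param trains list of [pulse_train()] objects (or numeric pulse-time
#'   vectors in seconds).
#' @param params a [ding_params()] object.
#' @param dt_ms integrator step, ms.
#' @param ref_frequency reference constant frequency, Hz.
#' @param ref_duration_s reference train length, seconds (defaults to the
#'   first train's window length).
#' @return numeric vector of normalized force-time integrals.
#' @export
force_norm <- function(trains, params = ding_param_set(), dt_ms = 0.1,
                       ref_frequency = 20, ref_duration_s = NULL) {
  if (inherits(trains, "pulse_train")) trains <- list(trains)
  if (is.null(ref_duration_s)) {
    ref_duration_s <- if (inherits(trains[[1]], "pulse_train"))
      diff(trains[[1]]$window) else max(as.numeric(trains[[1]]))
  }
  ref <- make_constant_train(ref_frequency, c(0, ref_duration_s))
  ref_fti <- simulate_force(ref, params, dt_ms)$fti
  if (ref_fti <= 0) stop("reference force-time integral is zero")
  vapply(trains, function(tr) simulate_force(tr, params, dt_ms)$fti,
         numeric(1)) / ref_fti
}
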