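test_that("ganglion transmission probability matches independent arithmetic", {
  # independent oracle: same printed coefficients, different expression path
  oracle <- function(dt) pmin(pmax(1.028 - 2.183 * exp(-0.7146 * log(dt)), 0), 1)
  dts <- exp(seq(log(0.5), log(2000), length.out = 400))
  expect_equal(success_probability(dts), oracle(dts), tolerance = 1e-14)
  expect_equal(success_probability(10), 0.607, tolerance = 5e-4)
  expect_error(success_probability(0), "positive")
  expect_error(success_probability(-3), "positive")

  # clamp boundaries located by root-finding on the unclamped curve
  raw <- function(dt) 1.028 - 2.183 * dt^(-0.7146)
  lo <- uniroot(raw, c(0.1, 50))$root
  hi <- uniroot(function(dt) raw(dt) - 1, c(50, 5000))$root
  expect_equal(lo, 2.87, tolerance = 0.01)
  expect_equal(hi, 444, tolerance = 0.5)
  expect_equal(success_probability(lo * 0.99), 0)
  expect_equal(success_probability(hi * 1.01), 1)
  expect_gt(success_probability(lo * 1.05), 0)
  expect_lt(success_probability(hi * 0.95), 1)
})

test_that("steady transmission matches a brute-force Markov simulation", {
  # oracle: direct stochastic simulation of the renewal process
  sim_fraction <- function(f, n = 40000, seed = 99) {
    set.seed(seed)
    t0 <- -Inf; succ <- 0
    tt <- (1:n) / f * 1000
    u <- runif(n)
    for (i in 1:n) {
      p <- min(max(1.028 - 2.183 * (tt[i] - t0)^(-0.7146), 0), 1)
      if (is.na(p)) p <- 1
      if (u[i] < p) { succ <- succ + 1; t0 <- tt[i] }
    }
    succ / n
  }
  for (f in c(10, 50, 100)) {
    expect_equal(transmission_fraction(f), sim_fraction(f), tolerance = 0.02)
  }
  expect_equal(transmission_fraction(2), 1)  # p clamps to 1 at 500 ms
  # dynamic-programming fraction agrees on constant trains
  tr <- make_constant_train(50, c(0, 20))
  expect_equal(train_transmission_fraction(tr), transmission_fraction(50),
               tolerance = 0.01)
})

test_that("the ICNS stage filters, bypasses and reproduces as specified", {
  tr <- make_constant_train(100, c(2, 6))
  off <- simulate_icns(tr, 8, seed = 1, filtering = FALSE,
                       intrinsic_cells = integer(0))
  for (i in c(1, 50, 100))
    expect_identical(off$stim_events[[i]], tr$onsets)

  lo <- simulate_icns(make_constant_train(2, c(0, 20)), 20, seed = 2,
                      intrinsic_cells = integer(0))
  fr <- mean(vapply(lo$stim_events, length, integer(1))) / 40
  expect_gte(fr, 0.999)

  hi <- simulate_icns(tr, 8, seed = 3, intrinsic_cells = integer(0))
  counts <- vapply(hi$stim_events, length, integer(1))
  expect_true(all(counts <= length(tr$onsets)))
  # mean transmitted rate matches the renewal expectation within MC error
  expect_equal(mean(counts) / length(tr$onsets), transmission_fraction(100),
               tolerance = 0.03)

  a <- simulate_icns(tr, 8, seed = 7)
  b <- simulate_icns(tr, 8, seed = 7)
  expect_identical(a, b)
})

test_that("ACh kinetics have the closed-form single-event solution", {
  p <- ach_params(k_exchange = 0, k_hydrolysis = 14)
  tr <- simulate_ach(0.2, p, duration_s = 1, dt_s = 1e-3)
  after <- tr$time >= 0.2
  expect_equal(tr$junction_ach[after],
               p$quantum * exp(-14 * (tr$time[after] - 0.2)),
               tolerance = 1e-10)
  expect_true(all(simulate_ach(numeric(0), p, 1)$junction_ach == 0))
  # steady 10 Hz carries more time-averaged ACh than steady 2 Hz
  p2 <- ach_params()
  m10 <- mean(simulate_ach(seq(0.05, 4.95, 0.1), p2, 5)$junction_ach)
  m2 <- mean(simulate_ach(seq(0.25, 4.75, 0.5), p2, 5)$junction_ach)
  expect_gt(m10, m2)
  expect_error(ach_params(k_hydrolysis = -1), "non-negative")
})

test_that("the conductance scaling reproduces the capacitance-ratio value", {
  expect_identical(kach_scaled_conductance(), 0.00864 * 25 / 32)
  expect_equal(kach_scaled_conductance(), 0.00675)
})

test_that("the unperturbed network fires at the calibrated intrinsic rate", {
  san <- simulate_san(NULL, 12, seed = 4)
  ser <- network_hr_series(san, 12)
  sel <- ser$time >= 5 & !is.na(ser$bpm)
  expect_equal(mean(ser$bpm[sel]), 389, tolerance = 2 / 389)
  # synchronized identical cells: all peripheral cells at the same rate
  rates <- vapply(san$spikes[san$periphery], function(s) {
    s <- s[s > 5]; 60 / mean(diff(s))
  }, numeric(1))
  expect_lt(diff(range(rates)), 1)
})

test_that("saturating ACh to all cells silences the network", {
  dense <- lapply(1:100, function(i) seq(0.01, 10, by = 0.01))
  san <- simulate_san(dense, 10, seed = 5)
  late <- unlist(lapply(san$spikes[san$periphery], function(s) s[s > 6]))
  expect_length(late, 0)
})

test_that("a trial with zero ACh density leaves heart rate unchanged", {
  out <- run_hr_trial(vns_condition(1, 50), density = 0, seed = 6,
                      protocol = short_protocol())
  expect_equal(out$hr_norm, 1, tolerance = 0.02)
})

test_that("density calibration recovers the minimizer on a monotone surrogate", {
  # surrogate response: hr_norm falls linearly with density at every frequency
  freqs <- c(5, 20, 50)
  surrogate <- function(d) 1 - d / 120 * c(0.5, 1, 1.5)
  targets <- surrogate(42)
  cal <- calibrate_density(targets, freqs, simulate_fn = surrogate)
  expect_equal(cal$density, 42)
  expect_lt(cal$rmse, 1e-12)
  expect_equal(calibrate_density(c(1, 1, 1), freqs,
                                 simulate_fn = surrogate)$density, 0)
  expect_warning(
    cal2 <- calibrate_density(c(0.85, 0.85, 0.85), freqs,
                              simulate_fn = function(d) rep(0.8 + d / 1000, 3)),
    "monotone")
  expect_equal(cal2$density, 50)
})
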