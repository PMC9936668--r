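test_that("zero amplitude produces no stimulation effect", {
  g <- generate_trial(vns_condition(0, 20), quiet_surface(), noise_sd = 0,
                      seed = 1, protocol = short_protocol())
  expect_equal(g$ground_truth$target_hr_norm, 1)
  expect_length(g$ground_truth$per_pulse_emg_amplitude, 0)
  expect_equal(max(abs(g$recording$emg)), 0)
})

test_that("vagotomy abolishes evoked EMG and the heart-rate response", {
  g <- generate_trial(vns_condition(1.2, 50), response_surface(),
                      noise_sd = 0, seed = 2, protocol = short_protocol(),
                      vagotomized = TRUE)
  expect_equal(g$ground_truth$target_hr_norm, 1)
  expect_true(all(g$ground_truth$per_pulse_emg_amplitude == 0))
  # trajectory is pure baseline x RSA: constant across the stim window mean
  hr <- g$ground_truth$hr_trajectory
  expect_equal(mean(hr), 450, tolerance = 1e-3)
  # artifacts still present on the EMG channel
  expect_gt(max(abs(g$recording$emg)), 1)
})

test_that("noiseless constant-rate trials have exact beat intervals", {
  surf <- quiet_surface()
  g <- generate_trial(vns_condition(0, 20), surf, noise_sd = 0, seed = 3,
                      protocol = short_protocol())
  rr <- diff(g$ground_truth$beat_times)
  expect_equal(max(abs(rr - 60 / 450)), 0, tolerance = 1e-6)
})

test_that("trial generation is reproducible from the seed", {
  a <- generate_trial(vns_condition(1, 20), response_surface(), seed = 9,
                      protocol = short_protocol())
  b <- generate_trial(vns_condition(1, 20), response_surface(), seed = 9,
                      protocol = short_protocol())
  expect_identical(a$recording$ecg, b$recording$ecg)
  expect_identical(a$recording$emg, b$recording$emg)
})

test_that("high-rate stimulation shows a fatigue decline in evoked EMG", {
  g <- generate_trial(vns_condition(1, 100), quiet_surface(), noise_sd = 0,
                      seed = 4, protocol = short_protocol())
  pp <- g$ground_truth$per_pulse_emg_amplitude
  expect_lt(mean(tail(pp, 100)), mean(head(pp, 100)))
  # later pulses strictly below the early plateau
  expect_true(all(tail(pp, 100) < pp[1]))
})

test_that("ground-truth HR_norm is monotone in MPR and amplitude", {
  surf <- response_surface()
  for (f in c(20, 50, 100)) {
    mprs <- c(5, 10, 20)
    hrn <- vapply(mprs, function(m)
      surface_hr_norm(surf, vns_condition(1, f, m, if (m == f) "constant" else "burst")),
      numeric(1))
    expect_true(all(diff(hrn) <= 0))
  }
  for (a in list(c(0.8, 1), c(1, 1.2))) {
    expect_gte(surface_hr_norm(surf, vns_condition(a[1], 20)),
               surface_hr_norm(surf, vns_condition(a[2], 20)))
  }
  # increasing intra-burst frequency at fixed MPR weakens the response
  hrn_f <- vapply(c(20, 50, 100), function(f)
    surface_hr_norm(surf, vns_condition(1, f, 10, "burst")), numeric(1))
  expect_true(all(diff(hrn_f) >= 0))
})

test_that("the surface rejects non-monotone amplitude gains", {
  expect_error(response_surface(gains = c("0.8" = 0.3, "1" = 0.1)),
               "non-decreasing")
})

test_that("cohort generation counts, jitters and reproduces correctly", {
  design <- enumerate_design(c(10, 20), amplitudes = c(0.8, 1))
  co <- generate_cohort(2, design, quiet_surface(), seed = 5,
                        protocol = short_protocol(), noise_sd = 0,
                        process = function(rec, gt)
                          data.frame(animal = rec$animal_id,
                                     hrn = gt$target_hr_norm))
  expect_length(co, 2 * nrow(design))
  co2 <- generate_cohort(2, design, quiet_surface(), seed = 5,
                         protocol = short_protocol(), noise_sd = 0,
                         process = function(rec, gt)
                           data.frame(animal = rec$animal_id,
                                      hrn = gt$target_hr_norm))
  expect_identical(do.call(rbind, co), do.call(rbind, co2))

  # zero animal-effect sigma: all animals share the ground-truth surface
  co0 <- generate_cohort(3, design[design$amplitude == 1, ], quiet_surface(),
                         seed = 6, animal_sigma = 0, emg_sigma = 0,
                         protocol = short_protocol(), noise_sd = 0,
                         process = function(rec, gt)
                           data.frame(animal = rec$animal_id,
                                      frequency = rec$condition$frequency,
                                      mpr = rec$condition$mpr,
                                      hrn = gt$target_hr_norm))
  df0 <- do.call(rbind, co0)
  per_cond <- tapply(df0$hrn, paste(df0$frequency, df0$mpr),
                     function(x) length(unique(x)))
  expect_true(all(per_cond == 1))
  expect_error(generate_cohort(2, design[0, ], quiet_surface(), seed = 1),
               "empty design")
})

test_that("random sessions bracket the random trial with constant controls", {
  ses <- generate_random_session(10, seed = 3, surface = quiet_surface(),
                                 noise_sd = 0, protocol = short_protocol())
  expect_named(ses, c("C1", "R", "C2"))
  for (tr in ses)
    expect_length(tr$recording$trigger_times, 10 * short_protocol()$stim_s)
  r_on <- ses$R$recording$trigger_times
  expect_true(all(table(floor(r_on)) == 10))
  # ground truth of R evaluates the surface on the realized intervals
  expect_lt(abs(ses$R$ground_truth$target_hr_norm -
                ses$C1$ground_truth$target_hr_norm), 0.02)
})
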