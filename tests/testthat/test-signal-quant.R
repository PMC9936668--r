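test_that("beat detection recovers generator beats exactly on clean traces", {
  g <- generate_trial(vns_condition(1, 20), quiet_surface(), noise_sd = 0,
                      seed = 1, protocol = short_protocol())
  b <- detect_beats(g$recording$ecg)
  bt <- g$ground_truth$beat_times
  expect_equal(length(b), length(bt))
  expect_lt(max(abs(b - bt)), 1.5 / 5000)
  expect_length(detect_beats(rep(0, 5000)), 0)
})

test_that("beat detection is robust at moderate noise with no false positives", {
  hits <- fps <- 0; total <- 0
  for (s in 1:5) {
    g <- generate_trial(vns_condition(1, 20), response_surface(),
                        noise_sd = 0.1, seed = s, protocol = short_protocol())
    b <- detect_beats(g$recording$ecg)
    bt <- g$ground_truth$beat_times
    hits <- hits + sum(vapply(bt, function(t) min(abs(b - t)) < 5e-3, logical(1)))
    fps <- fps + sum(vapply(b, function(t) min(abs(bt - t)) >= 5e-3, logical(1)))
    total <- total + length(bt)
  }
  expect_gte(hits / total, 0.99)
  expect_equal(fps, 0)
})

test_that("heart-rate metrics reproduce hand-computed interval cases", {
  prot <- trial_protocol()
  beats <- seq(0.15, prot$total_s, by = 0.15)
  m <- hr_metrics(beats, prot)
  expect_equal(m$hr_baseline, 400, tolerance = 1e-6)
  expect_equal(m$hr_stim, 400, tolerance = 1e-6)
  expect_equal(m$hr_norm, 1, tolerance = 1e-6)
  expect_true(m$valid)

  # 150 ms RR at baseline, 187.5 ms during stimulation: 400 -> 320 BPM
  b2 <- c(seq(0.15, 10, by = 0.15), seq(10.1875, prot$total_s, by = 0.1875))
  m2 <- hr_metrics(b2, prot)
  # small deviations reflect sliding windows straddling the rate change
  expect_equal(m2$hr_norm, 0.8, tolerance = 5e-3)
  expect_lt(m2$hr_norm, 1)  # bradycardia

  expect_false(hr_metrics(c(1, 1.2), prot)$valid)
})

test_that("artifact template subtraction removes identical artifacts exactly", {
  fs <- 5000
  n <- 2 * fs
  triggers <- seq(0.1, 1.9, by = 0.05)
  art <- c(2, -1.5, 1, -0.5, 0.25)
  emg <- numeric(n)
  wave <- 0.3 * sin(pi * seq(0, 1, length.out = 20))
  for (tr in triggers) {
    i0 <- round(tr * fs) + 1
    emg[i0:(i0 + 4)] <- emg[i0:(i0 + 4)] + art
    j0 <- i0 + round(0.0015 * fs)
    emg[j0:(j0 + 19)] <- emg[j0:(j0 + 19)] + wave
  }
  cleaned <- subtract_artifact(emg, triggers, fs)
  for (tr in triggers) {
    i0 <- round(tr * fs) + 1
    expect_equal(max(abs(cleaned[i0:(i0 + 4)])), 0, tolerance = 1e-12)
    j0 <- i0 + round(0.0015 * fs)
    expect_equal(cleaned[j0:(j0 + 19)], wave)  # evoked wave untouched
  }
  # idempotence: a second pass changes nothing
  expect_equal(subtract_artifact(cleaned, triggers, fs), cleaned)
})

test_that("template subtraction halves jittered-artifact power on average", {
  set.seed(11)
  fs <- 5000; n <- 2 * fs
  triggers <- seq(0.1, 1.9, by = 0.05)
  art <- c(2, -1.5, 1, -0.5, 0.25)
  rms_before <- rms_after <- 0
  emg <- numeric(n)
  scale <- 1 + runif(length(triggers), -0.5, 0.5)
  for (k in seq_along(triggers)) {
    i0 <- round(triggers[k] * fs) + 1
    emg[i0:(i0 + 4)] <- emg[i0:(i0 + 4)] + scale[k] * art
  }
  cleaned <- subtract_artifact(emg, triggers, fs)
  idx <- unlist(lapply(round(triggers * fs) + 1, function(i) i:(i + 4)))
  expect_lte(sqrt(mean(cleaned[idx]^2)), 0.5 * sqrt(mean(emg[idx]^2)))
})

test_that("overlapping artifact windows are truncated with a warning", {
  emg <- rnorm(1000)
  expect_warning(subtract_artifact(emg, c(0.05, 0.0512), 5000), "overlap")
  expect_error(subtract_artifact(emg, numeric(0), 5000), "trigger")
})

test_that("per-pulse ARV quantification is exact for rectangular waves", {
  fs <- 5000
  emg <- numeric(fs)
  triggers <- c(0.1, 0.3, 0.5)
  rel <- seq(round(1e-3 * fs), round(6e-3 * fs))
  for (tr in triggers) emg[round(tr * fs) + 1 + rel] <- 0.4
  q <- emg_quantify(emg, triggers, fs)
  expect_equal(q$emg_arv, rep(0.4, 3))
  expect_equal(q$emg_sum, 1.2)
  expect_equal(emg_quantify(numeric(fs), triggers, fs)$emg_sum, 0)
})

test_that("summed ARV is linear in the number of identical pulses", {
  fs <- 5000
  triggers <- seq(0.05, by = 0.05, length.out = 600)
  emg <- numeric(31 * fs)
  rel <- seq(round(1e-3 * fs), round(6e-3 * fs))
  for (tr in triggers) emg[round(tr * fs) + 1 + rel] <- 0.25
  q <- emg_quantify(emg, triggers, fs)
  expect_equal(q$emg_sum, 600 * 0.25, tolerance = 1e-9)
})

test_that("EMG normalization and the effect score follow their definitions", {
  expect_equal(normalize_emg(5, 5), 1)
  expect_equal(normalize_emg(0, 5), 0)
  expect_equal(normalize_emg(10, 5), 2)
  expect_error(normalize_emg(1, 0), "positive")

  expect_equal(effect_score(0.84, 0.84, 1), 0)
  expect_equal(effect_score(1, 0.84, 0), 0)
  expect_equal(effect_score(0.68, 0.84, 1), 1)  # (0.32/0.16) - 1
  expect_error(effect_score(0.9, 1, 1), "bradycardia")

  # strictly decreasing in emg_norm and in hr_norm
  expect_gt(effect_score(0.7, 0.84, 0.5), effect_score(0.7, 0.84, 0.8))
  expect_gt(effect_score(0.6, 0.84, 1), effect_score(0.7, 0.84, 1))
})

test_that("cohort quantification normalizes to the per-animal reference", {
  design <- enumerate_design(c(10, 20), amplitudes = 1)
  rows <- do.call(rbind, generate_cohort(
    2, design, quiet_surface(), seed = 8, protocol = short_protocol(),
    noise_sd = 0, animal_sigma = 0.2, emg_sigma = 0.3,
    process = function(rec, gt) quantify_trial(rec)))
  q <- quantify_cohort(rows, ref_frequency = 20)
  ref <- q[q$frequency == 20 & q$mpr == 20 & q$pattern == "constant", ]
  expect_equal(ref$emg_norm, rep(1, 2))
  expect_equal(ref$effect_score, rep(0, 2))
  expect_true(all(is.finite(q$emg_norm)))
})
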