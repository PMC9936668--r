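test_that("constant trains have uniform spacing and the right count", {
  tr <- make_constant_train(20, c(10, 40))
  expect_length(tr$onsets, 600)
  expect_equal(unique(round(diff(tr$onsets), 9)), 0.05)
  expect_length(make_constant_train(2, c(10, 40))$onsets, 60)
  expect_error(make_constant_train(2000, c(10, 40)), "too high")
})

test_that("burst trains pack each epoch at the intra-burst spacing", {
  tr <- make_burst_train(40, 10, c(10, 40))
  expect_length(tr$onsets, 300)
  within_epoch <- round((tr$onsets - floor(tr$onsets)) * 1000, 6)
  expect_setequal(unique(within_epoch), seq(0, 225, by = 25))

  hi <- make_burst_train(100, 50, c(10, 40))
  expect_length(hi$onsets, 1500)
  expect_equal(max(hi$onsets - floor(hi$onsets)), 0.49)

  expect_error(make_burst_train(10, 20, c(10, 40)), "not a valid burst")
})

test_that("a burst with mpr equal to frequency degenerates to the constant train", {
  expect_identical(make_burst_train(20, 20, c(10, 40))$onsets,
                   make_constant_train(20, c(10, 40))$onsets)
})

test_that("random trains tile one seeded epoch across the window", {
  tr <- make_random_train(10, seed = 42, window = c(10, 40))
  expect_length(tr$onsets, 300)
  e1 <- tr$onsets[1:10]
  e2 <- tr$onsets[11:20]
  expect_equal(e2, e1 + 1)
  expect_length(make_random_train(20, 1, c(10, 40))$onsets, 600)
  expect_identical(make_random_train(10, 7, c(10, 40))$onsets,
                   make_random_train(10, 7, c(10, 40))$onsets)
  expect_false(identical(make_random_train(10, 7, c(10, 40))$onsets,
                         make_random_train(10, 8, c(10, 40))$onsets))
})

test_that("random epochs respect the minimum inter-pulse interval and rate", {
  for (s in 1:50) {
    tr <- make_random_train(10, seed = s, window = c(0, 2))
    expect_true(all(diff(tr$onsets[1:10]) >= 1e-3))
    st <- pattern_stats(tr)
    # arithmetic mean of inverse intervals can only exceed the nominal rate
    expect_gte(st$mean_ipf, 10)
    expect_lte(st$geom_mean_ipf, st$mean_ipf)
  }
})

test_that("duty-cycle trains compress pulses into the first half second", {
  tr <- make_duty50_train(10, c(10, 40))
  expect_length(tr$onsets, 300)
  off <- tr$onsets - floor(tr$onsets)
  expect_true(all(off < 0.5))
  expect_equal(unique(round(diff(tr$onsets[1:10]), 9)), 0.05)
})

test_that("the default factorial design has 36 patterns and 108 conditions", {
  d <- enumerate_design()
  expect_equal(nrow(d), 108)
  d1 <- d[d$amplitude == 1, ]
  expect_equal(nrow(d1), 36)
  expect_equal(sum(d1$pattern == "constant"), 8)
  expect_equal(sum(d1$pattern == "burst"), 28)
  expect_true(all(d$mpr <= d$frequency))
})

test_that("design size follows the triangular-grid formula", {
  for (n in 2:5) {
    grid <- seq_len(n) * 10
    d <- enumerate_design(grid, amplitudes = c(1, 1.2))
    expect_equal(nrow(d), 2 * (n + n * (n - 1) / 2))
  }
  d <- enumerate_design(c(10, 20), amplitudes = 1)
  expect_equal(nrow(d), 3)
  expect_error(enumerate_design(c(10, 10, 20)), "duplicate")
})

test_that("every design row yields exactly mpr pulses per epoch", {
  d <- enumerate_design()[enumerate_design()$amplitude == 1, ]
  prot <- trial_protocol()
  for (i in seq_len(nrow(d))) {
    cond <- vns_condition(1, d$frequency[i], d$mpr[i], d$pattern[i])
    tr <- condition_train(cond, prot)
    counts <- table(floor(tr$onsets))
    expect_true(all(counts == d$mpr[i]))
    expect_length(tr$onsets, d$mpr[i] * 30)
  }
})

test_that("pattern statistics match hand-computed interval cases", {
  st <- pattern_stats(make_constant_train(20, c(0, 5)))
  expect_equal(st$mean_ipf, 20)
  expect_equal(st$geom_mean_ipf, 20)

  tr <- pulse_train(c(0, 0.025, 0.125), c(0, 1))
  st <- pattern_stats(tr)
  expect_equal(st$mean_ipf, 25)          # (40 + 10) / 2
  expect_equal(st$geom_mean_ipf, 20)     # sqrt(40 * 10)

  expect_error(pattern_stats(pulse_train(0.5, c(0, 1))), "2 pulses")
})

test_that("pulse train invariants are enforced", {
  expect_error(pulse_train(c(0.2, 0.1), c(0, 1)), "increasing")
  expect_error(pulse_train(c(0.1, 0.1004), c(0, 1)), "inter-pulse")
  expect_error(pulse_train(c(0.5, 1.5), c(0, 1)), "window")
  expect_error(vns_condition(1, 10, 20, "burst"), "exceed")
  expect_error(vns_condition(1, 20, 10, "constant"), "constant")
})
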