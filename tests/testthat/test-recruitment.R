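test_that("fiber populations respect their anatomical ranges and reproduce", {
  pop <- sample_population(150, 150, seed = 2)
  a <- pop[pop$type == "A", ]; b <- pop[pop$type == "B", ]
  expect_true(all(a$diameter >= 7 & a$diameter <= 11))
  expect_true(all(b$diameter >= 2 & b$diameter <= 5))
  expect_true(all(pop$jitter >= -0.5 & pop$jitter <= 0.5))
  expect_true(all(pop$x^2 + pop$y^2 <= 90^2))
  expect_equal(pop$inl, 100 * pop$diameter)
  expect_identical(pop, sample_population(150, 150, seed = 2))
})

test_that("point-source potentials match the closed form and its symmetries", {
  geo <- electrode_geometry(sigma_s_m = 1, n_ring = 1, contact_width_um = 0,
                            n_axial = 1)
  # 1 mA monopole at 1 mm: 1/(4 pi) volts; isolate by a distant far contact
  far <- geo; far$anode_pts[, "z"] <- 1e12
  v <- extracellular_potential(far, 1, cbind(geo$cathode[["x"]],
                                             geo$cathode[["y"]],
                                             geo$cathode[["z"]] + 1000))
  expect_equal(unname(v), -1 / (4 * pi), tolerance = 1e-6)
  # bipolar antisymmetry: the midplane is at zero potential
  v0 <- extracellular_potential(geo, 1, cbind(0, 0, 0))
  expect_equal(unname(v0), 0, tolerance = 1e-12)
  # magnitude decays monotonically with distance from the cathode: points
  # at increasing radial offset from the contact
  xs <- seq(0, 80, by = 10)
  vr <- extracellular_potential(geo, 1, cbind(xs, 0, geo$cathode[["z"]]))
  expect_true(all(diff(abs(vr)) > 0))  # closer to the contact as x grows
  expect_warning(
    extracellular_potential(geo, 1, cbind(100, 0, geo$cathode[["z"]])),
    "clamped")
  # band sub-sources average to the same far-field dipole
  band <- electrode_geometry(sigma_s_m = 1)
  v_far <- extracellular_potential(band, 1, cbind(0, 0, 25000))
  v_far_pt <- extracellular_potential(geo, 1, cbind(0, 0, 25000))
  expect_equal(unname(v_far), unname(v_far_pt), tolerance = 1e-3)
})

test_that("perineurium thickness follows the published linear fit", {
  expect_equal(perineurium_thickness(0), 1.367)
  expect_equal(perineurium_thickness(180), 3.6926)
  d <- c(50, 120, 400)
  expect_equal(perineurium_thickness(2 * d) - perineurium_thickness(d),
               0.01292 * d)
  expect_error(perineurium_thickness(-1), "non-negative")
})

test_that("a uniformly weaker field raises the threshold", {
  # doubling every source-to-node distance halves the whole potential
  # profile; with the field entering linearly, the threshold must at least
  # double
  pop <- sample_population(2, 2, seed = 5)
  for (i in c(1, 3)) {
    f <- pop[i, ]
    t1 <- find_threshold(f, electrode_geometry(sigma_s_m = 0.3))
    t2 <- find_threshold(f, electrode_geometry(sigma_s_m = 0.6))
    expect_gt(t2, t1)
    expect_equal(t2, 2 * t1, tolerance = 0.05)
  }
})

test_that("B-fiber thresholds are governed by diameter more than alignment", {
  # with the sharply peaked near field, per-position diameter ordering is
  # confounded by node alignment; the population-level contrast is the
  # robust statement (diameter share of log-threshold variance exceeds the
  # jitter share)
  pop <- population_thresholds(sample_population(2, 80, seed = 9))
  b <- pop[pop$type == "B" & is.finite(pop$threshold_ma), ]
  b$jit <- cut(b$jitter, 4)
  b$dia <- cut(b$diameter, 4)
  b$rad <- cut(sqrt(b$x^2 + b$y^2), 4)
  av1 <- anova(lm(log(threshold_ma) ~ rad + jit + dia, b))
  av2 <- anova(lm(log(threshold_ma) ~ rad + dia + jit, b))
  ss1 <- setNames(av1[["Sum Sq"]], rownames(av1))
  ss2 <- setNames(av2[["Sum Sq"]], rownames(av2))
  expect_gt(mean(c(ss1[["dia"]], ss2[["dia"]])),
            mean(c(ss1[["jit"]], ss2[["jit"]])))
})

test_that("A-fiber thresholds swing more over jitter than over diameter", {
  pos <- list(x = 40, y = -25)
  th_j <- vapply(seq(-0.5, 0.5, by = 0.125), function(j) {
    f <- data.frame(fiber_id = 1, type = "A", diameter = 9, x = pos$x,
                    y = pos$y, jitter = j, inl = 900)
    find_threshold(f, electrode_geometry())
  }, numeric(1))
  th_d <- vapply(seq(7, 11, by = 0.5), function(d) {
    f <- data.frame(fiber_id = 1, type = "A", diameter = d, x = pos$x,
                    y = pos$y, jitter = 0.25, inl = 100 * d)
    find_threshold(f, electrode_geometry())
  }, numeric(1))
  swing <- function(x) max(x) / min(x)
  expect_gt(swing(th_j), swing(th_d))
})

test_that("recruitment curves rise from zero to complete activation", {
  pop <- population_thresholds(sample_population(25, 25, seed = 6))
  amax <- max(pop$threshold_ma[is.finite(pop$threshold_ma)])
  grid <- c(0, 10^seq(-3, log10(amax * 1.01), length.out = 12))
  rc <- recruitment_curves(pop, grid)
  expect_equal(rc$fraction[rc$amplitude_ma == 0], c(0, 0))
  for (ty in c("A", "B")) {
    fr <- rc$fraction[rc$type == ty]
    expect_true(all(diff(fr) >= 0))
  }
  if (all(is.finite(pop$threshold_ma)))
    expect_equal(rc$fraction[rc$amplitude_ma == max(grid)], c(1, 1))
})

test_that("returned thresholds bracket activation for random fibers", {
  pop <- population_thresholds(sample_population(15, 15, seed = 7))
  ok <- 0; tested <- 0
  for (i in seq_len(nrow(pop))) {
    f <- pop[i, ]
    if (!is.finite(f$threshold_ma)) next
    tested <- tested + 1
    ok <- ok + (!fiber_fires(f, 0.99 * f$threshold_ma) &&
                  fiber_fires(f, 1.01 * f$threshold_ma))
  }
  expect_gte(ok / tested, 0.9)
})
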