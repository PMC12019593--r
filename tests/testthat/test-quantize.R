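test_that("drive calibration finds the minimal spiking current", {
  dc <- drive_const()
  expect_gt(dc, 5)  # must exceed the 5 mV drive-to-threshold asymptote
  expect_lt(dc, 20)
  expect_gt(mc_spike_phase(dc), 0)
  expect_equal(mc_spike_phase(dc - 2e-4), 0L)  # just below: silent
  # at the detection limit the spike lands at the latest attainable phase:
  # just after the oscillation's most permissive step, and still within the
  # first half of the cycle so the 25 ms delay clears the cycle boundary
  osc <- oscillator_config()
  expect_gte(mc_spike_phase(dc), osc$peak_step)
  expect_lte(mc_spike_phase(dc), 25L)
})

test_that("threshold grids are equidistant and 1/x maps to weights", {
  g <- make_threshold_grid(c(0.01, 1), 10)
  expect_length(g, 10)
  expect_equal(g[1], 0.01)
  expect_equal(g[10], 1)
  expect_equal(diff(g), rep(0.11, 9))
  expect_equal(make_threshold_grid(c(0.01, 1), 1), 1)
  expect_error(make_threshold_grid(c(0.01, 1), 0), "at least 1")
  # weights c/x decrease as thresholds increase (1/x distribution)
  w <- 7 / g
  expect_true(all(diff(w) < 0))
  expect_equal(w[1] / w[10], 100)
})

test_that("Jenks DP equals exhaustive search on all small instances", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    k <- sample(1:min(4, n), 1)
    values <- round(runif(n, 0, 10), 2)
    if (length(unique(values)) < k) next
    dp <- jenks_breaks(values, k)
    bf <- jenks_brute_force(values, k)
    expect_equal(attr(dp, "ss"), bf$ss, tolerance = 1e-10)
    expect_equal(as.integer(attr(dp, "sizes")), as.integer(bf$sizes))
  }
})

test_that("Jenks handles canonical and degenerate cases", {
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_equal(as.numeric(b), c(1, 6.5, 12))  # break between 3 and 10
  b1 <- jenks_breaks(c(5, 1, 9), 1)
  expect_equal(as.numeric(b1), c(1, 9))
  expect_warning(bk <- jenks_breaks(c(1, 1, 2), 5), "distinct")
  expect_length(as.numeric(bk), 3)  # reduced to k = 2
})

test_that("schemes satisfy their per-condition structure", {
  dc <- drive_const()
  hom <- build_scheme("homogeneous", 32, gain_index = 4, drive_constant = dc)
  expect_equal(length(unique(as.vector(hom$weights))), 1L)
  expect_equal(dim(hom$weights), c(32L, 8L))
  uni <- build_scheme("uniform", 4, drive_constant = dc)
  for (j in 1:8) {
    expect_equal(uni$thresholds[, j], make_threshold_grid(c(0.01, 1), 4))
  }
  expect_equal(uni$weights, dc / uni$thresholds)
  # scaled: thresholds span each sensor's observed range
  set.seed(3)
  obs <- matrix(runif(16 * 8, 0.1, 0.6), 16, 8)
  sca <- build_scheme("scaled", 8, calib = calibration_set(obs, 8),
                      drive_constant = dc)
  for (j in 1:8) {
    expect_equal(sca$thresholds[1, j], min(obs[, j]))
    expect_equal(sca$thresholds[8, j], max(obs[, j]))
    expect_true(all(diff(sca$thresholds[, j]) > 0))
  }
  # adaptive: thresholds stay inside the observed range
  obs2 <- obs
  obs2[, 3] <- runif(16, 0.2, 0.4)
  ada <- build_scheme("adaptive", 8, calib = calibration_set(obs2, 8),
                      drive_constant = dc)
  expect_true(all(ada$thresholds[, 3] >= 0.2 - 1e-9))
  expect_true(all(ada$thresholds[, 3] <= 0.4 + 1e-9))
  expect_true(all(diff(ada$thresholds[, 3]) > 0))
  expect_error(build_scheme("scaled", 4, drive_constant = dc),
               "calibration")
  expect_error(build_scheme("homogeneous", 4, drive_constant = dc),
               "gain_index")
})

test_that("uniform scheme is the scaled scheme on full-range observations", {
  dc <- drive_const()
  obs <- matrix(rep(c(0.01, 1), each = 8), 16, 8, byrow = FALSE)
  obs <- rbind(matrix(0.01, 8, 8), matrix(1, 8, 8))
  sca <- build_scheme("scaled", 8, calib = calibration_set(obs, 8),
                      drive_constant = dc)
  uni <- build_scheme("uniform", 8, drive_constant = dc)
  expect_equal(sca$thresholds, uni$thresholds)
})

test_that("adaptive thresholds are denser where observations are denser", {
  dc <- drive_const()
  # sensor 1: observations piled in [0.1, 0.2] with a few in [0.8, 0.9]
  set.seed(9)
  dense <- c(runif(13, 0.1, 0.2), runif(3, 0.8, 0.9))
  obs <- matrix(runif(16 * 8, 0.1, 0.9), 16, 8)
  obs[, 1] <- dense
  ada <- build_scheme("adaptive", 16, calib = calibration_set(obs, 16),
                      drive_constant = dc)
  th <- ada$thresholds[, 1]
  expect_gt(sum(th <= 0.25), sum(th >= 0.75))
})

test_that("weight/threshold duality holds on a drive grid", {
  dc <- drive_const()
  sch <- build_scheme("uniform", 8, drive_constant = dc)
  for (i in c(1, 4, 8)) {
    x <- sch$thresholds[i, 1]
    w <- sch$weights[i, 1]
    expect_gt(mc_spike_phase(w * (x * 1.01)), 0)
    expect_equal(mc_spike_phase(w * (x * 0.98)), 0L)
  }
})

test_that("schemes serialize to JSON and tidy into tables", {
  dc <- drive_const()
  sch <- build_scheme("uniform", 4, drive_constant = dc)
  tf <- tempfile(fileext = ".json")
  write_scheme(sch, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$condition, "uniform")
  expect_equal(back$c, sch$c)
  expect_equal(as.vector(back$thresholds), as.vector(sch$thresholds))
  td <- generics::tidy(sch)
  expect_equal(nrow(td), 32L)
  expect_equal(td$weight, sch$c / td$threshold)
  unlink(tf)
})
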