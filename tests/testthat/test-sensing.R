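test_that("analog conversion is linear in the offset-subtracted counts", {
  cal <- sensor_calibration(analog_offset = 102)
  expect_equal(analog_to_cmH2O(102, cal), 0)
  # 96 offset-subtracted counts at the fitted slope land on the 20 cmH2O
  # calibration point to within half a count of quantisation
  p <- analog_to_cmH2O(102 + 96, cal)
  expect_equal(p, 96 * 0.208879)
  expect_lt(abs(p - 20), 0.208879 / 2)
})

test_that("the pressure-sensor forward model inverts the calibration", {
  cal <- sensor_calibration(analog_offset = 102)
  expect_equal(simulate_pressure_sensor(0, cal), 102)
  expect_equal(simulate_pressure_sensor(96 * 0.208879, cal), 102 + 96)
  # noiseless round trip across the working range, within quantisation
  p_true <- seq(0, 60, by = 0.7)
  back <- analog_to_cmH2O(simulate_pressure_sensor(p_true, cal), cal)
  expect_lt(max(abs(back - p_true)), 0.208879 / 2 + 1e-12)
  # Monte-Carlo: the sample mean of many noisy draws sits on the noiseless
  # value to within 3 standard errors
  draws <- simulate_pressure_sensor(rep(20, 1e4), cal, noise_sd = 3, seed = 9)
  se <- 3 / sqrt(1e4)
  expect_lt(abs(mean(draws) - (102 + 20 / 0.208879)), 3 * se + 0.5)
})

test_that("the packaged MPX2010DP table fits the published slope", {
  tab <- read_calibration_table(system.file("extdata",
                                            "mpx2010_calibration.csv",
                                            package = "ventsim"))
  expect_equal(nrow(tab), 21)
  fit <- fit_calibration(tab)
  expect_equal(round(fit$c_constant, 6), 0.208879)
})

test_that("fit_calibration is exactly the closed-form OLS slope", {
  # exact line
  tab <- calibration_table(pressure = 0.2 * (0:10), analog = 0:10)
  expect_equal(fit_calibration(tab)$c_constant, 0.2)
  # oracle identity on seeded random tables: slope = cov(p, a) / var(a)
  set.seed(21)
  for (i in 1:20) {
    a <- sort(sample(0:500, 15))
    p <- 0.21 * a + rnorm(15, 0, 0.5)
    tab <- calibration_table(p, a)
    expect_equal(fit_calibration(tab)$c_constant,
                 stats::cov(tab$pressure_cmH2O, tab$analog_counts) /
                   stats::var(tab$analog_counts))
  }
  expect_error(fit_calibration(calibration_table(c(1, 2), c(5, 5))),
               "degenerate")
  expect_error(calibration_table(c(1, 2, 3), c(9, 6, 3)), "increase")
})

test_that("a noisy synthetic table recovers its true slope within 2 SE", {
  set.seed(33)
  a <- 0:100
  p <- 0.21 * a + rnorm(length(a), 0, 0.3)
  fit <- fit_calibration(calibration_table(p, a))
  # independent closed-form standard error of the OLS slope
  res <- p - (fit$intercept + fit$c_constant * a)
  se <- sqrt(sum(res^2) / (length(a) - 2) / sum((a - mean(a))^2))
  expect_lt(abs(fit$c_constant - 0.21), 2 * se)
})

test_that("band filtration reproduces the hand-computed oracle", {
  r0 <- band_filter(c(5, 5, 5, 5), filter_config(4, 0.5))
  expect_equal(r0$filtered_mean, 5)
  expect_equal(r0$n_kept, 4)

  r <- band_filter(c(10, 10, 10, 10, 100), filter_config(5, 0.5))
  expect_equal(r$mean, 28)
  expect_equal(r$std_dev, 36)       # population form (divide by n)
  expect_equal(r$std_shrink, 18)    # band [10, 46]
  expect_equal(r$filtered_mean, 10) # the spike is rejected
  expect_equal(r$n_kept, 4)
})

test_that("band filtration stays within the sample range and degrades to the mean", {
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(20, runif(1, -50, 50), runif(1, 0.1, 30))
    r <- band_filter(x, filter_config(20, runif(1, 0, 0.95)))
    expect_gte(r$filtered_mean, min(x))
    expect_lte(r$filtered_mean, max(x))
  }
  # shrink 0 with every sample inside +-1 sd keeps everything: plain mean
  x <- c(1, 3, 1, 3)
  r <- band_filter(x, filter_config(4, 0))
  expect_equal(r$n_kept, 4)
  expect_identical(r$filtered_mean, mean(x))
  # extreme shrink can empty the band; fail-safe returns the raw mean
  r2 <- band_filter(c(0, 10), filter_config(2, 0.99))
  expect_equal(r2$n_kept, 0)
  expect_equal(r2$filtered_mean, 5)
  expect_error(band_filter(1:3, filter_config(5, 0.5)), "expected 5 samples")
  expect_error(filter_config(1), "n")
})

test_that("band filtration beats the raw mean on spike-contaminated data", {
  # one 10-sigma spike in a 10-sample Gaussian window (a spike the raw mean
  # cannot ignore); the filtered mean should be closer to the truth in at
  # least 95% of seeded trials
  mu <- 10; sigma <- 1
  wins <- logical(1000)
  set.seed(1234)
  for (i in seq_along(wins)) {
    x <- rnorm(10, mu, sigma)
    x[sample(10, 1)] <- mu + 10 * sigma
    r <- band_filter(x, filter_config(10, 0.5))
    wins[i] <- abs(r$filtered_mean - mu) < abs(mean(x) - mu)
  }
  expect_gte(mean(wins), 0.95)
})

test_that("the flow-sensor model is an identity with clipping", {
  expect_equal(simulate_flow_sensor(c(-100, 0, 2000)), c(-100, 0, 2000))
  lim <- 250 * 1000 / 60
  expect_equal(simulate_flow_sensor(c(-1e6, 1e6)), c(-lim, lim))
  # integrating the sensed flow over a synthetic breath recovers the volume
  dt <- 0.001
  t <- seq(0, 2, by = dt)
  q <- 600 * sin(pi * t / 2)^2          # ml/s
  v_true <- sum(q) * dt
  sensed <- simulate_flow_sensor(q, noise_sd = 2, seed = 99)
  v_sensed <- sum(sensed) * dt
  se <- 2 * sqrt(length(t)) * dt
  expect_lt(abs(v_sensed - v_true), 4 * se)
})
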