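#' Named MPX2010DP conversion-constant presets
#'
#' Two values of the analog-to-cmH2O slope `C` are in circulation for the
#' MPX2010DP + LM358 chain: `"fitted"` (0.208879), the least-squares slope of
#' the packaged water-column calibration table and the package default, and
#' `"nominal"` (0.20916), the mean-of-increments constant from the original
#' syringe experiment.
#'
#' @format Named numeric vector of length 2.
#' @export
mpx2010_constants <- c(fitted = 0.208879, nominal = 0.20916)

#' Pressure-sensor calibration
#'
#' Linear calibration of the amplified MPX2010DP analog reading:
#' `pressure = (analog - analog_offset) * c_constant`.
#'
#' @param analog_offset Zero-pressure analog reading, counts.
#' @param c_constant Slope, cmH2O per count (> 0). Default is the fitted
#'   preset in [mpx2010_constants].
#' @return An object of class `sensor_calibration`.
#' @export
sensor_calibration <- function(analog_offset = 102,
                               c_constant = mpx2010_constants[["fitted"]]) {
  stopifnot(is.finite(analog_offset), is.finite(c_constant), c_constant > 0)
  structure(list(analog_offset = analog_offset, c_constant = c_constant),
            class = "sensor_calibration")
}

#' Convert an analog pressure reading to cmH2O
#'
#' @param analog Analog reading(s), counts.
#' @param cal A [sensor_calibration()].
#' @return Pressure in cmH2O.
#' @examples
#' cal <- sensor_calibration(analog_offset = 0)
#' analog_to_cmH2O(96, cal) # ~20.05 cmH2O
#' @export
analog_to_cmH2O <- function(analog, cal = sensor_calibration()) {
  stopifnot(inherits(cal, "sensor_calibration"))
  (analog - cal$analog_offset) * cal$c_constant
}

#' Forward model of the pressure-sensing chain
#'
#' Simulates the MPX2010DP + amplifier + 10-bit ADC chain: the true pressure
#' is mapped through the inverse calibration, Gaussian analog noise is added,
#' and the result is rounded to integer counts and clipped to the ADC range.
#'
#' @param true_pressure True airway pressure(s), cmH2O.
#' @param cal A [sensor_calibration()].
#' @param noise_sd Analog noise standard deviation, counts (>= 0).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @param adc_range Two-element ADC saturation bounds in counts.
#' @return Integer analog counts.
#' @export
simulate_pressure_sensor <- function(true_pressure, cal = sensor_calibration(),
                                     noise_sd = 0, seed = NULL,
                                     adc_range = c(0, 1023)) {
  stopifnot(noise_sd >= 0)
  n <- length(true_pressure)
  eps <- if (noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(n, 0, noise_sd)
    else with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else 0
  counts <- round(true_pressure / cal$c_constant + cal$analog_offset + eps)
  pmin(adc_range[2], pmax(adc_range[1], counts))
}

#' Forward model of the SFM3300 flow sensor
#'
#' Adds seeded Gaussian noise to the true flow and clips to the sensor's
#' bidirectional range (+-250 slm = +-4166.7 ml/s). The SFM3300 needs no
#' calibration.
#'
#' @param true_flow True flow(s), ml/s.
#' @param noise_sd Noise standard deviation, ml/s (>= 0).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @param range Two-element saturation bounds, ml/s.
#' @return Sensed flow in ml/s.
#' @export
simulate_flow_sensor <- function(true_flow, noise_sd = 0, seed = NULL,
                                 range = c(-250, 250) * 1000 / 60) {
  stopifnot(noise_sd >= 0)
  n <- length(true_flow)
  eps <- if (noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(n, 0, noise_sd)
    else with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else 0
  pmin(range[2], pmax(range[1], true_flow + eps))
}

#' Calibration table of pressure vs offset-subtracted analog counts
#'
#' @param pressure Pressures, cmH2O.
#' @param analog Offset-subtracted analog readings, counts. Readings must
#'   trend upward with pressure (local inversions from measurement noise are
#'   tolerated; an overall non-increasing trend is rejected).
#' @return A `data.frame` of class `calibration_table` with columns
#'   `pressure_cmH2O` and `analog_counts`, ordered by pressure.
#' @export
calibration_table <- function(pressure, analog) {
  if (length(pressure) < 2 || length(pressure) != length(analog))
    stop("a calibration table needs >= 2 (pressure, analog) rows")
  if (any(!is.finite(pressure)) || any(!is.finite(analog)))
    stop("calibration values must be finite")
  o <- order(pressure)
  pressure <- pressure[o]; analog <- analog[o]
  if (stats::sd(analog) > 0 && stats::sd(pressure) > 0 &&
      stats::cor(pressure, analog) <= 0)
    stop("analog readings must increase with pressure")
  structure(data.frame(pressure_cmH2O = pressure, analog_counts = analog),
            class = c("calibration_table", "data.frame"))
}

#' Read a two-column calibration table from CSV
#'
#' The packaged MPX2010DP water-column calibration table (21 points spanning
#' 0-20 cmH2O) ships at
#' `system.file("extdata", "mpx2010_calibration.csv", package = "ventsim")`.
#'
#' @param path Path to a CSV with pressure (cmH2O) in the first column and
#'   offset-subtracted analog counts in the second.
#' @return A [calibration_table()].
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("calibration CSV needs two columns")
  calibration_table(df[[1]], df[[2]])
}

#' Fit the analog-to-cmH2O conversion constant
#'
#' Ordinary least squares (with intercept) of pressure on analog counts; the
#' slope is the conversion constant `C` of [analog_to_cmH2O()]. On the
#' packaged MPX2010DP table the fitted slope is 0.208879 cmH2O/count.
#'
#' @param table A [calibration_table()].
#' @return A list with `c_constant` (the slope), `intercept`, `r_squared` and
#'   `n`.
#' @examples
#' tab <- read_calibration_table(system.file("extdata",
#'   "mpx2010_calibration.csv", package = "ventsim"))
#' fit_calibration(tab)$c_constant
#' @export
fit_calibration <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  if (length(unique(table$analog_counts)) < 2)
    stop("degenerate calibration table: all analog readings equal")
  fit <- stats::lm(pressure_cmH2O ~ analog_counts, data = table)
  ss_tot <- sum((table$pressure_cmH2O - mean(table$pressure_cmH2O))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(c_constant = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(table))
}

#' Band-filter configuration
#'
#' @param n Window size in samples (>= 2).
#' @param shrink_percent Band-shrink fraction in \[0, 1).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(n = 50, shrink_percent = 0.5) {
  if (!is.numeric(n) || n < 2) stop("filter window `n` must be >= 2")
  if (shrink_percent < 0 || shrink_percent >= 1)
    stop("`shrink_percent` must be in [0, 1)")
  structure(list(n = as.integer(n), shrink_percent = shrink_percent),
            class = "filter_config")
}

#' Outlier-band sensor filtration
#'
#' The firmware's spike-rejection statistic. Over a window of `n` samples it
#' computes the mean, the population standard deviation (divide by n), a
#' shrunk envelope `std_shrink = std_dev * (1 - shrink_percent)`, and the mean
#' of the samples falling inside the data band
#' `[mean - std_shrink, mean + std_shrink]` (boundaries inclusive). If no
#' sample falls in the band the unfiltered mean is returned as a fail-safe.
#'
#' @param samples Numeric vector of sensor samples; length must equal `cfg$n`.
#' @param cfg A [filter_config()].
#' @return A list of class `filter_result` with `mean`, `std_dev`,
#'   `std_shrink`, `filtered_mean` and `n_kept`.
#' @examples
#' band_filter(c(10, 10, 10, 10, 100), filter_config(5, 0.5))
#' @export
band_filter <- function(samples, cfg = filter_config(length(samples))) {
  stopifnot(inherits(cfg, "filter_config"))
  if (length(samples) != cfg$n)
    stop(sprintf("expected %d samples, got %d", cfg$n, length(samples)))
  m <- sum(samples) / cfg$n
  std_dev <- sqrt(sum((samples - m)^2) / cfg$n)  # population form
  std_shrink <- std_dev - std_dev * cfg$shrink_percent
  inband <- samples >= m - std_shrink & samples <= m + std_shrink
  n_kept <- sum(inband)
  filtered_mean <- if (n_kept > 0) mean(samples[inband]) else m
  structure(list(mean = m, std_dev = std_dev, std_shrink = std_shrink,
                 filtered_mean = filtered_mean, n_kept = n_kept),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "<filter_result> mean %.4g, sd %.4g, band +-%.4g, filtered mean %.4g (%d kept)\n",
    x$mean, x$std_dev, x$std_shrink, x$filtered_mean, x$n_kept))
  invisible(x)
}
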