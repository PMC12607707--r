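## Environmental telemetry: record construction, CSV persistence in the
## deployed column layout, welfare-threshold compliance, and sensor
## calibration statistics (mean error, expanded uncertainty at a coverage
## probability, root-sum-square combination with the reference instrument).

.ENV_COLS <- c(time = "Time", wind = "Wind Speed (m/s)",
               pressure = "Air Pressure (hPa)", nh3 = "NH3 (ppm)",
               co2 = "CO2 (ppm)", temperature = "Temperature (C)",
               humidity = "Humidity (%)", light = "Light Intensity (lux)",
               location = "Sample Location")

.emptyEnv <- function() {
  out <- data.frame(time = character(), wind = numeric(),
                    pressure = numeric(), nh3 = numeric(), co2 = numeric(),
                    temperature = numeric(), humidity = numeric(),
                    light = numeric(), location = character())
  out
}

#' Construct an environmental telemetry record
#'
#' One telemetry row: the six measured parameters plus acquisition time and
#' cage location.
#'
#' @param time Acquisition time, `MMDD-HH:MM:SS` (e.g. `"0604-10:53:45"`).
#' @param wind Wind speed (m/s, non-negative).
#' @param pressure Air pressure (hPa).
#' @param nh3 Ammonia concentration (ppm).
#' @param co2 Carbon dioxide concentration (ppm).
#' @param temperature Air temperature (degrees C).
#' @param humidity Relative humidity (%RH, 0-100).
#' @param light Illumination (lux).
#' @param location Cage coordinate rendered `"x-y"` (e.g. `"1-1"`).
#' @return A one-row data.frame.
#' @export
envRecord <- function(time, wind, pressure, nh3, co2, temperature, humidity,
                      light, location) {
  vals <- c(wind, pressure, nh3, co2, temperature, humidity, light)
  if (any(!is.finite(vals))) stop("environmental values must be finite")
  if (wind < 0) stop("wind speed must be non-negative")
  if (humidity < 0 || humidity > 100) stop("humidity must lie in [0, 100]")
  data.frame(time = time, wind = wind, pressure = pressure, nh3 = nh3,
             co2 = co2, temperature = temperature, humidity = humidity,
             light = light, location = location)
}

#' Welfare thresholds for the rabbit house
#'
#' Defaults follow common husbandry guidance: ammonia below 20 ppm, CO2
#' below 3000 ppm, temperature 15-25 C, humidity 60-70 %RH, illumination
#' 50-100 lux, wind speed 0.1-0.2 m/s; atmospheric pressure is left at
#' natural levels and never assessed.
#'
#' @param nh3Max,co2Max Upper bounds (ppm); values at or above flag.
#' @param tempRange,humidityRange,lightRange,windRange Closed intervals.
#' @return A list of class `WelfareThresholds`.
#' @export
welfareThresholds <- function(nh3Max = 20, co2Max = 3000,
                              tempRange = c(15, 25),
                              humidityRange = c(60, 70),
                              lightRange = c(50, 100),
                              windRange = c(0.1, 0.2)) {
  for (r in list(tempRange, humidityRange, lightRange, windRange))
    stopifnot(length(r) == 2L, r[1] <= r[2])
  structure(list(nh3Max = nh3Max, co2Max = co2Max, tempRange = tempRange,
                 humidityRange = humidityRange, lightRange = lightRange,
                 windRange = windRange),
            class = "WelfareThresholds")
}

#' Assess one telemetry record against welfare thresholds
#'
#' Upper-bound parameters (NH3, CO2) flag `above-range` when the value
#' reaches the bound ("controlled below" is read strictly). Interval
#' parameters flag `below-range` / `above-range` outside their closed
#' interval. Pressure is always `not-assessed` and never affects the overall
#' verdict.
#'
#' @param record A one-row data.frame from [envRecord()] (or a session CSV
#'   row).
#' @param thresholds [welfareThresholds()].
#' @return A list of class `ComplianceReport` with `verdicts` (named
#'   character vector) and `overall` (`TRUE` iff every assessed parameter is
#'   compliant).
#' @export
assessWelfare <- function(record, thresholds = welfareThresholds()) {
  upper <- function(value, bound)
    if (value >= bound) "above-range" else "compliant"
  interval <- function(value, range)
    if (value < range[1]) "below-range"
    else if (value > range[2]) "above-range" else "compliant"
  verdicts <- c(
    wind = interval(record$wind, thresholds$windRange),
    pressure = "not-assessed",
    nh3 = upper(record$nh3, thresholds$nh3Max),
    co2 = upper(record$co2, thresholds$co2Max),
    temperature = interval(record$temperature, thresholds$tempRange),
    humidity = interval(record$humidity, thresholds$humidityRange),
    light = interval(record$light, thresholds$lightRange))
  assessed <- verdicts[verdicts != "not-assessed"]
  structure(list(verdicts = verdicts, overall = all(assessed == "compliant")),
            class = "ComplianceReport")
}

#' @export
print.ComplianceReport <- function(x, ...) {
  cat("ComplianceReport:", if (x$overall) "compliant" else "NON-compliant", "\n")
  for (nm in names(x$verdicts))
    cat(sprintf("  %-12s %s\n", nm, x$verdicts[[nm]]))
  invisible(x)
}

#' Sensor calibration error statistics
#'
#' For paired readings of the module under test and a reference instrument,
#' computes the signed mean error and the expanded uncertainty `k * s`,
#' where `s` is the sample standard deviation of the errors (n-1
#' denominator) and `k` the two-sided Student-t quantile at the coverage
#' probability with n-1 degrees of freedom (k = 2.201 for n = 12 at 95%).
#'
#' @param module,reference Numeric vectors of paired readings (same units).
#' @param coverage Coverage probability (default 0.95).
#' @return A list with `meanError`, `expandedUncertainty`, `k`, `s`, `n`,
#'   `coverage`.
#' @export
sensorErrorStats <- function(module, reference, coverage = 0.95) {
  if (length(module) != length(reference))
    stop("module and reference readings must be paired")
  n <- length(module)
  if (n < 2L) stop("insufficient data: at least 2 pairs required")
  e <- module - reference
  s <- sd(e)
  k <- qt(1 - (1 - coverage) / 2, df = n - 1)
  list(meanError = mean(e), expandedUncertainty = k * s, k = k, s = s,
       n = n, coverage = coverage)
}

#' Combine independent uncertainty components
#'
#' Root-sum-square of the module's expanded uncertainty and the reference
#' instrument's nominal uncertainty: `sqrt(u1^2 + u2^2)`.
#'
#' @param uModule,uReference Non-negative uncertainties (same units).
#' @return The combined uncertainty.
#' @examples
#' combinedUncertainty(2.8, 3)   # 4.10 (%RH)
#' @export
combinedUncertainty <- function(uModule, uReference) {
  if (any(uModule < 0) || any(uReference < 0))
    stop("uncertainties must be non-negative")
  sqrt(uModule^2 + uReference^2)
}

#' Reference CO2 uncertainty at a measured value
#'
#' The reference CO2 detector's nominal uncertainty is value-dependent:
#' +-(40 ppm + 3% of the measured value), evaluated at each reference
#' reading.
#'
#' @param measuredPpm Reference reading(s) (ppm).
#' @return Uncertainty (ppm), vectorized.
#' @export
co2ReferenceUncertainty <- function(measuredPpm) {
  stopifnot(all(measuredPpm >= 0))
  40 + 0.03 * measuredPpm
}

#' Write / read environmental telemetry CSV
#'
#' One header row in the deployed column order (`Time`, `Wind Speed (m/s)`,
#' `Air Pressure (hPa)`, `NH3 (ppm)`, `CO2 (ppm)`, `Temperature (C)`,
#' `Humidity (%)`, `Light Intensity (lux)`, `Sample Location`) plus one row
#' per record. The round trip is lossless for values up to 15 significant
#' digits.
#'
#' @param records A data.frame of [envRecord()] rows.
#' @param path CSV file path.
#' @return `readEnvCsv()` returns the records data.frame (canonical column
#'   names); `writeEnvCsv()` the path, invisibly.
#' @export
writeEnvCsv <- function(records, path) {
  lines <- paste(.ENV_COLS, collapse = ",")
  if (nrow(records)) {
    fmtNum <- function(x) vapply(x, function(v) format(v, digits = 15),
                                 character(1))
    body <- paste(records$time, fmtNum(records$wind), fmtNum(records$pressure),
                  fmtNum(records$nh3), fmtNum(records$co2),
                  fmtNum(records$temperature), fmtNum(records$humidity),
                  fmtNum(records$light), records$location, sep = ",")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeEnvCsv
#' @export
readEnvCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c("character", rep("numeric", 7), "character"))
  missing <- setdiff(unname(.ENV_COLS), names(df))
  if (length(missing))
    stop("environment CSV missing columns: ", paste(missing, collapse = ", "))
  out <- df[, unname(.ENV_COLS)]
  names(out) <- names(.ENV_COLS)
  out
}
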