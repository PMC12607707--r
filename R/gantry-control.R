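## Banded deviation-correction controller for the dual-drive X axis, plus a
## closed-loop plant simulator to exercise it. The adjustable unit on the
## left rail is the reference; only the fixed (right) unit's speed is
## modulated. Encoders are absolute, quantized to 1 mm.

#' Deviation bands and corrective gains
#'
#' The controller compares the absolute left-right encoder difference
#' against three thresholds: below `normalMax` (50 mm) no action; in
#' `[normalMax, mildMax)` (50-70 mm) the right unit runs at 120% or 80% of
#' its commanded speed; in `[mildMax, severeMax)` (70-100 mm) at 140% or
#' 60%; at or beyond `severeMax` (100 mm) the system halts and alarms. All
#' bands are half-open at the left edge.
#'
#' @param normalMax,mildMax,severeMax Band thresholds (mm), strictly
#'   increasing.
#' @param mildGain,severeGain Fractional speed corrections in (0, 1).
#' @return A list of class `DeviationBands`.
#' @export
deviationBands <- function(normalMax = 50, mildMax = 70, severeMax = 100,
                           mildGain = 0.20, severeGain = 0.40) {
  stopifnot(0 < normalMax, normalMax < mildMax, mildMax < severeMax,
            mildGain > 0, mildGain < 1, severeGain > 0, severeGain < 1)
  structure(list(normalMax = normalMax, mildMax = mildMax,
                 severeMax = severeMax, mildGain = mildGain,
                 severeGain = severeGain),
            class = "DeviationBands")
}

#' Compute the speed command for the adjusted (right) drive unit
#'
#' Given the two quantized encoder readings and the direction of travel,
#' returns the multiplier applied to the right unit's commanded speed, or a
#' halt-with-alarm when the deviation reaches the severe limit. "Trailing"
#' is evaluated with respect to the direction of travel: moving forward the
#' right unit trails when its encoder reads less than the left one; moving
#' backward the comparison reverses.
#'
#' @param encoderLeft,encoderRight Encoder positions (mm).
#' @param direction `"forward"` or `"backward"`.
#' @param bands [deviationBands()].
#' @return A list with `multiplier` (one of 0.6, 0.8, 1.0, 1.2, 1.4, or 0
#'   when halted), `halt`, `alarm`, and `deviation` (mm).
#' @examples
#' deviationCommand(1030, 1000, "forward")   # in band: multiplier 1.0
#' deviationCommand(1060, 1000, "forward")   # right trails by 60: 1.2
#' deviationCommand(1000, 1085, "forward")   # right leads by 85: 0.6
#' deviationCommand(1120, 1000, "forward")   # 120 mm: halt + alarm
#' @export
deviationCommand <- function(encoderLeft, encoderRight,
                             direction = c("forward", "backward"),
                             bands = deviationBands()) {
  direction <- match.arg(direction)
  stopifnot(is.finite(encoderLeft), is.finite(encoderRight))
  d <- abs(encoderLeft - encoderRight)
  if (d >= bands$severeMax)
    return(list(multiplier = 0, halt = TRUE, alarm = TRUE, deviation = d))
  trailing <- if (direction == "forward") encoderRight < encoderLeft
              else encoderRight > encoderLeft
  multiplier <- if (d < bands$normalMax) 1.0
    else if (d < bands$mildMax) 1 + if (trailing) bands$mildGain else -bands$mildGain
    else 1 + if (trailing) bands$severeGain else -bands$severeGain
  list(multiplier = multiplier, halt = FALSE, alarm = FALSE, deviation = d)
}

#' Per-side drive drift profile
#'
#' Models the disturbances that desynchronize the two X-axis drives: uneven
#' rails, wheel diameter differences, motor/reducer speed differences and
#' asymmetric load. Each side's effective speed is
#' `commanded * multiplier * (1 + bias) + noise`, with an optional
#' position-dependent additive bias (rail slope / joints).
#'
#' @param biasLeft,biasRight Multiplicative speed bias per side (fraction;
#'   e.g. `-0.05` for a 5% slow right drive).
#' @param noiseSd Additive Gaussian speed noise scale (m/s), drawn per side
#'   per control cycle.
#' @param posBias Optional `function(posMm, side)` returning an additive
#'   speed bias (m/s); `side` is `"left"` or `"right"`.
#' @return A list of class `DriftProfile`.
#' @export
driftProfile <- function(biasLeft = 0, biasRight = 0, noiseSd = 0,
                         posBias = NULL) {
  stopifnot(is.finite(biasLeft), is.finite(biasRight), noiseSd >= 0)
  structure(list(biasLeft = biasLeft, biasRight = biasRight,
                 noiseSd = noiseSd, posBias = posBias),
            class = "DriftProfile")
}

#' Initial gantry state
#'
#' @param posLeft,posRight Positions along X of the left (reference) and
#'   right (adjusted) drive units (mm); must lie on the 0-50000 mm rails.
#' @param alarmLatched Whether a previous alarm is still latched.
#' @param railLengthMm Rail length (mm).
#' @return A list of class `GantryState`.
#' @export
gantryState <- function(posLeft = 0, posRight = 0, alarmLatched = FALSE,
                        railLengthMm = 50000) {
  stopifnot(posLeft >= 0, posLeft <= railLengthMm,
            posRight >= 0, posRight <= railLengthMm)
  structure(list(posLeft = posLeft, posRight = posRight,
                 alarmLatched = alarmLatched, railLengthMm = railLengthMm),
            class = "GantryState")
}

#' Reset a latched alarm after human intervention
#'
#' @param state A `GantryState`.
#' @return The state with the alarm cleared.
#' @export
resetAlarm <- function(state) {
  state$alarmLatched <- FALSE
  state
}

#' Simulate a closed-loop X-axis traverse
#'
#' Integrates both drive sides at `1/dt` Hz. Each cycle the controller reads
#' the quantized (1 mm) encoders, issues a [deviationCommand()] for the
#' right unit, and both sides advance with their drift-perturbed effective
#' speeds. The run ends when the reference (left) side is within
#' `tolMm` of the target, or immediately when the alarm fires (the alarm is
#' latched until [resetAlarm()]). Identical seeds and configurations yield
#' identical trajectories.
#'
#' @param start [gantryState()] to start from.
#' @param targetMm Target X position of the reference side (mm).
#' @param speed Commanded set-point speed (m/s), within the 0.05-0.3 m/s
#'   X-axis envelope.
#' @param drift [driftProfile()].
#' @param bands [deviationBands()].
#' @param dt Control cycle period (s); default 0.1 (10 Hz).
#' @param seed Integer seed for the speed noise.
#' @param tolMm Stop tolerance around the target (mm); default the system's
#'   +-10 mm positioning accuracy.
#' @param maxTime Safety cap on simulated time (s); default 3x the nominal
#'   travel time plus 60 s.
#' @return A list with `log` (data.frame: `time_s`, `pos_left_mm`,
#'   `pos_right_mm`, `deviation_mm`, `multiplier`, `alarm`), `state` (final
#'   `GantryState`), `stopErrorMm` (`NA` when the run ended on alarm or
#'   timeout), and flags `alarm`, `reachedTarget`.
#' @export
simulateTravel <- function(start = gantryState(), targetMm, speed = 0.05,
                           drift = driftProfile(), bands = deviationBands(),
                           dt = 0.1, seed = 1, tolMm = 10, maxTime = NULL) {
  stopifnot(speed >= 0.05, speed <= 0.3, dt > 0,
            targetMm >= 0, targetMm <= start$railLengthMm)
  if (start$alarmLatched)
    stop("alarm is latched; call resetAlarm() before resuming")
  set.seed(as.integer(seed))
  posL <- start$posLeft; posR <- start$posRight
  sgn <- if (targetMm >= posL) 1 else -1
  direction <- if (sgn > 0) "forward" else "backward"
  if (is.null(maxTime))
    maxTime <- 3 * abs(targetMm - posL) / (speed * 1000) + 60
  nCap <- ceiling(maxTime / dt) + 2L
  tV <- pL <- pR <- dV <- mV <- numeric(nCap)
  aV <- logical(nCap)
  n <- 0L; t <- 0; alarm <- FALSE; reached <- abs(posL - targetMm) <= tolMm
  pbias <- function(pos, side)
    if (is.null(drift$posBias)) 0 else drift$posBias(pos, side)

  while (!reached && !alarm && t < maxTime) {
    encL <- floor(posL); encR <- floor(posR)
    cmd <- deviationCommand(encL, encR, direction, bands)
    if (cmd$halt) {
      alarm <- TRUE
      n <- n + 1L
      tV[n] <- t; pL[n] <- posL; pR[n] <- posR
      dV[n] <- abs(posL - posR); mV[n] <- 0; aV[n] <- TRUE
      break
    }
    vL <- speed * (1 + drift$biasLeft) + pbias(posL, "left") +
      rnorm(1, 0, drift$noiseSd)
    vR <- speed * cmd$multiplier * (1 + drift$biasRight) +
      pbias(posR, "right") + rnorm(1, 0, drift$noiseSd)
    posL <- posL + sgn * vL * dt * 1000
    posR <- posR + sgn * vR * dt * 1000
    t <- t + dt
    ## post-move guard so no logged sample can exceed the severe limit
    ## without the alarm flag set at that same sample
    postAlarm <- abs(floor(posL) - floor(posR)) >= bands$severeMax
    n <- n + 1L
    tV[n] <- t; pL[n] <- posL; pR[n] <- posR
    dV[n] <- abs(posL - posR); mV[n] <- cmd$multiplier; aV[n] <- postAlarm
    if (postAlarm) { alarm <- TRUE; break }
    if (sgn * (posL - targetMm) >= -tolMm) reached <- TRUE
  }
  idx <- seq_len(n)
  state <- gantryState(min(max(posL, 0), start$railLengthMm),
                       min(max(posR, 0), start$railLengthMm),
                       alarmLatched = alarm,
                       railLengthMm = start$railLengthMm)
  list(log = data.frame(time_s = tV[idx], pos_left_mm = pL[idx],
                        pos_right_mm = pR[idx], deviation_mm = dV[idx],
                        multiplier = mV[idx], alarm = aV[idx]),
       state = state,
       stopErrorMm = if (reached) abs(posL - targetMm) else NA_real_,
       alarm = alarm, reachedTarget = reached)
}

#' Write a trajectory log to CSV
#'
#' @param result A [simulateTravel()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(result, path) {
  utils::write.csv(result$log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the Z-axis operating posture
#'
#' Three postures: lower-tier imaging with the arm vertical (0 deg), upper-tier
#' imaging with the arm rotated to 30 deg (extending the effective arm to about
#' 86.6 cm so the camera sits about 38.4 cm above the cage), and obstacle
#' bypass with the module lifted 65 cm toward the Y-axis beam. Bypass takes
#' precedence over the tier.
#'
#' @param tier `"lower"` or `"upper"`.
#' @param bypassObstacle Lift the module to clear overhead lighting.
#' @param effectiveArmUpperCm Configured effective arm length at 30 deg (cm).
#' @return A list with `mode`, `armAngleDeg`, `liftCm`, `effectiveArmCm`.
#' @export
selectPosture <- function(tier = c("lower", "upper"), bypassObstacle = FALSE,
                          effectiveArmUpperCm = 86.6) {
  tier <- match.arg(tier)
  if (bypassObstacle)
    return(list(mode = "obstacle-bypass", armAngleDeg = 0, liftCm = 65,
                effectiveArmCm = 80))
  if (tier == "upper")
    list(mode = "upper-tier", armAngleDeg = 30, liftCm = 0,
         effectiveArmCm = effectiveArmUpperCm)
  else
    list(mode = "lower-tier", armAngleDeg = 0, liftCm = 0,
         effectiveArmCm = 80)
}
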