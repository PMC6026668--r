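#' Charge diffusion time across one channel spacing
#'
#' One-dimensional mean-squared-displacement estimate `t = x^2 / (2 D)` —
#' the most conservative (fastest) estimate of how long diffusing Na+ charge
#' needs to spread from one ion channel to the next.
#'
#' @param spacingUm inter-channel distance, um (>= 0).
#' @param D diffusion coefficient, m^2/s (> 0). The default is the handbook
#'   value for Na+ in water at 25 C.
#' @return time in seconds.
#' @examples
#' diffusionTime(1.5)  # ~8.46e-4 s
#' @export
diffusionTime <- function(spacingUm, D = 1.33e-9) {
  .assertScalar(spacingUm, "spacingUm", min = 0)
  .assertScalar(D, "D", min = 0, strict = TRUE)
  .um_to_m(spacingUm)^2 / (2 * D)
}

#' Ratio of diffusive charge speed to the required propagation speed
#'
#' The effective speed of diffusing charge over one spacing is
#' `x / diffusionTime(x, D) = 2 D / x`; dividing by the speed the action
#' potential actually travels gives a dimensionless ratio. At the measured
#' spacing range's upper end (5 um) with the standard Na+ diffusion
#' coefficient and 1 m/s required speed the ratio is about 5e-4 — below
#' 1/1000, so charge diffusion alone cannot carry propagation.
#'
#' @param spacingUm inter-channel distance, um (> 0).
#' @param D diffusion coefficient, m^2/s (> 0).
#' @param requiredVelocity propagation speed to match, m/s (> 0).
#' @return dimensionless speed ratio.
#' @examples
#' chargeSpeedRatio(5)    # ~5.3e-4, < 1/1000
#' chargeSpeedRatio(1.5)  # ~1.8e-3
#' @export
chargeSpeedRatio <- function(spacingUm, D = 1.33e-9, requiredVelocity = 1) {
  .assertScalar(spacingUm, "spacingUm", min = 0, strict = TRUE)
  .assertScalar(requiredVelocity, "requiredVelocity", min = 0, strict = TRUE)
  chargeSpeed <- 2 * D / .um_to_m(spacingUm)
  chargeSpeed / requiredVelocity
}

#' Temporal accuracy of threshold timing
#'
#' The time for the threshold front to pass between adjacent ion channels:
#' spacing / velocity. At 1 um spacing and 1 m/s this is 1 us — the maximum
#' point of accuracy for phase-ternary computation.
#'
#' @param spacingUm inter-channel distance, um (>= 0).
#' @param velocity conduction speed, m/s (> 0).
#' @return time in seconds.
#' @examples
#' temporalAccuracy(1, 1)  # 1e-6 s
#' @export
temporalAccuracy <- function(spacingUm, velocity = 1) {
  .assertScalar(spacingUm, "spacingUm", min = 0)
  .assertScalar(velocity, "velocity", min = 0, strict = TRUE)
  .um_to_m(spacingUm) / velocity
}

#' Precision gain between two timing accuracies
#'
#' Ratio of a coarse timing accuracy to a fine one — e.g. millisecond-level
#' waveform timing versus microsecond-level threshold timing gives a factor
#' of 1000.
#'
#' @param coarseAccuracy coarse accuracy, s (> 0).
#' @param fineAccuracy fine accuracy, s (> 0).
#' @return dimensionless factor `coarseAccuracy / fineAccuracy`.
#' @examples
#' precisionGain(1e-3, 1e-6)  # 1000
#' @export
precisionGain <- function(coarseAccuracy, fineAccuracy) {
  .assertScalar(coarseAccuracy, "coarseAccuracy", min = 0, strict = TRUE)
  .assertScalar(fineAccuracy, "fineAccuracy", min = 0, strict = TRUE)
  coarseAccuracy / fineAccuracy
}

#' Moens-Korteweg pulse-wave velocity
#'
#' Textbook form `PWV = sqrt(E h / (rho d))` for a pressure pulse in an
#' elastic tube: velocity grows with the square root of the wall's elastic
#' modulus. Used to model the fast pulse-wave conduction of a myelinated
#' stretch, where the rigid sheath guides the soliton as a cytoplasmic
#' pressure wave.
#'
#' @param elasticModulus incremental elastic modulus of the wall, Pa (> 0).
#' @param wallThickness wall (sheath) thickness, m (> 0).
#' @param fluidDensity fluid density, kg/m^3 (> 0).
#' @param diameter tube diameter, m (> 0).
#' @return velocity in m/s.
#' @examples
#' moensKortewegVelocity(4e5, 1e-6, 1000, 1e-6)  # 20 m/s
#' @export
moensKortewegVelocity <- function(elasticModulus, wallThickness,
                                  fluidDensity, diameter) {
  .assertScalar(elasticModulus, "elasticModulus", min = 0, strict = TRUE)
  .assertScalar(wallThickness, "wallThickness", min = 0, strict = TRUE)
  .assertScalar(fluidDensity, "fluidDensity", min = 0, strict = TRUE)
  .assertScalar(diameter, "diameter", min = 0, strict = TRUE)
  sqrt(elasticModulus * wallThickness / (fluidDensity * diameter))
}

#' Full feasibility report
#'
#' Combines the diffusion-time, charge-speed and temporal-accuracy
#' calculations into one report with a verdict: charge diffusion is
#' "insufficient" for propagation whenever the speed ratio is below 1.
#'
#' @param spacingUm inter-channel distance, um (> 0).
#' @param D Na+ diffusion coefficient, m^2/s (> 0).
#' @param requiredVelocity propagation speed to match, m/s (> 0).
#' @param ionicRadiusPm Na+ ionic radius, pm (informational only).
#' @return A [FeasibilityReport-class].
#' @examples
#' feasibilityReport(5)  # verdict: insufficient
#' @export
feasibilityReport <- function(spacingUm = 5, D = 1.33e-9,
                              requiredVelocity = 1, ionicRadiusPm = 116) {
  dt <- diffusionTime(spacingUm, D)
  ratio <- chargeSpeedRatio(spacingUm, D, requiredVelocity)
  new("FeasibilityReport",
      diffusionTime = dt,
      chargeSpeed = 2 * D / .um_to_m(spacingUm),
      speedRatio = ratio,
      temporalAccuracy = temporalAccuracy(spacingUm, requiredVelocity),
      verdict = if (ratio < 1) "insufficient" else "sufficient",
      params = list(channelSpacingUm = spacingUm, diffusionCoefficient = D,
                    requiredVelocity = requiredVelocity,
                    ionicRadiusPm = ionicRadiusPm))
}

#' Serialize a feasibility report to a plain list
#'
#' Handy for JSON output from scripts.
#'
#' @param report a [FeasibilityReport-class].
#' @return a named list of scalars.
#' @export
feasibilityAsList <- function(report) {
  stopifnot(is(report, "FeasibilityReport"))
  c(report@params,
    list(diffusion_time_s = report@diffusionTime,
         charge_speed_m_per_s = report@chargeSpeed,
         speed_ratio = report@speedRatio,
         temporal_accuracy_s = report@temporalAccuracy,
         verdict = report@verdict))
}
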