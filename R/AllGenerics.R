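#' Accessors for capnet objects
#'
#' `graphNodes()` and `graphSegments()` return the node and segment tables of
#' a [NeuriteGraph-class]; `stimuli()` the stimulus table of a
#' [StimulusSchedule-class]; `events()`, `arrivalTimes()` and `counters()`
#' the event table, per-terminal arrival lists and conservation counters of
#' an [EventLog-class]; `redactionFraction()` the headline fraction of a
#' [RedactionReport-class].
#'
#' @param x the object.
#' @return A data.frame (`graphNodes`, `graphSegments`, `stimuli`, `events`),
#'   a named list of numeric vectors (`arrivalTimes`), a named numeric vector
#'   (`counters`), or a single numeric (`redactionFraction`).
#' @name accessors
#' @aliases graphNodes graphSegments stimuli events arrivalTimes counters
#'   redactionFraction
NULL

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphSegments", function(x) standardGeneric("graphSegments"))

#' @rdname accessors
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("arrivalTimes", function(x) standardGeneric("arrivalTimes"))

#' @rdname accessors
#' @export
setGeneric("counters", function(x) standardGeneric("counters"))

#' @rdname accessors
#' @export
setGeneric("redactionFraction", function(x) standardGeneric("redactionFraction"))

#' @rdname accessors
setMethod("graphNodes", "NeuriteGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("graphSegments", "NeuriteGraph", function(x) x@segments)

#' @rdname accessors
setMethod("stimuli", "StimulusSchedule", function(x) x@stimuli)

#' @rdname accessors
setMethod("events", "EventLog", function(x) x@events)

#' @rdname accessors
setMethod("arrivalTimes", "EventLog", function(x) x@arrivals)

#' @rdname accessors
setMethod("counters", "EventLog", function(x) x@counters)

#' @rdname accessors
setMethod("redactionFraction", "RedactionReport", function(x) x@redactionFraction)

setMethod("show", "MembraneDynamics", function(object) {
  cat(sprintf(
    "MembraneDynamics: v = %g m/s, tau = %g ms, spacing = %g um,\n  dissipation = %g /um, threshold = %g, myelinated = %s\n",
    object@velocity, object@refractoryDuration * 1e3, object@channelSpacing,
    object@dissipationRate, object@activationThreshold, object@myelinated))
})

setMethod("show", "NeuriteGraph", function(object) {
  roles <- table(factor(object@nodes$role, levels = .NODE_ROLES))
  cat(sprintf("NeuriteGraph: %d nodes, %d segments\n",
              nrow(object@nodes), nrow(object@segments)))
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = " "),
      "\n")
  if (nrow(object@segments))
    cat(sprintf("  total length %.1f um\n", sum(object@segments$length_um)))
})

setMethod("show", "StimulusSchedule", function(object) {
  s <- object@stimuli
  cat(sprintf("StimulusSchedule: %d stimuli (%d SIGNAL, %d NOISE)\n",
              nrow(s), sum(s$label == "SIGNAL"), sum(s$label == "NOISE")))
})

setMethod("show", "CAPPulse", function(object) {
  cat(sprintf(
    "CAPPulse %s [%s] on %s: front at %.2f um (t0 = %g us), dir %+d,\n  v = %g m/s, E = %g, tau = %g ms\n",
    object@id, object@label, object@segment, object@position,
    object@birthTime * 1e6, object@direction, object@velocity,
    object@energy, object@refractoryDuration * 1e3))
})

setMethod("show", "CollisionOutcome", function(object) {
  cat(sprintf("CollisionOutcome: %s at t = %g us", object@kind,
              object@time * 1e6))
  if (!is.na(object@segment))
    cat(sprintf(" (%s, x = %.2f um)", object@segment, object@position))
  if (length(object@survivors))
    cat(", survivors:", paste(object@survivors, collapse = ", "))
  cat("\n")
})

setMethod("show", "EventLog", function(object) {
  ct <- object@counters
  cat(sprintf("EventLog: %d events, %d pulses spawned\n",
              nrow(object@events), ct[["spawned"]]))
  cat(sprintf(
    "  exited %d | annihilated %d | annulled %d | merged %d | failed %d | active %d\n",
    ct[["exited"]], ct[["annihilated"]], ct[["annulled"]], ct[["merged"]],
    ct[["failed"]], ct[["active"]]))
})

setMethod("show", "RedactionReport", function(object) {
  cat(sprintf(
    "RedactionReport: %d noise injected, %d exited, %d merged in-phase\n",
    object@noiseInjected, object@noiseExits, object@noiseMerged))
  cat(sprintf("  redaction fraction: %s\n",
              format(object@redactionFraction)))
  cat(sprintf("  signal: %d injected, %d exited\n",
              object@signalInjected, object@signalExits))
})

setMethod("show", "FeasibilityReport", function(object) {
  p <- object@params
  cat("FeasibilityReport (charge diffusion between ion channels)\n")
  cat(sprintf("  spacing %g um, D = %g m^2/s, required v = %g m/s\n",
              p$channelSpacingUm, p$diffusionCoefficient, p$requiredVelocity))
  cat(sprintf("  diffusion time: %.3g s\n", object@diffusionTime))
  cat(sprintf("  effective charge speed: %.3g m/s\n", object@chargeSpeed))
  cat(sprintf("  speed ratio: %.3g\n", object@speedRatio))
  cat(sprintf("  temporal accuracy: %.3g s\n", object@temporalAccuracy))
  cat(sprintf("  verdict: charge diffusion %s for propagation\n",
              object@verdict))
})
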