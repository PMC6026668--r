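#' Construct a travelling pulse
#'
#' @param id pulse id.
#' @param birthTime time (s) the front was at `position`.
#' @param segment segment id.
#' @param segmentLength segment length, um.
#' @param position front position at `birthTime`, um from the segment source.
#' @param direction +1 towards the target node, -1 towards the source.
#' @param velocity conduction speed, m/s.
#' @param energy residual soliton energy.
#' @param refractoryDuration refractory tail tau, s.
#' @param label `"SIGNAL"` or `"NOISE"`.
#' @return A [CAPPulse-class].
#' @examples
#' capPulse("p1", 0, "edge", 100, 0, +1)
#' @export
capPulse <- function(id = "p1", birthTime = 0, segment = "seg",
                     segmentLength = 100, position = 0, direction = 1,
                     velocity = 1, energy = 1, refractoryDuration = 2e-3,
                     label = "SIGNAL") {
  new("CAPPulse", id = as.character(id), birthTime = birthTime,
      segment = as.character(segment), segmentLength = segmentLength,
      position = position, direction = direction, velocity = velocity,
      energy = energy, refractoryDuration = refractoryDuration,
      label = as.character(label))
}

#' Ternary phase state of a pulse at a point
#'
#' The pulse decomposes the membrane state at position `x` and time `t` into
#' a ternary digit: `+1` exactly at the threshold front, `-1` at points the
#' front passed within the preceding refractory duration tau (the analog
#' tail), and `0` elsewhere (resting membrane, including everywhere before
#' the pulse was born).
#'
#' @param p a [CAPPulse-class].
#' @param x position on the pulse's segment, um from the source.
#' @param t time, s.
#' @param tolUm spatial tolerance for "at the front", um.
#' @return `-1`, `0` or `+1`.
#' @examples
#' p <- capPulse(velocity = 1, refractoryDuration = 2e-3)
#' ternaryState(p, 50, 50e-6)   # +1: front is at 50 um after 50 us
#' ternaryState(p, 80, 50e-6)   #  0: resting, ahead of the front
#' ternaryState(p, 49, 50e-6)   # -1: refractory, just behind the front
#' @export
ternaryState <- function(p, x, t, tolUm = 1e-6) {
  stopifnot(is(p, "CAPPulse"))
  .assertScalar(x, "x")
  if (x < 0 || x > p@segmentLength)
    stop("x is off the pulse's segment [0, ", p@segmentLength, "]",
         call. = FALSE)
  if (t < p@birthTime) return(0)
  vum <- .v_um_per_s(p@velocity)
  travelled <- vum * (t - p@birthTime)
  s <- p@direction * (x - p@position)  # signed distance from entry, along travel
  if (s < -tolUm) return(0)            # behind the entry point, never visited
  if (abs(s - travelled) <= tolUm) return(1)
  if (s > travelled) return(0)         # ahead of the front
  tPassed <- p@birthTime + s / vum
  if (t - tPassed <= p@refractoryDuration) -1 else 0
}

#' Residual soliton energy after travelling a distance
#'
#' Linear dissipation with a floor at zero: an initial energy budget E loses
#' `rate` units per micrometre, so the residual after distance d is
#' `max(E - rate * d, 0)`. A pulse whose residual hits zero is dead.
#'
#' @param E0 initial energy (>= 0).
#' @param rate dissipation per um (>= 0).
#' @param distance um travelled (>= 0).
#' @return residual energy.
#' @examples
#' residualEnergy(10, 0.05, 100)  # 5
#' residualEnergy(1, 1, 100)      # 0 (floored)
#' @export
residualEnergy <- function(E0, rate, distance) {
  .assertScalar(E0, "E0", min = 0)
  .assertScalar(rate, "rate", min = 0)
  .assertScalar(distance, "distance", min = 0)
  max(E0 - rate * distance, 0)
}

#' Can a residual energy trigger the next channel?
#'
#' Boundary inclusive: a residual exactly at threshold activates.
#'
#' @param residual residual energy.
#' @param threshold activation threshold.
#' @return logical.
#' @export
canActivate <- function(residual, threshold) {
  residual >= threshold
}

#' Are two firing times in phase?
#'
#' @param t1,t2 times, s.
#' @param tolerance in-phase tolerance, s (>= 0); the natural default is the
#'   membrane's temporal accuracy, channel spacing / velocity.
#' @return logical: `abs(t1 - t2) <= tolerance`.
#' @export
inPhase <- function(t1, t2, tolerance) {
  .assertScalar(tolerance, "tolerance", min = 0)
  abs(t1 - t2) <= tolerance
}

#' Resolve a pulse arrival at a junction with refractory memory
#'
#' Given the time the threshold last passed through a node, classify a new
#' arrival: with no prior passage the pulse passes; an arrival within
#' `mergeTolerance` of the last passage is in phase and merges with it (one
#' pulse continues); an arrival inside the remaining refractory window
#' `(mergeTolerance, tau)` is annulled by the trailing refractory tail
#' (occlusion); an arrival at or beyond `tau` passes. The refractory window
#' is half-open — an arrival exactly `tau` after the last passage passes.
#'
#' @param nodeLastPassage time (s) of the last threshold passage, or `NULL` /
#'   `NA` if none.
#' @param arrival arrival time, s (must not precede the recorded passage).
#' @param tauNode refractory duration left at the node, s.
#' @param mergeTolerance in-phase tolerance, s.
#' @return `"PASS"`, `"MERGE"` or `"ANNUL_SECOND"`.
#' @examples
#' resolveNodeArrival(NULL, 1e-4, 2e-3, 1.5e-6)        # PASS
#' resolveNodeArrival(1e-4, 1e-4, 2e-3, 1.5e-6)        # MERGE
#' resolveNodeArrival(1e-4, 1e-4 + 1e-3, 2e-3, 1.5e-6) # ANNUL_SECOND
#' resolveNodeArrival(1e-4, 1e-4 + 3e-3, 2e-3, 1.5e-6) # PASS
#' @export
resolveNodeArrival <- function(nodeLastPassage, arrival, tauNode,
                               mergeTolerance) {
  .assertScalar(arrival, "arrival")
  .assertScalar(tauNode, "tauNode", min = 0)
  .assertScalar(mergeTolerance, "mergeTolerance", min = 0)
  if (is.null(nodeLastPassage) || is.na(nodeLastPassage)) return("PASS")
  delta <- arrival - nodeLastPassage
  if (delta < 0)
    stop("ordering error: arrival precedes recorded node passage",
         call. = FALSE)
  if (delta <= mergeTolerance) return("MERGE")
  if (delta < tauNode) return("ANNUL_SECOND")
  "PASS"
}

#' Resolve a head-on meeting of two pulses on one segment
#'
#' Two pulses approaching each other on the same segment meet where their
#' linear front trajectories cross and mutually annihilate — neither
#' threshold front can cross the other's refractory zone. The resolution is
#' symmetric in argument order. Same-direction pulses are a domain error
#' (a chase, not a collision).
#'
#' @param a,b [CAPPulse-class] objects on the same segment with opposite
#'   directions.
#' @return A [CollisionOutcome-class] of kind `MUTUAL_ANNIHILATION` with the
#'   meeting time and position.
#' @examples
#' # entries at both ends of a 100 um edge at 1 m/s, offset by 20 us:
#' a <- capPulse("a", 0,     "edge", 100, 0,   +1)
#' b <- capPulse("b", 20e-6, "edge", 100, 100, -1)
#' resolveHeadOn(a, b)  # meet at x = 60 um, t = 60 us
#' @export
resolveHeadOn <- function(a, b) {
  stopifnot(is(a, "CAPPulse"), is(b, "CAPPulse"))
  if (a@segment != b@segment)
    stop("pulses are on different segments", call. = FALSE)
  if (a@direction == b@direction)
    stop("same-direction pulses do not collide head-on (chase)",
         call. = FALSE)
  v <- .v_um_per_s(a@velocity)
  if (abs(b@velocity - a@velocity) > 1e-12 * a@velocity)
    stop("pulses on one segment must share its conduction velocity",
         call. = FALSE)
  # a.pos + da*v*(t - ta) = b.pos + db*v*(t - tb), db = -da
  da <- a@direction; db <- b@direction
  tStar <- (b@position - a@position + v * (da * a@birthTime - db * b@birthTime)) /
    ((da - db) * v)
  t0 <- max(a@birthTime, b@birthTime)
  xStar <- a@position + da * v * (tStar - a@birthTime)
  if (tStar < t0 - 1e-15 || xStar < 0 || xStar > a@segmentLength)
    stop("pulses do not approach each other on the segment", call. = FALSE)
  new("CollisionOutcome", kind = "MUTUAL_ANNIHILATION",
      survivors = character(0), time = tStar, segment = a@segment,
      position = xStar)
}
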