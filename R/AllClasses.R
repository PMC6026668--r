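#' @import methods
NULL

.NODE_ROLES <- c("ENTRY", "BRANCH", "CONVERGE", "TERMINAL", "PASS")

.SEGMENT_COLS <- c("id", "source", "target", "length_um", "velocity_m_per_s",
                   "refractory_ms", "channel_spacing_um", "dissipation_per_um",
                   "activation_threshold", "myelinated")

.EVENT_KINDS <- c("SPAWN", "FRONT_AT_NODE", "HEAD_ON_ANNIHILATION", "ANNUL",
                  "MERGE", "PULSE_FAILURE", "TERMINAL_EXIT")

#' Membrane dynamics of a neurite segment
#'
#' Per-segment physical parameters of the excitable membrane: conduction
#' velocity of the pulse, duration of the analog refractory tail, spacing
#' between adjacent ion channels, linear soliton energy dissipation, and the
#' minimum residual energy needed to trigger the next channel.
#'
#' @slot velocity conduction speed in m/s (equivalently um/us).
#' @slot refractoryDuration refractory tail length in seconds.
#' @slot channelSpacing inter-channel distance in micrometres.
#' @slot dissipationRate soliton energy loss per micrometre travelled
#'   (arbitrary energy units / um).
#' @slot activationThreshold minimum residual energy required to trigger the
#'   channels at the end of a segment (arbitrary energy units).
#' @slot myelinated logical flag; myelinated stretches are conventionally
#'   configured as high-velocity, low-dissipation segments.
#' @seealso [membraneDynamics()]
#' @exportClass MembraneDynamics
setClass("MembraneDynamics",
  representation(
    velocity            = "numeric",
    refractoryDuration  = "numeric",
    channelSpacing      = "numeric",
    dissipationRate     = "numeric",
    activationThreshold = "numeric",
    myelinated          = "logical"
  ),
  validity = function(object) {
    msg <- character(0)
    sc1 <- function(x, nm) {
      if (length(slot(object, x)) != 1L || is.na(slot(object, x)))
        msg <<- c(msg, sprintf("%s must be a single non-NA value", nm))
    }
    for (s in slotNames(object)) sc1(s, s)
    if (length(msg)) return(msg)
    if (object@velocity <= 0) msg <- c(msg, "velocity must be > 0")
    if (object@refractoryDuration < 0) msg <- c(msg, "refractoryDuration must be >= 0")
    if (object@channelSpacing <= 0) msg <- c(msg, "channelSpacing must be > 0")
    if (object@dissipationRate < 0) msg <- c(msg, "dissipationRate must be >= 0")
    if (object@activationThreshold < 0) msg <- c(msg, "activationThreshold must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Neurite network graph
#'
#' A directed graph of membrane segments. `nodes` is a data.frame with
#' columns `id` and `role` (one of ENTRY, BRANCH, CONVERGE, TERMINAL, PASS;
#' roles are annotations, not structural constraints). `segments` is a
#' data.frame with one row per directed segment and per-segment membrane
#' dynamics columns (see [membraneDynamics()] for units):
#' `id, source, target, length_um, velocity_m_per_s, refractory_ms,
#' channel_spacing_um, dissipation_per_um, activation_threshold, myelinated`.
#'
#' @slot nodes data.frame of node ids and roles.
#' @slot segments data.frame of directed segments with dynamics.
#' @slot meta list of free-form metadata (e.g. generator parameters),
#'   round-tripped through the native JSON format.
#' @seealso [neuriteGraph()], [generateLadder()], [validateGraph()]
#' @exportClass NeuriteGraph
setClass("NeuriteGraph",
  representation(nodes = "data.frame", segments = "data.frame", meta = "list"),
  validity = function(object) {
    msg <- character(0)
    if (!all(c("id", "role") %in% names(object@nodes)))
      msg <- c(msg, "nodes must have columns 'id' and 'role'")
    if (!all(.SEGMENT_COLS %in% names(object@segments)))
      msg <- c(msg, paste("segments must have columns:",
                          paste(.SEGMENT_COLS, collapse = ", ")))
    if (length(msg)) return(msg)
    bad <- setdiff(object@nodes$role, .NODE_ROLES)
    if (length(bad))
      msg <- c(msg, paste("unknown node roles:", paste(bad, collapse = ", ")))
    # semantic invariants (endpoints, connectivity, positivity) are reported
    # as diagnostics by validateGraph(), not as construction errors
    if (length(msg)) msg else TRUE
  }
)

#' Stimulus schedule
#'
#' Entry-node firing times. `stimuli` is a data.frame with columns
#' `node_id`, `time_s` and `label` (`"SIGNAL"` or `"NOISE"`).
#'
#' @slot stimuli data.frame of (node_id, time_s, label).
#' @seealso [stimulusSchedule()], [injectNoise()]
#' @exportClass StimulusSchedule
setClass("StimulusSchedule",
  representation(stimuli = "data.frame"),
  validity = function(object) {
    s <- object@stimuli
    msg <- character(0)
    if (!all(c("node_id", "time_s", "label") %in% names(s)))
      return("stimuli must have columns node_id, time_s, label")
    if (nrow(s)) {
      if (any(!is.finite(s$time_s)) || any(s$time_s < 0))
        msg <- c(msg, "stimulus times must be finite and >= 0")
      if (!all(s$label %in% c("SIGNAL", "NOISE")))
        msg <- c(msg, "labels must be SIGNAL or NOISE")
    }
    if (length(msg)) msg else TRUE
  }
)

#' A travelling computational action potential
#'
#' Snapshot of a single phase-ternary pulse on one segment: its threshold
#' front position at `birthTime` (the moment it entered the segment), travel
#' direction, residual soliton energy and inherited refractory duration.
#' The front at time `t >= birthTime` is at
#' `position + direction * velocity * (t - birthTime)` (velocity in um/s).
#'
#' @slot id pulse identifier.
#' @slot birthTime time (s) the pulse entered its current segment.
#' @slot segment id of the segment the pulse travels on.
#' @slot segmentLength length of that segment (um).
#' @slot position front position at `birthTime`, um from the segment source.
#' @slot direction +1 towards the target node, -1 towards the source node.
#' @slot velocity conduction speed, m/s.
#' @slot energy residual soliton energy (arbitrary units).
#' @slot refractoryDuration refractory tail length tau (s).
#' @slot label provenance, `"SIGNAL"` or `"NOISE"`.
#' @seealso [capPulse()], [ternaryState()], [resolveHeadOn()]
#' @exportClass CAPPulse
setClass("CAPPulse",
  representation(
    id = "character", birthTime = "numeric", segment = "character",
    segmentLength = "numeric", position = "numeric", direction = "numeric",
    velocity = "numeric", energy = "numeric", refractoryDuration = "numeric",
    label = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@segmentLength <= 0) msg <- c(msg, "segmentLength must be > 0")
    if (object@position < 0 || object@position > object@segmentLength)
      msg <- c(msg, "position must lie on the segment [0, length]")
    if (!object@direction %in% c(-1, 1))
      msg <- c(msg, "direction must be +1 or -1")
    if (object@velocity <= 0) msg <- c(msg, "velocity must be > 0")
    if (object@energy < 0) msg <- c(msg, "energy must be >= 0")
    if (object@refractoryDuration < 0) msg <- c(msg, "refractoryDuration must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Outcome of a pulse interaction
#'
#' Result of resolving a head-on meeting on a segment or an arrival at a
#' junction: `MUTUAL_ANNIHILATION` (no survivors), `ANNUL_SECOND` or `MERGE`
#' (one survivor), or `PASS`.
#'
#' @slot kind one of MUTUAL_ANNIHILATION, ANNUL_SECOND, MERGE, PASS.
#' @slot survivors ids of surviving pulses.
#' @slot time time (s) of the interaction.
#' @slot segment segment id (or NA for node interactions).
#' @slot position um from the segment source (or NA).
#' @exportClass CollisionOutcome
setClass("CollisionOutcome",
  representation(kind = "character", survivors = "character",
                 time = "numeric", segment = "character",
                 position = "numeric"),
  validity = function(object) {
    k <- object@kind
    if (!k %in% c("MUTUAL_ANNIHILATION", "ANNUL_SECOND", "MERGE", "PASS"))
      return("unknown outcome kind")
    if (k == "MUTUAL_ANNIHILATION" && length(object@survivors) != 0)
      return("MUTUAL_ANNIHILATION must have zero survivors")
    if (k %in% c("ANNUL_SECOND", "MERGE") && length(object@survivors) != 1)
      return(paste(k, "must have exactly one survivor"))
    TRUE
  }
)

#' Simulation event log
#'
#' Ordered record of everything that happened in a run: pulse spawns, front
#' arrivals at nodes, head-on annihilations, refractory annulments, in-phase
#' merges, propagation failures and terminal exits, plus per-terminal arrival
#' times (the output phase pattern) and conservation counters.
#'
#' The counters satisfy, exactly, on every run:
#' `spawned = exited + annihilated + annulled + merged + failed + active`.
#'
#' @slot events data.frame with columns `time_s, kind, pulses, node, segment,
#'   position_um, label`, sorted by processing order (time, then event id).
#' @slot arrivals named list: terminal node id -> sorted numeric arrival
#'   times (s).
#' @slot counters named numeric vector (spawned, exited, annihilated,
#'   annulled, merged, failed, active).
#' @slot config echo of the resolved run configuration.
#' @seealso [simulatePulses()], [outputPhasePattern()]
#' @exportClass EventLog
setClass("EventLog",
  representation(events = "data.frame", arrivals = "list",
                 counters = "numeric", config = "list"),
  validity = function(object) {
    need <- c("time_s", "kind", "pulses", "node", "segment", "position_um",
              "label")
    if (!all(need %in% names(object@events)))
      return(paste("events must have columns:", paste(need, collapse = ", ")))
    cn <- c("spawned", "exited", "annihilated", "annulled", "merged",
            "failed", "active")
    if (!all(cn %in% names(object@counters)))
      return("incomplete counters")
    ct <- object@counters
    if (ct[["spawned"]] != sum(ct[c("exited", "annihilated", "annulled",
                                    "merged", "failed", "active")]))
      return("conservation identity violated")
    TRUE
  }
)

#' Noise-redaction experiment report
#'
#' Summary of a ladder-network run with periodic signal plus injected noise:
#' how much noise reached the terminal versus how much was redacted by the
#' refractory gates at converging junctions.
#'
#' @slot noiseInjected number of injected NOISE stimuli.
#' @slot noiseExits number of NOISE-labelled terminal exits.
#' @slot noiseMerged number of NOISE pulses absorbed by in-phase merging
#'   (reported separately; in-phase noise is indistinguishable from signal).
#' @slot redactionFraction `1 - noiseExits / noiseInjected` (NA when no
#'   noise was injected).
#' @slot signalInjected,signalExits same accounting for SIGNAL stimuli.
#' @slot layerSurvival data.frame (layer, node, noiseArrived, noiseSurvived).
#' @slot interArrivalSd dispersion of terminal arrival times: sd of
#'   successive inter-arrival intervals (s); NA with < 3 arrivals.
#' @slot seed seed used (NA if none).
#' @slot config echo of the experiment parameters.
#' @seealso [runRedactionExperiment()]
#' @exportClass RedactionReport
setClass("RedactionReport",
  representation(
    noiseInjected = "numeric", noiseExits = "numeric", noiseMerged = "numeric",
    redactionFraction = "numeric", signalInjected = "numeric",
    signalExits = "numeric", layerSurvival = "data.frame",
    interArrivalSd = "numeric", seed = "numeric", config = "list"
  ),
  validity = function(object) {
    f <- object@redactionFraction
    if (object@noiseInjected > 0 && (is.na(f) || f < 0 || f > 1))
      return("redactionFraction must lie in [0, 1] when noise was injected")
    TRUE
  }
)

#' Physical feasibility report
#'
#' Back-of-envelope physics of charge diffusion between ion channels: the
#' time for Na+ charge to diffuse across one channel spacing, the effective
#' charge speed it implies, its ratio to the speed required for propagation,
#' and the temporal accuracy of threshold timing at that spacing. The verdict
#' is "insufficient" whenever the speed ratio is below 1, i.e. diffusing
#' charge alone cannot carry the pulse from channel to channel.
#'
#' @slot diffusionTime seconds for charge to diffuse one channel spacing.
#' @slot chargeSpeed effective diffusive charge speed, m/s.
#' @slot speedRatio chargeSpeed / required propagation speed.
#' @slot temporalAccuracy spacing / velocity, s.
#' @slot verdict "sufficient" or "insufficient".
#' @slot params list of the inputs used (spacing um, D m^2/s, required
#'   velocity m/s, ionic radius pm).
#' @seealso [feasibilityReport()]
#' @exportClass FeasibilityReport
setClass("FeasibilityReport",
  representation(diffusionTime = "numeric", chargeSpeed = "numeric",
                 speedRatio = "numeric", temporalAccuracy = "numeric",
                 verdict = "character", params = "list"),
  validity = function(object) {
    if (any(c(object@diffusionTime, object@chargeSpeed, object@speedRatio,
              object@temporalAccuracy) < 0))
      return("all quantities must be non-negative")
    ins <- object@speedRatio < 1
    if (ins != identical(object@verdict, "insufficient"))
      return("verdict must be 'insufficient' iff speedRatio < 1")
    TRUE
  }
)
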