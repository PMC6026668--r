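#' Inject Poisson noise into a stimulus schedule
#'
#' Appends NOISE-labelled stimuli drawn from an independent homogeneous
#' Poisson process of the given rate at each entry node, over `[0, horizon)`.
#' Deterministic under a fixed seed; the caller's RNG state is restored.
#'
#' @param s a [StimulusSchedule-class] (the clean signal).
#' @param rate events per second per entry node (>= 0).
#' @param horizon upper bound (s) for noise times.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @param entryNodes nodes to inject at; defaults to the distinct nodes
#'   already present in `s`.
#' @return A new [StimulusSchedule-class] with the noise appended.
#' @examples
#' s <- stimulusSchedule("entry", c(0, 0.01))
#' injectNoise(s, rate = 100, horizon = 0.02, seed = 1)
#' @export
injectNoise <- function(s, rate, horizon, seed = NULL, entryNodes = NULL) {
  stopifnot(is(s, "StimulusSchedule"))
  .assertScalar(rate, "rate", min = 0)
  .assertScalar(horizon, "horizon", min = 0, strict = TRUE)
  if (is.null(entryNodes)) entryNodes <- unique(s@stimuli$node_id)
  if (rate == 0 || !length(entryNodes)) return(s)
  noise <- withSeed(seed, {
    do.call(rbind, lapply(sort(entryNodes), function(n) {
      k <- stats::rpois(1, rate * horizon)
      if (k == 0) return(NULL)
      data.frame(node_id = n, time_s = sort(stats::runif(k, 0, horizon)),
                 label = "NOISE", stringsAsFactors = FALSE)
    }))
  })
  if (is.null(noise)) return(s)
  new("StimulusSchedule", stimuli = rbind(s@stimuli, noise))
}

.defaultHorizon <- function(graph, lastStim, tauMax) {
  sg <- graph@segments
  transit <- sum(sg$length_um / .v_um_per_s(sg$velocity_m_per_s))
  lastStim + transit + 2 * tauMax + 1e-6
}

#' Run a noise-redaction experiment on a parallel ladder
#'
#' Builds an `nLayers` x `nParallel` ladder, drives it with a periodic
#' SIGNAL train plus injected NOISE, simulates, and tallies
#' provenance-labelled terminal exits. On equal-length parallel limbs, every
#' noise spike whose offset from the preceding signal falls inside the
#' refractory window `(mergeTolerance, tau)` collides at the first
#' converging junction and is annulled, so the redaction fraction is 1 for
#' purely out-of-phase noise; in-phase noise (offset within the merge
#' tolerance) merges with the signal and is reported separately as
#' `noiseMerged` — the mechanism cannot distinguish it from signal. On a
#' single chain (`nParallel = 1`) nothing converges and nothing is redacted.
#'
#' @param nLayers ladder depth (>= 1).
#' @param nParallel parallel limbs (>= 1; >= 2 for any redaction).
#' @param signalPeriod signal inter-spike interval, s; keep it > tau so the
#'   signal never self-occludes (default 5x the refractory duration).
#' @param noiseRate Poisson noise rate (events/s per entry) for
#'   `noiseMode = "poisson"`.
#' @param seed RNG seed for the noise draw.
#' @param nSignals number of signal spikes.
#' @param segmentLength segment length, um.
#' @param dynamics a [MembraneDynamics-class].
#' @param jitterSd Gaussian segment-length jitter, um.
#' @param noiseMode `"poisson"` (homogeneous Poisson noise) or
#'   `"outOfPhase"` (one noise spike per signal spike at an offset drawn
#'   uniformly from the open refractory window `(mergeTolerance, tau)`).
#' @param noiseOffset optional fixed offset (s) from each signal spike,
#'   overriding the random draw in `"outOfPhase"` mode.
#' @param config a [runConfig()] list.
#' @return A [RedactionReport-class].
#' @examples
#' rep <- runRedactionExperiment(1, 2, noiseMode = "outOfPhase", seed = 1)
#' redactionFraction(rep)  # 1
#' @export
runRedactionExperiment <- function(nLayers, nParallel,
                                   signalPeriod = NULL, noiseRate = 50,
                                   seed = NULL, nSignals = 3,
                                   segmentLength = 100,
                                   dynamics = membraneDynamics(),
                                   jitterSd = 0,
                                   noiseMode = c("poisson", "outOfPhase"),
                                   noiseOffset = NULL,
                                   config = runConfig()) {
  noiseMode <- match.arg(noiseMode)
  tau <- dynamics@refractoryDuration
  if (is.null(signalPeriod)) signalPeriod <- 5 * tau
  .assertScalar(signalPeriod, "signalPeriod", min = 0, strict = TRUE)
  .assertScalar(noiseRate, "noiseRate", min = 0)
  graph <- generateLadder(nLayers, nParallel, segmentLength,
                          dynamics = dynamics, jitterSd = jitterSd,
                          seed = seed)
  sigT <- (seq_len(nSignals) - 1) * signalPeriod
  sched <- stimulusSchedule("entry", sigT, "SIGNAL")
  tol <- if (is.null(config$mergeTolerance))
    dynamics@channelSpacing / .v_um_per_s(dynamics@velocity) else
    config$mergeTolerance

  if (noiseMode == "poisson") {
    stimHorizon <- max(sigT) + signalPeriod
    sched <- injectNoise(sched, noiseRate, stimHorizon, seed = seed)
  } else {
    offs <- if (!is.null(noiseOffset)) rep_len(noiseOffset, nSignals) else
      withSeed(seed, stats::runif(nSignals, tol * 1.05, tau * 0.95))
    noise <- stimulusSchedule("entry", sigT + offs, "NOISE")
    sched <- new("StimulusSchedule",
                 stimuli = rbind(sched@stimuli, noise@stimuli))
  }

  st <- sched@stimuli
  horizon <- .defaultHorizon(graph, max(st$time_s), tau)
  log <- simulatePulses(graph, sched, horizon, config)

  e <- events(log)
  exits <- e[e$kind == "TERMINAL_EXIT", , drop = FALSE]
  noiseInjected <- sum(st$label == "NOISE")
  sigInjected <- sum(st$label == "SIGNAL")
  noiseExits <- sum(exits$label == "NOISE")
  sigExits <- sum(exits$label == "SIGNAL")
  noiseMerged <- sum(e$kind == "MERGE" & e$label == "NOISE")
  frac <- if (noiseInjected > 0) 1 - noiseExits / noiseInjected else NA_real_

  convNodes <- graphNodes(graph)
  convNodes <- convNodes$id[grepl("^conv", convNodes$id)]
  layerSurvival <- do.call(rbind, lapply(seq_along(convNodes), function(l) {
    n <- convNodes[l]
    here <- e$node == n & !is.na(e$node) & e$label == "NOISE"
    arrived <- sum(here & e$kind == "FRONT_AT_NODE")
    lost <- sum(here & e$kind %in% c("MERGE", "ANNUL", "PULSE_FAILURE"))
    data.frame(layer = l, node = n, noiseArrived = arrived,
               noiseSurvived = arrived - lost)
  }))
  if (is.null(layerSurvival))
    layerSurvival <- data.frame(layer = integer(0), node = character(0),
                                noiseArrived = integer(0),
                                noiseSurvived = integer(0))

  termArr <- sort(unlist(arrivalTimes(log)["terminal"]))
  iaSd <- if (length(termArr) >= 3) stats::sd(diff(termArr)) else NA_real_

  new("RedactionReport",
      noiseInjected = noiseInjected, noiseExits = noiseExits,
      noiseMerged = noiseMerged, redactionFraction = frac,
      signalInjected = sigInjected, signalExits = sigExits,
      layerSurvival = layerSurvival, interArrivalSd = iaSd,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      config = list(nLayers = nLayers, nParallel = nParallel,
                    signalPeriod = signalPeriod, noiseRate = noiseRate,
                    nSignals = nSignals, segmentLength = segmentLength,
                    jitterSd = jitterSd, noiseMode = noiseMode,
                    mergeTolerance = tol, tau = tau, horizon = horizon))
}

#' Mean redaction fraction as a function of ladder depth
#'
#' Runs paired-seed out-of-phase-noise experiments at depths 1..maxLayers
#' (the same `reps` seeds at every depth) and reports the mean redaction
#' fraction per depth. Because every out-of-phase noise spike is already
#' annulled at the first converging junction, the mean is non-decreasing in
#' depth and equals 1 for purely out-of-phase noise at every depth.
#'
#' @param maxLayers deepest ladder to test (>= 1).
#' @param reps experiments per depth (>= 1).
#' @param seed base seed; experiment `i` uses `seed + i`.
#' @param nParallel parallel limbs (>= 2 for redaction).
#' @param noiseMode passed to [runRedactionExperiment()].
#' @param ... further arguments for [runRedactionExperiment()].
#' @return data.frame with columns `layers`, `meanRedaction`, `reps`.
#' @export
redactionVsDepth <- function(maxLayers, reps = 20, seed = 1, nParallel = 2,
                             noiseMode = "outOfPhase", ...) {
  .assertScalar(maxLayers, "maxLayers", min = 1)
  .assertScalar(reps, "reps", min = 1)
  res <- lapply(seq_len(maxLayers), function(depth) {
    fr <- vapply(seq_len(reps), function(i) {
      r <- runRedactionExperiment(depth, nParallel, seed = seed + i,
                                  noiseMode = noiseMode, ...)
      redactionFraction(r)
    }, numeric(1))
    data.frame(layers = depth, meanRedaction = mean(fr, na.rm = TRUE),
               reps = reps)
  })
  do.call(rbind, res)
}
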