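# Shared fixtures, built in code.

defaultDyn <- function(...) membraneDynamics(...)

# segment-table row with explicit dynamics columns (keeps tests independent
# of package internals)
segRow <- function(id, source, target, length_um,
                   velocity = 1, refractory_ms = 2, spacing = 1.5,
                   dissipation = 0, threshold = 0, myelinated = FALSE) {
  data.frame(id = id, source = source, target = target,
             length_um = length_um, velocity_m_per_s = velocity,
             refractory_ms = refractory_ms, channel_spacing_um = spacing,
             dissipation_per_um = dissipation,
             activation_threshold = threshold, myelinated = myelinated,
             stringsAsFactors = FALSE)
}

# two parallel limbs of different lengths converging once, then an output
# segment: the canonical annulment motif
asymmetricMotif <- function(l1, l2, outLen = l1, ...) {
  nodes <- data.frame(id = c("entry", "conv1", "terminal"),
                      role = c("ENTRY", "CONVERGE", "TERMINAL"),
                      stringsAsFactors = FALSE)
  segs <- rbind(segRow("a", "entry", "conv1", l1, ...),
                segRow("b", "entry", "conv1", l2, ...),
                segRow("out", "conv1", "terminal", outLen, ...))
  neuriteGraph(nodes, segs)
}

# randomized small scenario (graph <= 10 nodes + schedule + horizon) with
# event separations far larger than the oracle step, so event order is
# unambiguous
randomScenario <- function(seed) {
  set.seed(seed)
  type <- sample(c("chain", "ladder", "tree", "collision", "asym"), 1)
  len <- sample(5:15, 1) * 10  # 50..150 um, multiples of 10
  if (type == "chain") {
    g <- generateChain(sample(2:5, 1), len)
    s <- stimulusSchedule("entry", sort(sample(0:3, sample(1:2, 1))) * 5e-3)
  } else if (type == "ladder") {
    g <- generateLadder(sample(1:3, 1), 2, len)
    s <- stimulusSchedule("entry", sort(sample(0:3, sample(1:2, 1))) * 5e-3)
  } else if (type == "tree") {
    g <- generateBinaryTree(sample(1:2, 1), len)
    s <- stimulusSchedule("root", 0)
  } else if (type == "collision") {
    g <- generateCollisionEdge(len)
    s <- stimulusSchedule(c("e1", "e2"), c(0, sample(0:3, 1) * 1e-5))
  } else {
    g <- asymmetricMotif(len, len + sample(1:5, 1) * 10)
    s <- stimulusSchedule("entry", 0)
  }
  transit <- sum(graphSegments(g)$length_um) / 1e6  # v = 1 m/s everywhere
  list(graph = g, schedule = s,
       horizon = max(stimuli(s)$time_s) + transit + 1e-2)
}

# canonical serialized event lines, for byte-identity checks
canonLines <- function(log) capnet:::.canonicalEventLines(log)

expectConservation <- function(log) {
  ct <- counters(log)
  expect_identical(
    unname(ct[["spawned"]]),
    unname(sum(ct[c("exited", "annihilated", "annulled", "merged",
                    "failed", "active")])))
}

# check the event-driven engine against the time-stepped oracle
expectOracleAgreement <- function(g, s, horizon, dt = 1e-6) {
  le <- simulatePulses(g, s, horizon)
  lo <- oracleSimulate(g, s, horizon, dt = dt)
  ee <- events(le); eo <- events(lo)
  expect_identical(ee$kind, eo$kind)
  expect_identical(ee$pulses, eo$pulses)
  expect_identical(ee$node, eo$node)
  expect_lt(max(c(0, abs(ee$time_s - eo$time_s))), dt + 1e-12)
  expect_identical(counters(le), counters(lo))
  invisible(list(event = le, oracle = lo))
}
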