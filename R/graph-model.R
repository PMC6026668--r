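#' Construct membrane dynamics
#'
#' Defaults follow the quantified values for small unmyelinated fibres:
#' conduction at 1 m/s (the stated unmyelinated maximum), a 2 ms refractory
#' tail, 1.5 um channel spacing (the minimum measured spacing), and inert
#' energetics (zero dissipation, zero threshold) so that soliton energy
#' modelling is opt-in.
#'
#' @param velocity conduction speed, m/s.
#' @param refractoryDuration refractory tail, seconds.
#' @param channelSpacing inter-channel distance, um.
#' @param dissipationRate energy loss per um travelled.
#' @param activationThreshold minimum residual energy to trigger the next
#'   channel.
#' @param myelinated logical flag.
#' @return A [MembraneDynamics-class] object.
#' @examples
#' membraneDynamics()
#' membraneDynamics(velocity = 20, dissipationRate = 0.01, myelinated = TRUE)
#' @export
membraneDynamics <- function(velocity = 1.0, refractoryDuration = 2e-3,
                             channelSpacing = 1.5, dissipationRate = 0,
                             activationThreshold = 0, myelinated = FALSE) {
  new("MembraneDynamics", velocity = velocity,
      refractoryDuration = refractoryDuration,
      channelSpacing = channelSpacing, dissipationRate = dissipationRate,
      activationThreshold = activationThreshold,
      myelinated = isTRUE(myelinated))
}

.segmentRow <- function(id, source, target, length_um, dyn) {
  data.frame(id = id, source = source, target = target,
             length_um = length_um,
             velocity_m_per_s = dyn@velocity,
             refractory_ms = dyn@refractoryDuration * 1e3,
             channel_spacing_um = dyn@channelSpacing,
             dissipation_per_um = dyn@dissipationRate,
             activation_threshold = dyn@activationThreshold,
             myelinated = dyn@myelinated,
             stringsAsFactors = FALSE)
}

#' Construct a neurite graph
#'
#' @param nodes data.frame with columns `id`, `role`.
#' @param segments data.frame with the segment columns described in
#'   [NeuriteGraph-class].
#' @param meta optional list of metadata carried into the native format.
#' @return A [NeuriteGraph-class] object.
#' @export
neuriteGraph <- function(nodes, segments, meta = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    segments <- segments[, .SEGMENT_COLS, drop = FALSE]
    for (col in c("id", "source", "target"))
      segments[[col]] <- as.character(segments[[col]])
    for (col in c("length_um", "velocity_m_per_s", "refractory_ms",
                  "channel_spacing_um", "dissipation_per_um",
                  "activation_threshold"))
      segments[[col]] <- as.numeric(segments[[col]])
    segments$myelinated <- as.logical(segments$myelinated)
  }
  rownames(nodes) <- rownames(segments) <- NULL
  new("NeuriteGraph", nodes = nodes, segments = segments, meta = meta)
}

#' Construct a stimulus schedule
#'
#' @param node_id character vector of entry node ids.
#' @param time_s numeric firing times (s).
#' @param label `"SIGNAL"` or `"NOISE"`, recycled.
#' @return A [StimulusSchedule-class].
#' @examples
#' stimulusSchedule("entry", c(0, 0.01, 0.02))
#' @export
stimulusSchedule <- function(node_id = character(0), time_s = numeric(0),
                             label = "SIGNAL") {
  n <- max(length(node_id), length(time_s))
  df <- data.frame(node_id = rep_len(as.character(node_id), n),
                   time_s = rep_len(as.numeric(time_s), n),
                   label = rep_len(label, n), stringsAsFactors = FALSE)
  if (n == 0L)
    df <- data.frame(node_id = character(0), time_s = numeric(0),
                     label = character(0), stringsAsFactors = FALSE)
  new("StimulusSchedule", stimuli = df)
}

#' Generate a parallel-ladder network
#'
#' One ENTRY node fans out into `nParallel` parallel segments that reconverge
#' at each of `nLayers` junction nodes in series, followed by a single output
#' segment to one TERMINAL. This is the motif on which out-of-phase noise is
#' redacted: copies of each stimulus travel the parallel limbs and meet at
#' every junction, where the refractory tail of the first arrival annuls any
#' out-of-phase second arrival.
#'
#' Node count is `nLayers + 2`; segment count is `nLayers * nParallel + 1`.
#' With `jitterSd > 0`, segment lengths are perturbed by seeded Gaussian
#' noise (clamped positive) so parallel limbs desynchronise.
#'
#' @param nLayers number of converging layers (>= 1).
#' @param nParallel parallel limbs per layer (>= 1; >= 2 for any redaction
#'   to be possible).
#' @param segmentLength nominal segment length, um.
#' @param dynamics a [MembraneDynamics-class] applied to every segment.
#' @param jitterSd standard deviation of the length perturbation, um.
#' @param seed RNG seed for the jitter (ignored when `jitterSd == 0`).
#' @return A validated [NeuriteGraph-class].
#' @examples
#' g <- generateLadder(3, 3, 100)
#' nrow(graphSegments(g))  # 10
#' @export
generateLadder <- function(nLayers, nParallel, segmentLength,
                           dynamics = membraneDynamics(), jitterSd = 0,
                           seed = NULL) {
  .assertScalar(nLayers, "nLayers", min = 1)
  .assertScalar(nParallel, "nParallel", min = 1)
  .assertScalar(segmentLength, "segmentLength", min = 0, strict = TRUE)
  .assertScalar(jitterSd, "jitterSd", min = 0)
  nLayers <- as.integer(nLayers); nParallel <- as.integer(nParallel)

  innerRole <- if (nParallel >= 2L) "CONVERGE" else "PASS"
  inner <- if (nLayers > 0) sprintf("conv%d", seq_len(nLayers)) else character(0)
  nodes <- data.frame(
    id = c("entry", inner, "terminal"),
    role = c("ENTRY", rep(innerRole, nLayers), "TERMINAL"),
    stringsAsFactors = FALSE)

  chain <- c("entry", inner, "terminal")
  segs <- list()
  for (l in seq_len(nLayers)) {
    for (p in seq_len(nParallel)) {
      segs[[length(segs) + 1L]] <- .segmentRow(
        sprintf("L%dP%d", l, p), chain[l], chain[l + 1L], segmentLength,
        dynamics)
    }
  }
  segs[[length(segs) + 1L]] <- .segmentRow(
    "out", chain[nLayers + 1L], "terminal", segmentLength, dynamics)
  segs <- do.call(rbind, segs)

  if (jitterSd > 0) {
    segs$length_um <- withSeed(seed,
      pmax(segs$length_um + stats::rnorm(nrow(segs), 0, jitterSd), 1e-3))
  }
  neuriteGraph(nodes, segs, meta = list(
    generator = "ladder", nLayers = nLayers, nParallel = nParallel,
    segmentLength = segmentLength, jitterSd = jitterSd,
    seed = if (is.null(seed)) NA else seed))
}

#' Generate a two-entry collision edge
#'
#' A single segment with ENTRY nodes at both ends; stimulating both ends
#' produces a head-on collision and mutual annihilation on the edge.
#'
#' @param length segment length, um.
#' @param dynamics a [MembraneDynamics-class].
#' @return A [NeuriteGraph-class] with 2 ENTRY nodes and 1 segment.
#' @examples
#' generateCollisionEdge(100)
#' @export
generateCollisionEdge <- function(length, dynamics = membraneDynamics()) {
  .assertScalar(length, "length", min = 0, strict = TRUE)
  nodes <- data.frame(id = c("e1", "e2"), role = c("ENTRY", "ENTRY"),
                      stringsAsFactors = FALSE)
  segs <- .segmentRow("edge", "e1", "e2", length, dynamics)
  neuriteGraph(nodes, segs,
               meta = list(generator = "collision-edge", length = length))
}

#' Generate a simple chain
#'
#' ENTRY -> (nSegments - 1 PASS nodes) -> TERMINAL, one segment between each
#' pair of consecutive nodes.
#'
#' @param nSegments number of segments (>= 1).
#' @param segmentLength segment length, um.
#' @param dynamics a [MembraneDynamics-class].
#' @return A [NeuriteGraph-class].
#' @export
generateChain <- function(nSegments, segmentLength,
                          dynamics = membraneDynamics()) {
  .assertScalar(nSegments, "nSegments", min = 1)
  .assertScalar(segmentLength, "segmentLength", min = 0, strict = TRUE)
  nSegments <- as.integer(nSegments)
  mid <- if (nSegments > 1L) sprintf("p%d", seq_len(nSegments - 1L)) else character(0)
  ids <- c("entry", mid, "terminal")
  nodes <- data.frame(
    id = ids,
    role = c("ENTRY", rep("PASS", length(mid)), "TERMINAL"),
    stringsAsFactors = FALSE)
  segs <- do.call(rbind, lapply(seq_len(nSegments), function(i)
    .segmentRow(sprintf("s%d", i), ids[i], ids[i + 1L], segmentLength,
                dynamics)))
  neuriteGraph(nodes, segs,
               meta = list(generator = "chain", nSegments = nSegments,
                           segmentLength = segmentLength))
}

#' Generate a binary tree
#'
#' One ENTRY root bifurcating `depth` times; internal nodes are BRANCH
#' points, leaves are TERMINAL. A pulse entering the root is copied down
#' every daughter at each bifurcation (phase diffraction), so a single
#' stimulus yields `2^depth` terminal exits in a lossless configuration.
#'
#' @param depth number of bifurcation levels (>= 1).
#' @param segmentLength segment length, um.
#' @param dynamics a [MembraneDynamics-class].
#' @return A [NeuriteGraph-class].
#' @export
generateBinaryTree <- function(depth, segmentLength,
                               dynamics = membraneDynamics()) {
  .assertScalar(depth, "depth", min = 1)
  .assertScalar(segmentLength, "segmentLength", min = 0, strict = TRUE)
  depth <- as.integer(depth)
  nodes <- data.frame(id = "root", role = "ENTRY", stringsAsFactors = FALSE)
  segs <- list()
  prev <- "root"
  for (lev in seq_len(depth)) {
    cur <- sprintf("n%d_%d", lev, seq_len(2L^lev))
    role <- if (lev == depth) "TERMINAL" else "BRANCH"
    nodes <- rbind(nodes, data.frame(id = cur, role = role,
                                     stringsAsFactors = FALSE))
    for (k in seq_along(cur)) {
      parent <- prev[ceiling(k / 2)]
      segs[[length(segs) + 1L]] <- .segmentRow(
        sprintf("t%d_%d", lev, k), parent, cur[k], segmentLength, dynamics)
    }
    prev <- cur
  }
  neuriteGraph(nodes, do.call(rbind, segs),
               meta = list(generator = "binary-tree", depth = depth,
                           segmentLength = segmentLength))
}

#' Validate a neurite graph
#'
#' Checks the structural invariants and returns one diagnostic message per
#' violation (an empty character vector means the graph is valid). Checked:
#' segment endpoints exist; unique ids; positive lengths and velocities;
#' non-negative refractory, dissipation and threshold; the graph is connected
#' (as an undirected graph); every ENTRY node touches at least one segment;
#' every TERMINAL has in-degree >= 1; and role annotations match structure
#' (a node labelled BRANCH should have out-degree >= 2, a CONVERGE in-degree
#' >= 2).
#'
#' @param g a [NeuriteGraph-class].
#' @return character vector of diagnostics (empty if valid).
#' @examples
#' validateGraph(generateLadder(2, 2, 100))  # character(0)
#' @export
validateGraph <- function(g) {
  stopifnot(is(g, "NeuriteGraph"))
  out <- character(0)
  nd <- g@nodes; sg <- g@segments
  if (anyDuplicated(nd$id))
    out <- c(out, "duplicate node ids")
  if (anyDuplicated(sg$id))
    out <- c(out, "duplicate segment ids")
  miss <- setdiff(c(sg$source, sg$target), nd$id)
  if (length(miss))
    out <- c(out, sprintf("segment endpoint '%s' missing from node set", miss))
  if (nrow(sg)) {
    if (any(sg$length_um <= 0)) out <- c(out, "non-positive segment length")
    if (any(sg$velocity_m_per_s <= 0)) out <- c(out, "non-positive velocity")
    if (any(sg$refractory_ms < 0)) out <- c(out, "negative refractory duration")
    if (any(sg$channel_spacing_um <= 0)) out <- c(out, "non-positive channel spacing")
    if (any(sg$dissipation_per_um < 0)) out <- c(out, "negative dissipation rate")
    if (any(sg$activation_threshold < 0)) out <- c(out, "negative activation threshold")
  }
  if (length(miss)) return(out)

  outDeg <- table(factor(sg$source, levels = nd$id))
  inDeg <- table(factor(sg$target, levels = nd$id))
  deg <- outDeg + inDeg
  if (nrow(nd) > 1L) {
    ig <- igraph::graph_from_data_frame(
      if (nrow(sg)) sg[, c("source", "target")] else
        data.frame(source = character(0), target = character(0)),
      directed = FALSE, vertices = nd$id)
    if (igraph::components(ig)$no > 1L)
      out <- c(out, "graph is not connected")
  }
  for (i in seq_len(nrow(nd))) {
    id <- nd$id[i]; role <- nd$role[i]
    if (role == "ENTRY" && deg[[id]] < 1L)
      out <- c(out, sprintf("ENTRY node '%s' touches no segment", id))
    if (role == "TERMINAL" && inDeg[[id]] < 1L)
      out <- c(out, sprintf("TERMINAL node '%s' has in-degree 0", id))
    if (role == "BRANCH" && outDeg[[id]] < 2L)
      out <- c(out, sprintf("node '%s' labelled BRANCH but out-degree < 2", id))
    if (role == "CONVERGE" && inDeg[[id]] < 2L)
      out <- c(out, sprintf("node '%s' labelled CONVERGE but in-degree < 2", id))
  }
  out
}
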