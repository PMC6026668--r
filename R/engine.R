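#' Run configuration
#'
#' @param mergeTolerance in-phase tolerance at junctions, s. `NULL` (default)
#'   uses each junction's own temporal accuracy, channel spacing / velocity
#'   of the segment the arriving pulse travelled (1.5 us at default
#'   dynamics).
#' @param initialEnergy soliton energy of freshly spawned pulses.
#' @param oracleDt default time step for [oracleSimulate()], s.
#' @param seed RNG seed echoed into logs (the engine itself is
#'   deterministic; the seed matters for generators and noise injection).
#' @return a named list.
#' @export
runConfig <- function(mergeTolerance = NULL, initialEnergy = 1,
                      oracleDt = 1e-6, seed = NULL) {
  if (!is.null(mergeTolerance))
    .assertScalar(mergeTolerance, "mergeTolerance", min = 0)
  .assertScalar(initialEnergy, "initialEnergy", min = 0)
  .assertScalar(oracleDt, "oracleDt", min = 0, strict = TRUE)
  list(mergeTolerance = mergeTolerance, initialEnergy = initialEnergy,
       oracleDt = oracleDt, seed = seed)
}

# Shared pre-processing for both engines. Errors on invalid graphs and on
# stimuli at non-ENTRY nodes or beyond the horizon.
.prepRun <- function(graph, schedule, horizon, config) {
  diags <- validateGraph(graph)
  if (length(diags))
    stop("invalid graph: ", paste(diags, collapse = "; "), call. = FALSE)
  .assertScalar(horizon, "horizon", min = 0, strict = TRUE)
  st <- stimuli(schedule)
  nd <- graph@nodes
  if (nrow(st)) {
    bad <- setdiff(st$node_id, nd$id[nd$role == "ENTRY"])
    if (length(bad))
      stop("schedule error: stimulus on non-ENTRY node: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    if (any(st$time_s >= horizon))
      stop("schedule error: all stimulus times must be < horizon",
           call. = FALSE)
    st <- st[order(st$time_s, st$node_id, st$label), , drop = FALSE]
    rownames(st) <- NULL
  }
  sg <- graph@segments
  env <- new.env(parent = emptyenv())
  env$segs <- sg
  env$vum <- .v_um_per_s(sg$velocity_m_per_s)       # um/s
  env$tau <- sg$refractory_ms * 1e-3                # s
  env$tolSeg <- if (is.null(config$mergeTolerance))
    sg$channel_spacing_um / env$vum else
    rep(config$mergeTolerance, nrow(sg))
  env$outSegs <- lapply(nd$id, function(n) {
    i <- which(sg$source == n)
    i[order(sg$id[i])]
  })
  names(env$outSegs) <- nd$id
  env$inSegs <- lapply(nd$id, function(n) {
    i <- which(sg$target == n)
    i[order(sg$id[i])]
  })
  names(env$inSegs) <- nd$id
  env$inDeg <- vapply(env$inSegs, length, 1L)
  env$roles <- stats::setNames(nd$role, nd$id)
  env$stim <- st
  env
}

.newCounters <- function(fates) {
  f <- factor(fates, levels = c("exited", "annihilated", "annulled",
                                "merged", "failed", "active"))
  ct <- c(spawned = length(fates), table(f))
  names(ct) <- c("spawned", levels(f))
  ct
}

.buildLog <- function(ev, fates, arrivals, config) {
  events <- if (length(ev$time)) data.frame(
    time_s = unlist(ev$time), kind = unlist(ev$kind),
    pulses = unlist(ev$pulses), node = unlist(ev$node),
    segment = unlist(ev$segment), position_um = unlist(ev$pos),
    label = unlist(ev$label), stringsAsFactors = FALSE)
  else data.frame(time_s = numeric(0), kind = character(0),
                  pulses = character(0), node = character(0),
                  segment = character(0), position_um = numeric(0),
                  label = character(0), stringsAsFactors = FALSE)
  rownames(events) <- NULL
  arrivals <- lapply(arrivals, sort)
  new("EventLog", events = events, arrivals = arrivals,
      counters = .newCounters(fates), config = config)
}

#' Simulate phase-ternary pulses on a neurite graph
#'
#' Event-driven continuous-time simulation. Stimuli spawn pulses at ENTRY
#' nodes (one copy per outgoing segment; at an entry with no outgoing
#' segments, pulses travel the incident segments in reverse, which is how a
#' two-entry collision edge is driven). Pulses traverse segments at the
#' segment velocity. Head-on meetings of opposite-direction pulses on one
#' segment are computed analytically and mutually annihilate both pulses.
#' At a junction where at least two afferent segments converge, the node's
#' refractory memory gates each arrival via [resolveNodeArrival()]: in-phase
#' arrivals merge into the earlier pulse, arrivals inside the refractory
#' window are annulled, later arrivals pass. A passing pulse is copied down
#' every outgoing segment (phase diffraction). Soliton energy decays by
#' [residualEnergy()] along each segment and is checked by [canActivate()]
#' against the traversed segment's activation threshold on arrival; an
#' under-threshold pulse fails (`PULSE_FAILURE`) and dies. Pulses reaching a
#' node with no onward segment exit (`TERMINAL_EXIT`).
#'
#' Simultaneous events are processed in (time, creation id) order; in-phase
#' junction arrivals merge regardless of queue order, so outcomes are
#' order-independent. The run is fully deterministic for a fixed graph,
#' schedule and config.
#'
#' @param graph a valid [NeuriteGraph-class].
#' @param schedule a [StimulusSchedule-class]; all times must be < horizon
#'   and all nodes ENTRY nodes.
#' @param horizon simulation end time, s.
#' @param config a [runConfig()] list.
#' @return An [EventLog-class].
#' @examples
#' g <- generateChain(1, 100)                       # 100 um at 1 m/s
#' log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-3)
#' arrivalTimes(log)$terminal                        # 1e-4 s = 100 us
#' @export
simulatePulses <- function(graph, schedule, horizon, config = runConfig()) {
  env <- .prepRun(graph, schedule, horizon, config)
  segs <- env$segs; vum <- env$vum; tau <- env$tau; tolSeg <- env$tolSeg
  outSegs <- env$outSegs; inSegs <- env$inSegs; inDeg <- env$inDeg
  roles <- env$roles

  # pulse state (grown by .addPulse)
  p_seg <- integer(0); p_pos <- numeric(0); p_time <- numeric(0)
  p_dir <- numeric(0); p_energy <- numeric(0); p_label <- character(0)
  p_alive <- logical(0); p_fate <- character(0)

  nodeTime <- stats::setNames(rep(NA_real_, length(roles)), names(roles))
  nodeTau <- nodeTime

  # priority queue as parallel vectors; pop = first index of min time among
  # pending entries, which breaks ties by creation order
  q_time <- numeric(0); q_kind <- character(0)
  q_a <- integer(0); q_b <- integer(0); q_seg <- integer(0)
  q_x <- numeric(0); q_node <- character(0); q_label <- character(0)
  q_done <- logical(0)
  pairSeen <- character(0)

  ev <- list(time = list(), kind = list(), pulses = list(), node = list(),
             segment = list(), pos = list(), label = list())
  arrivals <- list()

  logEvent <- function(time, kind, pulses, node = NA_character_,
                       segment = NA_character_, pos = NA_real_,
                       label = NA_character_) {
    i <- length(ev$time) + 1L
    ev$time[[i]] <<- time; ev$kind[[i]] <<- kind
    ev$pulses[[i]] <<- paste(pulses, collapse = ";")
    ev$node[[i]] <<- node; ev$segment[[i]] <<- segment
    ev$pos[[i]] <<- pos; ev$label[[i]] <<- label
  }

  push <- function(time, kind, a = NA_integer_, b = NA_integer_,
                   seg = NA_integer_, x = NA_real_, node = NA_character_,
                   label = NA_character_) {
    i <- length(q_time) + 1L
    q_time[i] <<- time; q_kind[i] <<- kind; q_a[i] <<- a; q_b[i] <<- b
    q_seg[i] <<- seg; q_x[i] <<- x; q_node[i] <<- node; q_label[i] <<- label
    q_done[i] <<- FALSE
  }

  scheduleArrival <- function(id) {
    s <- p_seg[id]
    dist <- if (p_dir[id] > 0) segs$length_um[s] - p_pos[id] else p_pos[id]
    tArr <- p_time[id] + dist / vum[s]
    node <- if (p_dir[id] > 0) segs$target[s] else segs$source[s]
    push(tArr, "ARRIVE", a = id, seg = s, node = node)
  }

  scheduleMeetings <- function(s) {
    ids <- which(p_alive & p_seg == s)
    plus <- ids[p_dir[ids] > 0]; minus <- ids[p_dir[ids] < 0]
    if (!length(plus) || !length(minus)) return(invisible())
    L <- segs$length_um[s]; v <- vum[s]
    for (i in plus) for (j in minus) {
      key <- paste(i, j, s, sep = ":")
      if (key %in% pairSeen) next
      tStar <- (p_pos[j] - p_pos[i] + v * (p_time[i] + p_time[j])) / (2 * v)
      if (tStar < max(p_time[i], p_time[j]) - 1e-15) next
      xStar <- p_pos[i] + v * (tStar - p_time[i])
      if (xStar <= 1e-9 || xStar >= L - 1e-9) next
      pairSeen <<- c(pairSeen, key)
      push(tStar, "HEADON", a = i, b = j, seg = s, x = xStar)
    }
  }

  placePulse <- function(id, s, pos, dir, time, energy) {
    p_seg[id] <<- s; p_pos[id] <<- pos; p_dir[id] <<- dir
    p_time[id] <<- time; p_energy[id] <<- energy
    scheduleArrival(id)
    scheduleMeetings(s)
  }

  addPulse <- function(s, pos, dir, time, energy, label) {
    id <- length(p_alive) + 1L
    p_seg[id] <<- s; p_pos[id] <<- pos; p_dir[id] <<- dir
    p_time[id] <<- time; p_energy[id] <<- energy; p_label[id] <<- label
    p_alive[id] <<- TRUE; p_fate[id] <<- NA_character_
    logEvent(time, "SPAWN", id, segment = segs$id[s], pos = pos,
             label = label)
    scheduleArrival(id)
    scheduleMeetings(s)
    id
  }

  kill <- function(id, fate) {
    p_alive[id] <<- FALSE; p_fate[id] <<- fate
  }

  # seed the queue with stimuli (already time-sorted)
  if (nrow(env$stim)) for (i in seq_len(nrow(env$stim)))
    push(env$stim$time_s[i], "STIM", node = env$stim$node_id[i],
         label = env$stim$label[i])

  # deterministic tie-break for simultaneous events: stimuli first, then
  # head-on meetings, then node arrivals in pulse-id order (outcomes at a
  # junction are order-independent anyway, since in-phase arrivals merge
  # regardless of which is processed first)
  kindRank <- c(STIM = 0, HEADON = 1, ARRIVE = 2)
  repeat {
    pending <- which(!q_done)
    if (!length(pending)) break
    tmin <- min(q_time[pending])
    ties <- pending[q_time[pending] == tmin]
    if (length(ties) > 1L) {
      o <- order(kindRank[q_kind[ties]],
                 ifelse(is.na(q_a[ties]), ties, q_a[ties]), ties)
      ties <- ties[o]
    }
    i <- ties[1L]
    q_done[i] <- TRUE
    t <- q_time[i]
    if (t > horizon) break

    if (q_kind[i] == "STIM") {
      n <- q_node[i]
      cands <- outSegs[[n]]
      if (length(cands)) {
        for (s in cands) addPulse(s, 0, +1, t, config$initialEnergy,
                                  q_label[i])
      } else {
        for (s in inSegs[[n]]) addPulse(s, segs$length_um[s], -1, t,
                                        config$initialEnergy, q_label[i])
      }

    } else if (q_kind[i] == "ARRIVE") {
      p <- q_a[i]
      if (!p_alive[p] || p_seg[p] != q_seg[i]) next
      s <- p_seg[p]; n <- q_node[i]
      logEvent(t, "FRONT_AT_NODE", p, node = n, segment = segs$id[s],
               pos = if (p_dir[p] > 0) segs$length_um[s] else 0,
               label = p_label[p])
      eRes <- residualEnergy(p_energy[p], segs$dissipation_per_um[s],
                             segs$length_um[s])
      if (inDeg[[n]] >= 2L && !is.na(nodeTime[[n]])) {
        out <- resolveNodeArrival(nodeTime[[n]], t, nodeTau[[n]], tolSeg[s])
        if (out == "MERGE") {
          logEvent(t, "MERGE", p, node = n, label = p_label[p])
          kill(p, "merged"); next
        }
        if (out == "ANNUL_SECOND") {
          logEvent(t, "ANNUL", p, node = n, label = p_label[p])
          kill(p, "annulled"); next
        }
      }
      nodeTime[[n]] <- t; nodeTau[[n]] <- tau[s]
      if (!canActivate(eRes, segs$activation_threshold[s])) {
        logEvent(t, "PULSE_FAILURE", p, node = n, label = p_label[p])
        kill(p, "failed"); next
      }
      cands <- setdiff(outSegs[[n]], s)
      if (!length(cands)) {
        logEvent(t, "TERMINAL_EXIT", p, node = n, label = p_label[p])
        kill(p, "exited")
        arrivals[[n]] <- c(arrivals[[n]], t)
      } else {
        placePulse(p, cands[1L], 0, +1, t, eRes)
        for (s2 in cands[-1L]) addPulse(s2, 0, +1, t, eRes, p_label[p])
      }

    } else if (q_kind[i] == "HEADON") {
      a <- q_a[i]; b <- q_b[i]; s <- q_seg[i]
      if (!p_alive[a] || !p_alive[b] || p_seg[a] != s || p_seg[b] != s) next
      logEvent(t, "HEAD_ON_ANNIHILATION", c(a, b), segment = segs$id[s],
               pos = q_x[i],
               label = if (p_label[a] == p_label[b]) p_label[a] else "MIXED")
      kill(a, "annihilated"); kill(b, "annihilated")
      scheduleMeetings(s)
    }
  }

  fates <- ifelse(is.na(p_fate), "active", p_fate)
  cfgEcho <- c(config,
               list(horizon = horizon, engine = "event",
                    terminals = names(roles)[roles == "TERMINAL"]))
  .buildLog(ev, fates, arrivals, cfgEcho)
}
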