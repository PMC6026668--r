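#' Brute-force time-stepped reference simulator
#'
#' Advances every pulse front by `v * dt` per step and detects arrivals and
#' head-on collisions by interval crossing, applying the same phase-ternary
#' rules as [simulatePulses()] (junction refractory gating, in-phase
#' merging, mutual annihilation, energy dissipation and activation checks).
#' Event times are accurate to within `dt`; overshoot past a node is carried
#' onto the next segment so timing error does not accumulate across nodes.
#' Intended as an independent check of the event-driven engine, not for
#' production runs.
#'
#' @param graph a valid [NeuriteGraph-class].
#' @param schedule a [StimulusSchedule-class].
#' @param horizon simulation end time, s.
#' @param dt time step, s; should be much smaller than the fastest segment
#'   transit time (a warning diagnostic is raised when `dt` exceeds a tenth
#'   of the minimum transit time).
#' @param config a [runConfig()] list.
#' @return An [EventLog-class].
#' @seealso [simulatePulses()]
#' @export
oracleSimulate <- function(graph, schedule, horizon, dt = NULL,
                           config = runConfig()) {
  if (is.null(dt)) dt <- config$oracleDt
  .assertScalar(dt, "dt", min = 0, strict = TRUE)
  env <- .prepRun(graph, schedule, horizon, config)
  segs <- env$segs; vum <- env$vum; tau <- env$tau; tolSeg <- env$tolSeg
  outSegs <- env$outSegs; inSegs <- env$inSegs; inDeg <- env$inDeg
  roles <- env$roles
  if (nrow(segs)) {
    minTransit <- min(segs$length_um / vum)
    if (dt > minTransit / 10)
      warning("dt = ", dt, " s is coarse relative to the minimum segment ",
              "transit time (", signif(minTransit, 3), " s); event times ",
              "may be unreliable", call. = FALSE)
  }

  p_seg <- integer(0); p_pos <- numeric(0); p_dir <- numeric(0)
  p_energy <- numeric(0); p_label <- character(0)
  p_alive <- logical(0); p_fate <- character(0)
  nodeTime <- stats::setNames(rep(NA_real_, length(roles)), names(roles))
  nodeTau <- nodeTime
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
  addPulse <- function(s, pos, dir, tSpawn, energy, label) {
    id <- length(p_alive) + 1L
    p_seg[id] <<- s; p_pos[id] <<- pos; p_dir[id] <<- dir
    p_energy[id] <<- energy; p_label[id] <<- label
    p_alive[id] <<- TRUE; p_fate[id] <<- NA_character_
    logEvent(tSpawn, "SPAWN", id, segment = segs$id[s],
             pos = if (dir > 0) 0 else segs$length_um[s], label = label)
    id
  }
  kill <- function(id, fate) {
    p_alive[id] <<- FALSE; p_fate[id] <<- fate
  }

  # arrival handling shared with the engine's semantics
  handleArrival <- function(p, n, t, overshoot) {
    s <- p_seg[p]
    logEvent(t, "FRONT_AT_NODE", p, node = n, segment = segs$id[s],
             pos = if (p_dir[p] > 0) segs$length_um[s] else 0,
             label = p_label[p])
    eRes <- residualEnergy(p_energy[p], segs$dissipation_per_um[s],
                           segs$length_um[s])
    if (inDeg[[n]] >= 2L && !is.na(nodeTime[[n]])) {
      out <- resolveNodeArrival(nodeTime[[n]], t, nodeTau[[n]], tolSeg[s])
      if (out == "MERGE") {
        logEvent(t, "MERGE", p, node = n, label = p_label[p])
        kill(p, "merged"); return(invisible())
      }
      if (out == "ANNUL_SECOND") {
        logEvent(t, "ANNUL", p, node = n, label = p_label[p])
        kill(p, "annulled"); return(invisible())
      }
    }
    nodeTime[[n]] <<- t; nodeTau[[n]] <<- tau[s]
    if (!canActivate(eRes, segs$activation_threshold[s])) {
      logEvent(t, "PULSE_FAILURE", p, node = n, label = p_label[p])
      kill(p, "failed"); return(invisible())
    }
    cands <- setdiff(outSegs[[n]], s)
    if (!length(cands)) {
      logEvent(t, "TERMINAL_EXIT", p, node = n, label = p_label[p])
      kill(p, "exited")
      arrivals[[n]] <<- c(arrivals[[n]], t)
    } else {
      p_seg[p] <<- cands[1L]; p_pos[p] <<- overshoot; p_dir[p] <<- +1
      p_energy[p] <<- eRes
      for (s2 in cands[-1L]) addPulse(s2, overshoot, +1, t, eRes, p_label[p])
    }
    invisible()
  }

  st <- env$stim
  stIdx <- 1L
  t <- 0
  lastT <- max(horizon, if (nrow(st)) max(st$time_s) else 0)
  while (t <= lastT + dt / 2) {
    anyAlive <- any(p_alive)
    if (stIdx > nrow(st) && !anyAlive) break
    # advance existing fronts
    act <- which(p_alive)
    if (length(act))
      p_pos[act] <- p_pos[act] + p_dir[act] * vum[p_seg[act]] * dt
    # spawn stimuli due in (t - dt, t], partially advanced to the step edge
    while (stIdx <= nrow(st) && st$time_s[stIdx] <= t + 1e-15) {
      t0 <- st$time_s[stIdx]; n <- st$node_id[stIdx]
      lab <- st$label[stIdx]
      adv <- (t - t0)
      cands <- outSegs[[n]]
      if (length(cands)) {
        for (s in cands)
          addPulse(s, adv * vum[s], +1, t0, config$initialEnergy, lab)
      } else {
        for (s in inSegs[[n]])
          addPulse(s, segs$length_um[s] - adv * vum[s], -1, t0,
                   config$initialEnergy, lab)
      }
      stIdx <- stIdx + 1L
    }
    # head-on crossings: opposite-direction pulses whose fronts crossed
    for (s in unique(p_seg[p_alive])) {
      ids <- which(p_alive & p_seg == s)
      plus <- ids[p_dir[ids] > 0]; minus <- ids[p_dir[ids] < 0]
      for (a in plus) for (b in minus) {
        if (!p_alive[a] || !p_alive[b]) next
        if (p_pos[a] >= p_pos[b]) {
          logEvent(t, "HEAD_ON_ANNIHILATION", c(a, b), segment = segs$id[s],
                   pos = (p_pos[a] + p_pos[b]) / 2,
                   label = if (p_label[a] == p_label[b]) p_label[a] else
                     "MIXED")
          kill(a, "annihilated"); kill(b, "annihilated")
        }
      }
    }
    # node arrivals, in pulse-id order
    for (p in which(p_alive)) {
      s <- p_seg[p]; L <- segs$length_um[s]
      if (p_dir[p] > 0 && p_pos[p] >= L - 1e-12) {
        handleArrival(p, segs$target[s], t, p_pos[p] - L)
      } else if (p_dir[p] < 0 && p_pos[p] <= 1e-12) {
        handleArrival(p, segs$source[s], t, -p_pos[p])
      }
    }
    t <- t + dt
    if (t > horizon) break
  }

  fates <- ifelse(is.na(p_fate), "active", p_fate)
  cfgEcho <- c(config,
               list(horizon = horizon, engine = "oracle", dt = dt,
                    terminals = names(roles)[roles == "TERMINAL"]))
  .buildLog(ev, fates, arrivals, cfgEcho)
}
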