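test_that("a single pulse crosses a 100 um segment at 1 m/s in 100 us", {
  g <- generateChain(1, 100)
  log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-3)
  expect_equal(arrivalTimes(log)$terminal, 1e-4)
  expect_identical(events(log)$kind,
                   c("SPAWN", "FRONT_AT_NODE", "TERMINAL_EXIT"))
  expect_equal(outputPhasePattern(log), list(terminal = 1e-4))
  expect_error(outputPhasePattern(log, "nonsense"), "unknown terminal")
})

test_that("simultaneous opposite stimuli annihilate mid-edge with no exits", {
  g <- generateCollisionEdge(100)
  log <- simulatePulses(g, stimulusSchedule(c("e1", "e2"), c(0, 0)), 1e-3)
  e <- events(log)
  hit <- e[e$kind == "HEAD_ON_ANNIHILATION", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$position_um, 50)
  expect_equal(hit$time_s, 50e-6)
  expect_identical(unname(counters(log)[["exited"]]), 2L * 0L)
  expect_identical(unname(counters(log)[["annihilated"]]), 2L)

  # staggered entries meet off-centre: t = 0 and 20 us -> x = 60, t = 60 us
  log2 <- simulatePulses(g, stimulusSchedule(c("e1", "e2"), c(0, 20e-6)),
                         1e-3)
  hit2 <- events(log2)[events(log2)$kind == "HEAD_ON_ANNIHILATION", ]
  expect_equal(hit2$position_um, 60)
  expect_equal(hit2$time_s, 60e-6)

  # a single-ended stimulus traverses and exits at the far entry
  log3 <- simulatePulses(g, stimulusSchedule("e1", 0), 1e-3)
  expect_identical(unname(counters(log3)[["exited"]]), 1L)
})

test_that("in-phase arrivals at a junction merge to a single exit", {
  g <- generateLadder(1, 2, 100)
  log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-2)
  ct <- counters(log)
  expect_identical(unname(ct[["spawned"]]), 2L)
  expect_identical(unname(ct[["merged"]]), 1L)
  expect_identical(unname(ct[["exited"]]), 1L)
  expect_identical(sum(events(log)$kind == "MERGE"), 1L)
  expect_length(arrivalTimes(log)$terminal, 1)
})

test_that("an out-of-phase second arrival is annulled by the refractory tail", {
  # limbs differ by 100 um -> arrivals differ by 100 us, inside (tol, tau)
  g <- asymmetricMotif(100, 200)
  log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-2)
  ct <- counters(log)
  expect_identical(unname(ct[["annulled"]]), 1L)
  expect_identical(unname(ct[["exited"]]), 1L)
  expect_identical(sum(events(log)$kind == "ANNUL"), 1L)
  # the survivor is the early (short-limb) pulse
  expect_equal(arrivalTimes(log)$terminal, 2e-4)

  # a second arrival beyond tau passes: limbs differ by 3 ms of travel
  g2 <- asymmetricMotif(100, 3100)
  log2 <- simulatePulses(g2, stimulusSchedule("entry", 0), 1e-1)
  expect_identical(unname(counters(log2)[["exited"]]), 2L)
})

test_that("phase diffraction copies a pulse down every branch", {
  g <- generateBinaryTree(3, 50)
  log <- simulatePulses(g, stimulusSchedule("root", 0), 1e-2)
  ct <- counters(log)
  expect_identical(unname(ct[["exited"]]), 8L)
  expect_identical(unname(ct[["spawned"]]),
                   unname(ct[["exited"]]))
  # all arrivals simultaneous at depth * 50 us
  arr <- unlist(arrivalTimes(log))
  expect_true(all(abs(arr - 150e-6) < 1e-12))
})

test_that("energy dissipates per segment and failure stops propagation", {
  dyn <- membraneDynamics(dissipationRate = 0.005,
                          activationThreshold = 0.6)
  g <- generateChain(1, 100, dyn)  # residual = 1 - 0.5 = 0.5 < 0.6
  log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-2)
  expect_identical(unname(counters(log)[["failed"]]), 1L)
  expect_identical(unname(counters(log)[["exited"]]), 0L)
  expect_identical(sum(events(log)$kind == "PULSE_FAILURE"), 1L)

  # boundary: residual exactly at threshold still activates
  dyn2 <- membraneDynamics(dissipationRate = 0.005,
                           activationThreshold = 0.5)
  g2 <- generateChain(1, 100, dyn2)
  log2 <- simulatePulses(g2, stimulusSchedule("entry", 0), 1e-2)
  expect_identical(unname(counters(log2)[["exited"]]), 1L)

  # multi-segment: energy decays cumulatively, failing mid-chain
  dyn3 <- membraneDynamics(dissipationRate = 0.004,
                           activationThreshold = 0.3)
  g3 <- generateChain(3, 100, dyn3)  # residuals 0.6, 0.2 -> fails at node 2
  log3 <- simulatePulses(g3, stimulusSchedule("entry", 0), 1e-2)
  e3 <- events(log3)
  expect_identical(e3$node[e3$kind == "PULSE_FAILURE"], "p2")
  expect_identical(unname(counters(log3)[["exited"]]), 0L)
})

test_that("event logs conserve pulses and respect causality", {
  for (seed in 1:8) {
    sc <- randomScenario(seed)
    log <- simulatePulses(sc$graph, sc$schedule, sc$horizon)
    expectConservation(log)
    e <- events(log)
    if (nrow(e)) {
      expect_true(all(diff(e$time_s) >= 0))  # sorted by processing order
      expect_gte(min(e$time_s), min(stimuli(sc$schedule)$time_s))
    }
  }
  # horizon cuts runs mid-flight: the still-active pulse is counted
  g <- generateChain(1, 100)
  log <- simulatePulses(g, stimulusSchedule("entry", 0), 5e-5)
  expect_identical(unname(counters(log)[["active"]]), 1L)
  expectConservation(log)
})

test_that("identical runs produce byte-identical canonical logs", {
  sc <- randomScenario(99)
  l1 <- simulatePulses(sc$graph, sc$schedule, sc$horizon)
  l2 <- simulatePulses(sc$graph, sc$schedule, sc$horizon)
  expect_identical(canonLines(l1), canonLines(l2))
  expect_identical(events(l1), events(l2))
})

test_that("doubling every segment velocity exactly halves every event time", {
  scenarios <- list(
    list(g = generateChain(3, 100), s = stimulusSchedule("entry", 0)),
    list(g = generateCollisionEdge(100),
         s = stimulusSchedule(c("e1", "e2"), c(0, 0))),
    list(g = generateLadder(2, 2, 100), s = stimulusSchedule("entry", 0)),
    list(g = asymmetricMotif(100, 110), s = stimulusSchedule("entry", 0)))
  for (sc in scenarios) {
    slow <- simulatePulses(sc$g, sc$s, 1e-1)
    fast <- sc$g
    fast@segments$velocity_m_per_s <- fast@segments$velocity_m_per_s * 2
    lfast <- simulatePulses(fast, sc$s, 1e-1)
    expect_identical(events(slow)$kind, events(lfast)$kind)
    expect_equal(events(lfast)$time_s, events(slow)$time_s / 2)
  }
})

test_that("non-interacting branches keep their own arrival times", {
  # one entry feeding two chains that never reconverge: each branch's
  # output matches the same chain simulated alone
  nodes <- data.frame(id = c("entry", "tA", "mB", "tB"),
                      role = c("ENTRY", "TERMINAL", "PASS", "TERMINAL"))
  segs <- rbind(segRow("sA", "entry", "tA", 100),
                segRow("sB1", "entry", "mB", 70),
                segRow("sB2", "mB", "tB", 70))
  g <- neuriteGraph(nodes, segs)
  log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-2)
  expect_equal(arrivalTimes(log)$tA, 1e-4)
  expect_equal(arrivalTimes(log)$tB, 1.4e-4)
  alone <- simulatePulses(generateChain(2, 70),
                          stimulusSchedule("entry", 0), 1e-2)
  expect_equal(arrivalTimes(log)$tB, arrivalTimes(alone)$terminal)
})

test_that("engine rejects bad schedules and invalid graphs", {
  g <- generateChain(2, 50)
  expect_error(simulatePulses(g, stimulusSchedule("terminal", 0), 1e-3),
               "non-ENTRY")
  expect_error(simulatePulses(g, stimulusSchedule("entry", 2e-3), 1e-3),
               "horizon")
  bad <- neuriteGraph(data.frame(id = "a", role = "ENTRY"),
                      segRow("s", "a", "ghost", 10))
  expect_error(simulatePulses(bad, stimulusSchedule("a", 0), 1e-3),
               "invalid graph")
})

test_that("empty schedules yield empty logs from both engines", {
  g <- generateChain(2, 50)
  s <- stimulusSchedule()
  le <- simulatePulses(g, s, 1e-3)
  lo <- oracleSimulate(g, s, 1e-3, dt = 1e-6)
  expect_identical(nrow(events(le)), 0L)
  expect_identical(nrow(events(lo)), 0L)
  expect_identical(unname(counters(le)[["spawned"]]), 0L)
})
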