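test_that("ladder generator produces the documented structure", {
  g <- generateLadder(1, 2, 100)
  nd <- graphNodes(g); sg <- graphSegments(g)
  expect_identical(sum(nd$role == "ENTRY"), 1L)
  expect_identical(sum(nd$role == "CONVERGE"), 1L)
  expect_identical(sum(nd$role == "TERMINAL"), 1L)
  expect_identical(nrow(sg), 3L)  # 2 parallel + 1 output
  expect_identical(sum(sg$source == "entry"), 2L)

  # node count = nLayers + 2; segment count = nLayers * nParallel + 1
  g3 <- generateLadder(3, 3, 100)
  expect_identical(nrow(graphNodes(g3)), 5L)
  expect_identical(nrow(graphSegments(g3)), 10L)
  # verify by traversal: every conv node has nParallel in-edges
  sg3 <- graphSegments(g3)
  for (cv in c("conv1", "conv2", "conv3"))
    expect_identical(sum(sg3$target == cv), 3L)

  expect_error(generateLadder(0, 2, 100))
  expect_error(generateLadder(2, 2, -5))
})

test_that("generators are deterministic under a fixed seed", {
  g1 <- generateLadder(2, 2, 100, jitterSd = 1, seed = 42)
  g2 <- generateLadder(2, 2, 100, jitterSd = 1, seed = 42)
  expect_identical(graphSegments(g1), graphSegments(g2))
  g3 <- generateLadder(2, 2, 100, jitterSd = 1, seed = 43)
  expect_false(identical(graphSegments(g1)$length_um,
                         graphSegments(g3)$length_um))
  # jittered lengths stay positive even with absurd jitter
  g4 <- generateLadder(2, 2, 1, jitterSd = 50, seed = 1)
  expect_true(all(graphSegments(g4)$length_um > 0))
})

test_that("collision edge has two entries sharing one segment", {
  g <- generateCollisionEdge(100)
  expect_identical(graphNodes(g)$role, c("ENTRY", "ENTRY"))
  expect_identical(nrow(graphSegments(g)), 1L)
  expect_length(validateGraph(g), 0)
  expect_error(generateCollisionEdge(0))
})

test_that("binary tree fans one pulse out to 2^depth terminals", {
  g <- generateBinaryTree(3, 50)
  nd <- graphNodes(g)
  expect_identical(sum(nd$role == "TERMINAL"), 8L)
  expect_identical(nrow(graphSegments(g)), 2L + 4L + 8L)
  expect_length(validateGraph(g), 0)
})

test_that("all generated graphs pass validation with zero diagnostics", {
  gs <- list(generateLadder(1, 2, 100), generateLadder(3, 4, 80),
             generateLadder(2, 1, 100),  # chain-shaped ladder
             generateCollisionEdge(10), generateChain(4, 25),
             generateBinaryTree(2, 60),
             generateLadder(2, 2, 100, jitterSd = 5, seed = 7))
  for (g in gs) expect_length(validateGraph(g), 0)
})

test_that("validateGraph reports one diagnostic per violation", {
  # segment referencing a missing node
  g <- neuriteGraph(data.frame(id = c("a", "b"), role = c("ENTRY", "TERMINAL")),
                    segRow("s1", "a", "ghost", 10))
  d <- validateGraph(g)
  expect_length(d, 1)
  expect_match(d, "ghost")

  # disconnected components
  g2 <- neuriteGraph(
    data.frame(id = c("a", "b", "c", "d"),
               role = c("ENTRY", "TERMINAL", "ENTRY", "TERMINAL")),
    rbind(segRow("s1", "a", "b", 10), segRow("s2", "c", "d", 10)))
  expect_identical(validateGraph(g2), "graph is not connected")

  # role annotations that do not match structure
  g3 <- neuriteGraph(
    data.frame(id = c("a", "b"), role = c("BRANCH", "TERMINAL")),
    segRow("s1", "a", "b", 10))
  expect_match(validateGraph(g3), "BRANCH")

  # bad physical parameters
  g4 <- neuriteGraph(data.frame(id = c("a", "b"),
                                role = c("ENTRY", "TERMINAL")),
                     segRow("s1", "a", "b", -1))
  expect_match(validateGraph(g4), "length")
})

test_that("membrane dynamics rejects unphysical parameters", {
  expect_error(membraneDynamics(velocity = 0))
  expect_error(membraneDynamics(refractoryDuration = -1))
  expect_error(membraneDynamics(channelSpacing = 0))
  d <- membraneDynamics()
  expect_identical(d@velocity, 1.0)
  expect_identical(d@channelSpacing, 1.5)
})

test_that("stimulus schedules validate node times and labels", {
  s <- stimulusSchedule("entry", c(0, 1e-3), "SIGNAL")
  expect_identical(nrow(stimuli(s)), 2L)
  expect_error(stimulusSchedule("entry", -1), "times")
  expect_error(stimulusSchedule("entry", 0, "JUNK"), "label")
})
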