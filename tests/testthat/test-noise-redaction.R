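test_that("noise injection is Poisson, seeded and label-preserving", {
  s <- stimulusSchedule("entry", c(0, 1e-2))
  expect_identical(injectNoise(s, 0, 1e-1), s)
  n1 <- injectNoise(s, 100, 1e-1, seed = 7)
  n2 <- injectNoise(s, 100, 1e-1, seed = 7)
  expect_identical(stimuli(n1), stimuli(n2))
  expect_true(all(stimuli(n1)$label[-(1:2)] == "NOISE"))
  expect_error(injectNoise(s, -1, 1e-1))

  # empirical mean of injected counts matches lambda * T * n_entries
  s2 <- stimulusSchedule(c("a", "b"), c(0, 0))
  lambda <- 200; Th <- 0.05  # expect 10 per entry, 20 total
  counts <- vapply(1:200, function(i) {
    sum(stimuli(injectNoise(s2, lambda, Th, seed = i))$label == "NOISE")
  }, numeric(1))
  expected <- lambda * Th * 2
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("out-of-phase noise is fully redacted on a 2-parallel ladder", {
  # a single noise spike offset 0.5 tau from the signal never exits
  r <- runRedactionExperiment(1, 2, nSignals = 1,
                              noiseMode = "outOfPhase", noiseOffset = 1e-3)
  expect_identical(r@noiseInjected, 1L)
  expect_identical(r@noiseExits, 0L)
  expect_identical(redactionFraction(r), 1)
  expect_identical(r@signalExits, 1L)

  # random out-of-phase offsets, several signals, depths 1..3
  for (depth in 1:3) {
    r <- runRedactionExperiment(depth, 2, noiseMode = "outOfPhase",
                                seed = depth)
    expect_identical(redactionFraction(r), 1)
    expect_identical(r@signalExits, r@signalInjected)
  }
})

test_that("nothing is redacted on a single chain", {
  r <- runRedactionExperiment(2, 1, noiseMode = "outOfPhase", seed = 3)
  expect_identical(redactionFraction(r), 0)
  expect_identical(r@noiseExits, r@noiseInjected)
})

test_that("in-phase noise merges with the signal and is reported separately", {
  # offset far below the merge tolerance (1.5 us at defaults)
  r <- runRedactionExperiment(1, 2, nSignals = 2,
                              noiseMode = "outOfPhase", noiseOffset = 1e-7)
  expect_identical(r@noiseExits, 0L)
  expect_gt(r@noiseMerged, 0)
  expect_identical(redactionFraction(r), 1)
  expect_identical(r@signalExits, 2L)
})

test_that("signal exits are unaffected by redacted noise", {
  clean <- runRedactionExperiment(2, 2, nSignals = 3, noiseMode = "outOfPhase",
                                  noiseOffset = 1e-9, seed = 5)
  noisy <- runRedactionExperiment(2, 2, nSignals = 3, noiseMode = "outOfPhase",
                                  seed = 5)
  expect_identical(clean@signalExits, noisy@signalExits)
})

test_that("redaction does not decrease with ladder depth", {
  tab <- redactionVsDepth(3, reps = 10, seed = 100)
  expect_identical(tab$layers, 1:3)
  expect_true(all(diff(tab$meanRedaction) >= 0))
  expect_equal(tab$meanRedaction[3], 1)
})

test_that("redaction fraction is NA when no noise is injected", {
  r <- runRedactionExperiment(1, 2, noiseRate = 0, noiseMode = "poisson")
  expect_true(is.na(redactionFraction(r)))
  expect_identical(r@noiseInjected, 0L)
})

test_that("per-layer survival shows noise dying at the first junction", {
  r <- runRedactionExperiment(3, 2, noiseMode = "outOfPhase", seed = 9)
  ls <- r@layerSurvival
  expect_identical(nrow(ls), 3L)
  expect_gt(ls$noiseArrived[1], 0)
  expect_identical(ls$noiseSurvived[1], 0L)
  expect_identical(ls$noiseArrived[2], 0L)
})
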