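test_that("ternary state is +1 at the front, -1 in the tail, 0 elsewhere", {
  # 1 m/s = 1 um/us front speed, 2 ms refractory tail
  p <- capPulse(birthTime = 0, segmentLength = 5000, position = 0,
                direction = 1, velocity = 1, refractoryDuration = 2e-3)
  t <- 1e-3  # front at 1000 um
  expect_identical(ternaryState(p, 1500, t), 0)   # resting, ahead
  expect_identical(ternaryState(p, 1000, t), 1)   # at the front
  # entry point was passed 1 ms = 0.5 tau ago: refractory
  expect_identical(ternaryState(p, 0, t), -1)
})

test_that("ternary tail window follows the front by exactly tau", {
  p <- capPulse(birthTime = 0, segmentLength = 1e4, position = 0,
                direction = 1, velocity = 1, refractoryDuration = 2e-3)
  # x = 1000 um is passed at t = 1 ms; refractory until 3 ms (half-open)
  expect_identical(ternaryState(p, 1000, 2e-3), -1)   # 0.5 tau after passage
  expect_identical(ternaryState(p, 1000, 5e-3), 0)    # 2 tau after passage
  # no acausal phase: everything is 0 before birth
  for (x in c(0, 500, 9999)) expect_identical(ternaryState(p, x, -1e-6), 0)
  expect_error(ternaryState(p, 1e4 + 1, 0), "off")
})

test_that("residual energy dissipates linearly and floors at zero", {
  expect_identical(residualEnergy(7, 0, 1e6), 7)
  expect_identical(residualEnergy(10, 0.05, 100), 5)
  expect_identical(residualEnergy(1, 1, 100), 0)
  expect_error(residualEnergy(-1, 0, 1))
  expect_error(residualEnergy(1, -0.1, 1))
  # non-increasing in distance and rate, exactly linear above the floor
  d <- seq(0, 300, by = 25)
  e <- vapply(d, function(x) residualEnergy(10, 0.05, x), numeric(1))
  expect_true(all(diff(e) <= 0))
  lin <- 10 - 0.05 * d
  expect_equal(e[lin >= 0], lin[lin >= 0])
  expect_true(all(e[lin < 0] == 0))
})

test_that("activation is boundary-inclusive", {
  expect_true(canActivate(5, 4))
  expect_false(canActivate(3, 4))
  expect_true(canActivate(4, 4))  # exactly at threshold activates
})

test_that("in-phase test is a symmetric closed tolerance band", {
  expect_true(inPhase(3e-3, 3e-3, 0))
  expect_true(inPhase(0, 0.5e-6, 1e-6))
  expect_false(inPhase(0, 2e-6, 1e-6))
  expect_identical(inPhase(1, 2, 0.5), inPhase(2, 1, 0.5))
})

test_that("node arrival resolution partitions (delta, tau, tol) exhaustively", {
  tau <- 2e-3; tol <- 1.5e-6
  expect_identical(resolveNodeArrival(NULL, 0.1, tau, tol), "PASS")
  expect_identical(resolveNodeArrival(NA, 0.1, tau, tol), "PASS")
  expect_identical(resolveNodeArrival(0.1, 0.1, tau, tol), "MERGE")
  expect_identical(resolveNodeArrival(0.1, 0.1 + 0.5 * tau, tau, tol),
                   "ANNUL_SECOND")
  expect_identical(resolveNodeArrival(0.1, 0.1 + 1.5 * tau, tau, tol),
                   "PASS")
  # half-open refractory window: arrival exactly at tau passes;
  # arrival exactly at the merge tolerance merges (deltas exact in binary)
  expect_identical(resolveNodeArrival(0, tau, tau, tol), "PASS")
  expect_identical(resolveNodeArrival(0, tol, tau, tol), "MERGE")
  expect_error(resolveNodeArrival(0.2, 0.1, tau, tol), "ordering")

  # exhaustive: every (delta, tau, tol) with 0 <= tol < tau maps to exactly
  # one outcome, and the expected one
  set.seed(1)
  for (i in 1:200) {
    tau <- stats::runif(1, 1e-4, 1e-2)
    tol <- stats::runif(1, 0, tau * 0.99)
    delta <- stats::runif(1, 0, 2 * tau)
    out <- resolveNodeArrival(1, 1 + delta, tau, tol)
    expected <- if (delta <= tol) "MERGE" else
      if (delta < tau) "ANNUL_SECOND" else "PASS"
    expect_identical(out, expected)
  }
})

test_that("head-on resolution annihilates both at the crossing point", {
  a <- capPulse("a", 0, "edge", 100, 0, +1)
  b <- capPulse("b", 0, "edge", 100, 100, -1)
  out <- resolveHeadOn(a, b)
  expect_identical(out@kind, "MUTUAL_ANNIHILATION")
  expect_length(out@survivors, 0)
  expect_equal(out@position, 50)   # symmetric entries meet at the midpoint
  expect_equal(out@time, 50e-6)

  # staggered entries: 100 um edge at 1 um/us, t = 0 and t = 20 us
  b2 <- capPulse("b", 20e-6, "edge", 100, 100, -1)
  out2 <- resolveHeadOn(a, b2)
  expect_equal(out2@position, 60)
  expect_equal(out2@time, 60e-6)

  # symmetric in argument order
  swapped <- resolveHeadOn(b2, a)
  expect_equal(swapped@time, out2@time)
  expect_equal(swapped@position, out2@position)

  expect_error(resolveHeadOn(a, capPulse("c", 0, "edge", 100, 50, +1)),
               "chase")
  expect_error(resolveHeadOn(a, capPulse("c", 0, "other", 100, 50, -1)),
               "different segments")
})

test_that("head-on meeting matches a brute-force time-stepped search", {
  set.seed(42)
  for (i in 1:10) {
    L <- sample(50:150, 1)
    tb <- sample(0:20, 1) * 1e-6
    a <- capPulse("a", 0, "edge", L, 0, +1)
    b <- capPulse("b", tb, "edge", L, L, -1)
    out <- resolveHeadOn(a, b)
    # brute force: march both fronts with a fine step
    dt <- 1e-8; v <- 1e6  # um/s
    t <- tb; xa <- v * tb; xb <- L
    while (xa < xb) {
      t <- t + dt
      xa <- xa + v * dt
      xb <- xb - v * dt
    }
    expect_lt(abs(t - out@time), 2 * dt)
    expect_lt(abs((xa + xb) / 2 - out@position), 2 * dt * v)
  }
})
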