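test_that("battery drains 5%/step and recharges at the 30% threshold", {
  tr <- batteryTrace(25)
  ## the printed reference trace: 35 at step 13, then a recharge after
  ## step 14 gives 85/65/45 at steps 17/21/25
  expect_equal(tr$trace[13], 35)
  expect_equal(tr$trace[17], 85)
  expect_equal(tr$trace[21], 65)
  expect_equal(tr$trace[25], 45)
  expect_equal(tr$charges, 2L)
  short <- batteryTrace(10)
  expect_equal(short$trace[10], 50)
  expect_equal(short$charges, 1L)
  ## trace values stay in (0, 100] and the battery never starts a step
  ## at or below the threshold
  long <- batteryTrace(200)
  expect_true(all(long$trace > 0 & long$trace <= 100))
  expect_equal(long$charges, 1L + sum(long$trace <= 30))
})

test_that("non-scouting flies nothing and condemns the whole field", {
  fx <- scoutFixtures()
  f <- fx$data$test[[1]]
  m <- runMission("non_scouting", f)
  expect_equal(nrow(flightPath(m)), 0L)
  expect_equal(chargesUsed(m), 1L)
  expect_true(all(predictedMap(m) == 0L))
  met <- mapMetrics(confusionCounts(predictedMap(m), truthMap(f)))
  expect_equal(met[["posRecall"]], 0)
  expect_equal(met[["negRecall"]], 1)
})

test_that("exhaustive scouting is serpentine and exactly right", {
  f <- FieldGrid(generateTruthMap(syntheticFieldSpec(rows = 3, cols = 3,
                                                     seed = 5)))
  m <- runMission("exhaustive", f)
  p <- flightPath(m)
  expect_equal(nrow(p), 9L)
  expect_equal(p[1:4, 2], c(1L, 2L, 3L, 3L))  # row 1 L-to-R, then down
  ## consecutive zones are flight-adjacent
  expect_true(all(pmax(abs(diff(p[, 1])), abs(diff(p[, 2]))) == 1))
  expect_identical(predictedMap(m), truthMap(f))
})

test_that("sampling missions hit the coverage target exactly", {
  fx <- scoutFixtures()
  f <- fx$data$test[[1]]
  for (cov in c(0.1, 0.4)) {
    m <- runMission("whole_field", f, cov, fx$ens, fx$ref, fx$rl,
                    windowSize = 7L, seed = 3)
    expect_equal(nrow(flightPath(m)), ceiling(cov * 256))
    expect_equal(nrow(unique(flightPath(m))), nrow(flightPath(m)))
    expect_false(any(is.na(predictedMap(m))))
    expect_true(all(m@batteryTrace > 0 & m@batteryTrace <= 100))
    expect_equal(m@coverage, nrow(flightPath(m)) / 256)
  }
})

test_that("missions are reproducible under a seed", {
  fx <- scoutFixtures()
  f <- fx$data$test[[1]]
  m1 <- runMission("whole_field", f, 0.3, fx$ens, fx$ref, fx$rl,
                   windowSize = 7L, seed = 8)
  m2 <- runMission("whole_field", f, 0.3, fx$ens, fx$ref, fx$rl,
                   windowSize = 7L, seed = 8)
  expect_identical(flightPath(m1), flightPath(m2))
  expect_identical(predictedMap(m1), predictedMap(m2))
  expect_identical(m1@batteryTrace, m2@batteryTrace)
  ## and sensitive to the seed
  m3 <- runMission("whole_field", f, 0.3, fx$ens, fx$ref, fx$rl,
                   windowSize = 7L, seed = 9)
  expect_false(identical(flightPath(m1), flightPath(m3)))
})

test_that("relocation flights drain one step per zone of distance", {
  fx <- scoutFixtures()
  f <- fx$data$test[[1]]
  m <- runMission("random", f, 0.5, seed = 4)
  p <- flightPath(m)
  jumps <- pmax(abs(diff(p[, 1])), abs(diff(p[, 2])))
  drained <- (100 - m@batteryTrace[1]) / 5 + sum(pmax(jumps, 1))
  recharges <- m@charges - 1L
  ## total drain equals steps flown; recharges account for the refills
  expect_equal(m@batteryTrace[length(m@batteryTrace)],
               100 - 5 * drained + recharges * (100 - 30))
})

test_that("local-field missions complete their map by dilation", {
  fx <- scoutFixtures()
  f <- fx$data$test[[1]]
  m <- runMission("local_field", f, 0.3, localDataset = scoutLocalDataset(),
                  seed = 6)
  expect_equal(nrow(flightPath(m)), ceiling(0.3 * 256))
  expect_false(any(is.na(predictedMap(m))))
  ## visited zones carry ground truth
  vis <- flightPath(m)
  expect_identical(predictedMap(m)[vis], truthMap(f)[vis])
})

test_that("policies needing models refuse to fly without them", {
  f <- scoutFixtures()$data$test[[1]]
  expect_error(runMission("whole_field", f, 0.3), "needs ensemble")
  expect_error(runMission("local_field", f, 0.3), "local-encoded dataset")
})
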