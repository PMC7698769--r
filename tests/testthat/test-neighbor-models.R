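test_that("directional predictors reach held-out single-zone accuracy >= 0.8", {
  fx <- scoutFixtures()
  hold <- computeTileFeatures(fx$data$test[[1]])
  d <- fieldDim(hold); tm <- truthMap(hold)
  dirs <- compassDirections()
  ctr <- as.matrix(expand.grid(row = 2:(d[1] - 1), col = 2:(d[2] - 1)))
  for (k in 1:8) {
    nb <- cbind(ctr[, 1] + dirs$drow[k], ctr[, 2] + dirs$dcol[k])
    X <- hold@features[nb[, 1] + (nb[, 2] - 1) * d[1], , drop = FALSE]
    p <- predictDirection(fx$ens, k, X)
    expect_gte(mean((p >= 0.5) == (tm[ctr] == 1)), 0.8)
  }
})

test_that("one-class training degrades to a healthy-leaning constant", {
  spec <- syntheticFieldSpec(rows = 6, cols = 6, tilePx = 8,
                             unhealthyFraction = 0, seed = 4)
  ens <- trainDirectional(generateField(spec))
  X <- rbind(tileFeatures(withSeed(1, renderZoneTile(spec, 0L))))
  for (k in 1:8) {
    p <- predictDirection(ens, k, X)
    expect_gte(p, 0.5)
    expect_lt(p, 1)  # smoothed, never certain
  }
})

test_that("training and prediction are deterministic", {
  fx <- scoutFixtures()
  ens2 <- trainDirectional(fx$data$train)
  X <- fx$data$train[[1]]@features[1:5, , drop = FALSE]
  expect_identical(predictDirection(fx$ens, 3, X), predictDirection(ens2, 3, X))
})

test_that("ensemblePredict averages over visible neighbours", {
  ## stub: every direction returns the same p, so the mean is p and the
  ## label flips at 0.5
  field <- FieldGrid(matrix(1L, 5, 5))
  part <- partitionField(rbind(c(3, 3)), c(5, 5))
  win <- extractWindow(field, part, c(3, 3), 5L)
  one <- ensemblePredict(c(2, 3), win, constantEnsemble(0.9))
  expect_equal(one$confHealthy, 0.9)
  expect_equal(one$label, 1L)
  low <- ensemblePredict(c(2, 3), win, constantEnsemble(0.2))
  expect_equal(low$label, 0L)
  expect_equal(low$confidence, 0.8)
  ## no visible neighbour in the window -> state error
  expect_error(ensemblePredict(c(5, 5), win, constantEnsemble(0.9)),
               "no visible neighbour")
})

test_that("ensemblePredict equals a brute-force neighbour mean", {
  fx <- scoutFixtures()
  field <- computeTileFeatures(fx$data$test[[1]])
  d <- fieldDim(field)
  dirs <- compassDirections()
  withSeed(23, for (rep in 1:5) {
    mask <- matrix(FALSE, d[1], d[2]); mask[sample(prod(d), 30)] <- TRUE
    part <- partitionField(mask)
    ctr <- which(mask, arr.ind = TRUE)[1, ]
    win <- extractWindow(field, part, ctr, 7L)
    s <- statusMap(part)
    ## pick a neighbour-area target inside the window
    sp <- windowSpan(win)
    cand <- which(s[sp$rows, sp$cols] == ZONE_NEIGHBOR, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    tg <- c(sp$rows[cand[1, 1]], sp$cols[cand[1, 2]])
    got <- ensemblePredict(tg, win, fx$ens)
    ## oracle: enumerate visible 8-neighbours explicitly on the full grid,
    ## restricted to the window span
    ps <- c()
    for (k in 1:8) {
      nb <- tg + c(dirs$drow[k], dirs$dcol[k])
      if (nb[1] < min(sp$rows) || nb[1] > max(sp$rows) ||
          nb[2] < min(sp$cols) || nb[2] > max(sp$cols)) next
      if (!mask[nb[1], nb[2]]) next
      X <- field@features[nb[1] + (nb[2] - 1) * d[1], , drop = FALSE]
      ps <- c(ps, predictDirection(fx$ens, k, X))
    }
    expect_equal(got$confHealthy, mean(ps))
  })
})

test_that("buildReference scores held-out tiles with calibrated confidence", {
  fx <- scoutFixtures()
  expect_length(fx$ref@conf, 150)
  expect_true(all(fx$ref@conf >= 0 & fx$ref@conf <= 1))
  ## an all-healthy tile set scores confidently healthy on median
  spec <- fx$spec
  healthyTiles <- withSeed(12, lapply(1:40, function(i)
    renderZoneTile(spec, 1L)))
  refH <- buildReference(healthyTiles, fx$ens)
  expect_gt(median(refH@conf), 0.5)
  expect_error(buildReference(list(), fx$ens), "empty")
  ## deterministic rebuild
  refB <- buildReference(fx$data$referenceTiles, fx$ens)
  expect_identical(refB@conf, fx$ref@conf)
})

test_that("nearestReference picks the closest confidence, stable on ties", {
  r <- ReferenceSet(c(0.60, 0.90))
  expect_equal(nearestReference(r, 0.70), 1L)
  expect_equal(nearestReference(r, 0.90), 2L)
  expect_equal(nearestReference(r, 0.75), 1L)  # equidistant: first entry
  ## exhaustive check on random small sets
  withSeed(3, for (rep in 1:20) {
    conf <- round(runif(8), 2)
    q <- runif(1)
    i <- nearestReference(ReferenceSet(conf), q)
    expect_true(all(abs(conf[i] - q) <= abs(conf - q)))
  })
})

test_that("model store round-trips through JSON", {
  fx <- scoutFixtures()
  path <- tempfile(fileext = ".json")
  saveModelStore(fx$ens, fx$ref, path)
  store <- loadModelStore(path)
  X <- fx$data$train[[1]]@features[1:4, , drop = FALSE]
  for (k in c(1, 5, 8))
    expect_equal(predictDirection(store$ensemble, k, X),
                 predictDirection(fx$ens, k, X), tolerance = 1e-12)
  expect_equal(store$ref@conf, fx$ref@conf, tolerance = 1e-12)
  unlink(path)
})
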