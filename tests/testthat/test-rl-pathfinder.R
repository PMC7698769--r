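test_that("randomPath covers the target and visits zones once", {
  p <- withSeed(2, randomPath(c(3, 3), 1))
  expect_equal(nrow(p), 9L)
  expect_equal(nrow(unique(p)), 9L)
  expect_identical(withSeed(9, randomPath(c(8, 8), 0.4)),
                   withSeed(9, randomPath(c(8, 8), 0.4)))
  expect_error(randomPath(c(3, 3), 0), "coverage")
  ## starts on the border
  for (s in 1:5) {
    p <- withSeed(s, randomPath(c(6, 6), 0.2))
    expect_true(p[1, 1] %in% c(1, 6) || p[1, 2] %in% c(1, 6))
  }
})

test_that("relocation targets the nearest unvisited zone (brute force)", {
  ## on a 1 x 5 strip the walk must dead-end and relocate; verify every
  ## non-adjacent jump against a brute-force nearest-unvisited scan
  for (s in 1:10) {
    p <- withSeed(s, randomPath(c(1, 5), 1, start = c(1, 2)))
    expect_equal(sort(p[, 2]), 1:5)
    visited <- matrix(FALSE, 1, 5)
    visited[p[1, 1], p[1, 2]] <- TRUE
    for (i in 2:nrow(p)) {
      d <- max(abs(p[i, ] - p[i - 1, ]))
      if (d > 1) {
        un <- which(!visited, arr.ind = TRUE)
        dmin <- min(pmax(abs(un[, 1] - p[i - 1, 1]),
                         abs(un[, 2] - p[i - 1, 2])))
        expect_equal(max(abs(p[i, ] - p[i - 1, ])), dmin)
      }
      visited[p[i, 1], p[i, 2]] <- TRUE
    }
  }
})

test_that("encodeState has fixed length 2w^2 + 1 and local L2 geometry", {
  w1 <- makeToyWindow(0.8)
  v1 <- encodeState(w1)
  expect_length(v1, 2 * 9 + 1)
  expect_equal(encodeState(makeToyWindow(0.8)), v1)  # identical windows
  ## perturbing one zone's prediction moves the vector by exactly that delta
  w2 <- w1
  w2@prob[1, 1] <- w2@prob[1, 1] + 0.25
  expect_equal(sqrt(sum((encodeState(w2) - v1)^2)), 0.25)
  ## w = 7 encodes to 99 dims
  field <- FieldGrid(matrix(1L, 9, 9))
  part <- partitionField(rbind(c(5, 5)), c(9, 9))
  win <- extractWindow(field, part, c(5, 5), 7L)
  fw <- fillWindow(win, constantEnsemble(0.9), ReferenceSet(0.9))
  expect_length(encodeState(fw), 99L)
  expect_error(encodeState(win), "filled")
})

test_that("buildRLDataset yields one record per transition", {
  field <- FieldGrid(generateTruthMap(
    syntheticFieldSpec(rows = 8, cols = 8, seed = 3)))
  rl <- buildRLDataset(field, coverage = 0.4, windowSize = 5L, nPaths = 10L,
                       ensemble = constantEnsemble(0.9),
                       ref = ReferenceSet(0.9), k = 11L, seed = 2L)
  len <- ceiling(0.4 * 64)
  expect_equal(nRecords(rl), 10L * (len - 1L))
  expect_true(all(rl@gains >= -1 & rl@gains <= 1))
  ## deterministic
  rl2 <- buildRLDataset(field, coverage = 0.4, windowSize = 5L, nPaths = 10L,
                        ensemble = constantEnsemble(0.9),
                        ref = ReferenceSet(0.9), k = 11L, seed = 2L)
  expect_identical(rl@states, rl2@states)
  expect_identical(rl@actions, rl2@actions)
})

test_that("revealing already-correctly-predicted zones gains no utility", {
  ## all-healthy field with a healthy-saying stub: every window prediction
  ## is already correct, so every step's utility gain is exactly zero
  field <- FieldGrid(matrix(1L, 8, 8))
  rl <- buildRLDataset(field, coverage = 0.3, windowSize = 5L, nPaths = 3L,
                       ensemble = constantEnsemble(0.9),
                       ref = ReferenceSet(0.9), k = 5L, seed = 7L)
  expect_true(all(rl@gains == 0))
})

test_that("selectAction flies toward the largest KNN-vs-model discrepancy", {
  win <- makeToyWindow(0.5)
  ## model says 0.1 everywhere; records say E's destination is healthy
  ens <- constantEnsemble(0.1)
  nl <- matrix(0, 10, 8); nl[, 3] <- 1  # E column
  ds <- makeToyDataset(states = matrix(rnorm(190), 10, 19),
                       actions = rep(1L, 10), gains = rep(0, 10),
                       nextLabels = nl)
  expect_equal(unname(selectAction(win, ds, ens)), 3L)  # E

  ## all discrepancies equal -> first direction in canonical order (N)
  nlTie <- matrix(0.5, 10, 8)
  dsTie <- makeToyDataset(states = matrix(rnorm(190), 10, 19),
                          actions = rep(1L, 10), gains = rep(0, 10),
                          nextLabels = nlTie)
  expect_equal(names(selectAction(win, dsTie, constantEnsemble(0.5))), "N")

  ## a dataset smaller than k is rejected at construction
  expect_error(makeToyDataset(states = matrix(rnorm(19), 1, 19),
                              actions = 1L, gains = 0,
                              nextLabels = nl[1, , drop = FALSE], k = 2L),
               "k may not exceed")
})

test_that("selectAction matches a brute-force KNN + argmax oracle", {
  withSeed(77, for (rep in 1:5) {
    win <- makeToyWindow(runif(1, 0.2, 0.8))
    q <- encodeState(win)
    n <- 20L; k <- 11L
    states <- matrix(rnorm(n * 19), n, 19)
    nl <- matrix(rbinom(n * 8, 1, 0.5), n, 8)
    p0 <- runif(1)
    ds <- makeToyDataset(states, sample(1:8, n, TRUE), runif(n, -1, 1), nl,
                         k = k)
    got <- unname(selectAction(win, ds, constantEnsemble(p0)))
    ## oracle: exhaustive distances, k smallest, per-action column means,
    ## argmax |knn - model| in canonical direction order
    d2 <- apply(states, 1, function(s) sum((s - q)^2))
    idx <- order(d2)[1:k]
    disc <- abs(colMeans(nl[idx, , drop = FALSE]) - p0)
    expect_equal(got, which.max(disc))
  })
})

test_that("selectActionUtility maximizes mean retrieved gain", {
  win <- makeToyWindow(0.5)
  ## only SE carries positive gain
  acts <- c(rep(4L, 3), rep(2L, 3), rep(7L, 4))
  gains <- c(0.5, 0.7, 0.6, 0, 0, 0, 0, 0, 0, 0)
  ds <- makeToyDataset(matrix(rnorm(190), 10, 19), acts, gains,
                       matrix(0.5, 10, 8))
  expect_equal(names(selectActionUtility(win, ds)), "SE")
  ## all gains zero -> N by tie-break
  dsZ <- makeToyDataset(matrix(rnorm(190), 10, 19), acts, rep(0, 10),
                        matrix(0.5, 10, 8))
  expect_equal(names(selectActionUtility(win, dsZ)), "N")
  ## brute-force agreement on a 50-record dataset
  withSeed(13, {
    n <- 50L; k <- 11L
    states <- matrix(rnorm(n * 19), n, 19)
    acts <- sample(1:8, n, TRUE)
    gains <- runif(n, -1, 1)
    ds <- makeToyDataset(states, acts, gains, matrix(0.5, n, 8), k = k)
    q <- encodeState(win)
    idx <- order(apply(states, 1, function(s) sum((s - q)^2)))[1:k]
    sc <- vapply(1:8, function(a) {
      g <- gains[idx][acts[idx] == a]
      if (!length(g)) 0 else mean(g)
    }, numeric(1))
    expect_equal(unname(selectActionUtility(win, ds)), which.max(sc))
  })
})
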