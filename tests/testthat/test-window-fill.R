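## Wavefront fixtures use label-only fields with a constant stub backend,
## which isolates the fill mechanics from model quality.

.stubWindow <- function(gridRows, gridCols, visited, center, w,
                        truth = NULL) {
  if (is.null(truth)) truth <- matrix(1L, gridRows, gridCols)
  field <- FieldGrid(truth)
  part <- partitionField(visited, c(gridRows, gridCols))
  extractWindow(field, part, center, w)
}

test_that("a fully visible window is a fixed point of fill", {
  win <- .stubWindow(5, 5, as.matrix(expand.grid(1:5, 1:5)), c(3, 3), 5L)
  out <- fillWindow(win, constantEnsemble(0.9), ReferenceSet(0.9))
  expect_identical(windowLabels(out), windowLabels(win))
  expect_identical(windowStatus(out), windowStatus(win))
})

test_that("the wavefront fills one Chebyshev ring per iteration", {
  ## 5x5 window, center visible: ring 1 after one iteration, full after 2
  win <- .stubWindow(5, 5, rbind(c(3, 3)), c(3, 3), 5L)
  it1 <- fillIteration(win, constantEnsemble(0.9), ReferenceSet(0.9))
  expect_equal(sum(windowStatus(it1) == ZONE_VISIBLE), 9L)
  it2 <- fillIteration(it1, constantEnsemble(0.9), ReferenceSet(0.9))
  expect_equal(sum(windowStatus(it2) == ZONE_VISIBLE), 25L)
  expect_true(all(windowLabels(it2) == 1L))  # p = 0.9 -> all healthy

  ## 7x7 needs exactly 3 iterations
  win7 <- .stubWindow(7, 7, rbind(c(4, 4)), c(4, 4), 7L)
  n <- 0L
  while (any(windowStatus(win7) != ZONE_VISIBLE)) {
    win7 <- fillIteration(win7, constantEnsemble(0.9), ReferenceSet(0.9))
    n <- n + 1L
  }
  expect_equal(n, 3L)
})

test_that("fill terminates within ceil((w-1)/2) iterations from the center", {
  for (w in c(5L, 7L, 11L)) {
    ctr <- c((w + 1L) %/% 2L, (w + 1L) %/% 2L)
    win <- .stubWindow(w, w, rbind(ctr), ctr, w)
    n <- 0L
    while (any(windowStatus(win) != ZONE_VISIBLE)) {
      win <- fillIteration(win, constantEnsemble(0.7), ReferenceSet(0.7))
      n <- n + 1L
    }
    expect_lte(n, ceiling((w - 1) / 2))
  }
})

test_that("fill is idempotent and conserves ground truth", {
  fx <- scoutFixtures()
  field <- computeTileFeatures(fx$data$test[[1]])
  withSeed(41, {
    mask <- matrix(FALSE, 16, 16)
    p <- randomPath(c(16, 16), 0.2)
    mask[p] <- TRUE
    part <- partitionField(mask)
    win <- extractWindow(field, part, p[1, ], 7L)
    f1 <- fillWindow(win, fx$ens, fx$ref)
    ## every zone determined
    expect_true(all(windowStatus(f1) == ZONE_VISIBLE))
    expect_false(any(is.na(windowLabels(f1))))
    ## originally observed zones keep their ground truth
    sp <- windowSpan(f1)
    tm <- truthMap(field)[sp$rows, sp$cols]
    obs <- windowStatus(win) == ZONE_VISIBLE
    expect_identical(windowLabels(f1)[obs], tm[obs])
    ## idempotence
    f2 <- fillWindow(f1, fx$ens, fx$ref)
    expect_identical(windowLabels(f2), windowLabels(f1))
    expect_identical(f2@prob, f1@prob)
  })
})

test_that("iteration predictions use only the pre-iteration visible set", {
  ## oracle: recompute each neighbour-zone prediction independently with
  ## an explicit per-zone loop over the frozen visible set; a sequential
  ## (order-dependent) fill would disagree
  fx <- scoutFixtures()
  field <- computeTileFeatures(fx$data$test[[1]])
  d <- fieldDim(field)
  dirs <- compassDirections()
  mask <- matrix(FALSE, d[1], d[2])
  mask[cbind(5:8, 5:8)] <- TRUE  # a diagonal: many multi-neighbour targets
  part <- partitionField(mask)
  win <- extractWindow(field, part, c(6, 6), 7L)
  it <- fillIteration(win, fx$ens, fx$ref)
  sp <- windowSpan(win)
  s0 <- windowStatus(win)
  newly <- which(s0 == ZONE_NEIGHBOR & it@status == ZONE_VISIBLE)
  expect_gt(length(newly), 0)
  for (i in newly) {
    rr <- ((i - 1) %% nrow(s0)) + 1; cc <- ((i - 1) %/% nrow(s0)) + 1
    tg <- c(sp$rows[rr], sp$cols[cc])
    ps <- c()
    for (k in 1:8) {
      nb <- tg + c(dirs$drow[k], dirs$dcol[k])
      if (nb[1] < min(sp$rows) || nb[1] > max(sp$rows) ||
          nb[2] < min(sp$cols) || nb[2] > max(sp$cols)) next
      if (!mask[nb[1], nb[2]]) next  # pre-iteration visible only
      X <- field@features[nb[1] + (nb[2] - 1) * d[1], , drop = FALSE]
      ps <- c(ps, predictDirection(fx$ens, k, X))
    }
    expect_equal(it@prob[rr, cc], mean(ps), tolerance = 1e-12)
  }
})

test_that("filled zones carry the closest-confidence reference tile", {
  fx <- scoutFixtures()
  field <- computeTileFeatures(fx$data$test[[1]])
  part <- partitionField(rbind(c(8, 8)), c(16, 16))
  win <- extractWindow(field, part, c(8, 8), 5L)
  out <- fillWindow(win, fx$ens, fx$ref)
  filled <- which(!win@observed & !is.na(out@refIdx))
  expect_gt(length(filled), 0)
  for (i in filled) {
    ri <- out@refIdx[i]
    expect_true(all(abs(fx$ref@conf[ri] - out@prob[i]) <=
                      abs(fx$ref@conf - out@prob[i])))
    expect_equal(out@features[i, ], unname(fx$ref@features[ri, ]),
                 ignore_attr = TRUE)
  }
})

test_that("fill errors without a visible zone or a reference set", {
  win <- .stubWindow(5, 5, rbind(c(3, 3)), c(3, 3), 5L)
  expect_error(fillWindow(win, constantEnsemble(0.9), NULL), "reference")
  full <- fillWindow(win, constantEnsemble(0.9), ReferenceSet(0.9))
  expect_error(fillIteration(full, constantEnsemble(0.9), ReferenceSet(0.9)),
               "fully determined")
})
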