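## Whole-field RL decision engine: random-path dataset construction, state
## encoding, KNN retrieval (k = 11), and the action rule that flies toward
## the largest disagreement between the KNN estimate and the directional
## ensemble (with the mean-utility-gain rule as an alternative mode).

.flightDirs <- function(adjacency = 8L) {
  if (adjacency == 8L) seq_len(8L)
  else if (adjacency == 4L) which(.DIRECTIONS %in% c("N", "E", "S", "W"))
  else stop("flight adjacency must be 4 or 8")
}

## nearest unvisited zone by Chebyshev distance; ties in row-major order
.nearestUnvisited <- function(visited, pos) {
  idx <- which(!visited)
  if (length(idx) == 0L) return(NULL)
  nr <- nrow(visited)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  d <- .chebyshev(r, c, pos[1L], pos[2L])
  tie <- d == min(d)
  r <- r[tie]; c <- c[tie]
  o <- order(r, c)[1L]
  c(r[o], c[o])
}

#' Simulate a random scouting path
#'
#' Starts at a uniformly random zone on the field border; each subsequent
#' step moves to a uniformly random unvisited flight-neighbour. When no
#' unvisited neighbour exists, the UAS relocates to the nearest unsampled
#' zone (minimum Chebyshev distance, ties broken in row-major order). The
#' walk stops once \code{ceiling(coverage * zones)} zones are visited.
#' Uses the current RNG stream; wrap in \code{\link{withSeed}} for
#' reproducible paths.
#'
#' @param gridDim Grid dimensions \code{c(rows, cols)}.
#' @param coverage Target coverage fraction in (0, 1].
#' @param adjacency Flight adjacency, 8 (default) or 4.
#' @param start Optional fixed start \code{c(row, col)} (must be on the
#'   border); random border zone if NULL.
#' @return Two-column (row, col) matrix of visited zones in flight order.
#' @export
randomPath <- function(gridDim, coverage, adjacency = 8L, start = NULL) {
  if (coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]")
  nr <- gridDim[1L]; nc <- gridDim[2L]
  target <- ceiling(coverage * nr * nc)
  if (is.null(start)) {
    border <- which(matrix(seq_len(nr) %in% c(1L, nr), nr, nc) |
                    matrix(rep(seq_len(nc) %in% c(1L, nc), each = nr), nr, nc))
    s <- border[sample.int(length(border), 1L)]
    start <- c(((s - 1L) %% nr) + 1L, ((s - 1L) %/% nr) + 1L)
  }
  dirs <- .flightDirs(adjacency)
  visited <- matrix(FALSE, nr, nc)
  path <- matrix(0L, target, 2L)
  pos <- as.integer(start)
  visited[pos[1L], pos[2L]] <- TRUE
  path[1L, ] <- pos
  n <- 1L
  while (n < target) {
    rr <- pos[1L] + .DIR_DROW[dirs]; cc <- pos[2L] + .DIR_DCOL[dirs]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    ok[ok] <- !visited[cbind(rr[ok], cc[ok])]
    if (any(ok)) {
      pick <- which(ok)[sample.int(sum(ok), 1L)]
      pos <- c(rr[pick], cc[pick])
    } else {
      pos <- .nearestUnvisited(visited, pos)
    }
    visited[pos[1L], pos[2L]] <- TRUE
    n <- n + 1L
    path[n, ] <- pos
  }
  colnames(path) <- c("row", "col")
  path
}

#' Encode a filled prediction window as an RL state vector
#'
#' Concatenates the flattened ground-truth layer (observed zones as 0/1,
#' everything else as the uninformative sentinel 0.5), the flattened
#' predicted probability-of-healthy layer, and the whole-field coverage
#' fraction. Clipped out-of-bounds positions encode as 0.5 in both layers,
#' so the vector length is always 2 w^2 + 1.
#'
#' @param window A fully filled \linkS4class{PredictionWindow}.
#' @return Numeric vector of length \code{2 * size^2 + 1}.
#' @export
encodeState <- function(window) {
  d <- dim(window@status)
  if (any(is.na(window@prob)))
    stop("window must be filled before encoding (run fillWindow)")
  w <- window@size
  h <- (w - 1L) %/% 2L
  truthLayer <- matrix(0.5, w, w)
  predLayer <- matrix(0.5, w, w)
  offR <- window@rowLo - (window@center[1L] - h) # >= 0 by construction
  offC <- window@colLo - (window@center[2L] - h)
  ri <- offR + seq_len(d[1L]); ci <- offC + seq_len(d[2L])
  tl <- matrix(0.5, d[1L], d[2L])
  tl[window@observed] <- as.numeric(window@labels[window@observed])
  truthLayer[ri, ci] <- tl
  predLayer[ri, ci] <- window@prob
  c(as.vector(truthLayer), as.vector(predLayer),
    window@nVisited / prod(window@gridDim))
}

## truth labels of the 8 zones around `pos` (NA out of bounds)
.nextLabels8 <- function(truth, pos) {
  d <- dim(truth)
  out <- rep(NA_real_, 8L)
  for (k in seq_len(8L)) {
    r <- pos[1L] + .DIR_DROW[k]; c <- pos[2L] + .DIR_DCOL[k]
    if (r >= 1L && c >= 1L && r <= d[1L] && c <= d[2L])
      out[k] <- as.numeric(truth[r, c])
  }
  out
}

## accuracy of a filled window against the field truth, over window zones
.windowAccuracy <- function(window, truth) {
  sp <- windowSpan(window)
  mean(window@labels == truth[sp$rows, sp$cols, drop = FALSE])
}

#' Build an RL experience dataset from random flight paths
#'
#' Simulates random scouting paths over the training fields; at every
#' transition it records the encoded state of the filled prediction window
#' before the move, the move direction, the realized utility gain (change
#' in window map accuracy against ground truth), and the realized health
#' labels of all eight surrounding zones. Gains are normalized by the
#' maximum absolute gain, mapping them to [-1, 1]. Relocation transitions
#' are recorded with the compass direction of their displacement, so the
#' dataset holds exactly one record per transition.
#'
#' @param trainFields List of labeled \linkS4class{FieldGrid}s.
#' @param coverage Coverage rate for the simulated paths (standard sweeps
#'   use 0.1 to 0.6).
#' @param windowSize Prediction window size w.
#' @param nPaths Paths simulated per field (full-scale: 1000; desk-scale
#'   defaults are far smaller).
#' @param ensemble A trained \linkS4class{DirectionalEnsemble} (or a stub).
#' @param ref A \linkS4class{ReferenceSet}.
#' @param k Neighbour count for later retrieval (default 11).
#' @param encoding "window" for whole-field RL state vectors, "local" for
#'   last-zone image features (the local-field baseline).
#' @param adjacency Flight adjacency (8 or 4).
#' @param seed RNG seed for the whole construction.
#' @return An \linkS4class{RLDataset}.
#' @export
buildRLDataset <- function(trainFields, coverage, windowSize, nPaths,
                           ensemble, ref, k = 11L, encoding = c("window",
                           "local"), adjacency = 8L, seed = 1L) {
  encoding <- match.arg(encoding)
  if (is(trainFields, "FieldGrid")) trainFields <- list(trainFields)
  if (encoding == "window" || length(trainFields[[1L]]@tiles))
    trainFields <- lapply(trainFields, function(f)
      if (length(f@tiles)) computeTileFeatures(f) else f)
  states <- list(); actions <- integer(0); gains <- numeric(0)
  nexts <- list()
  withSeed(seed, {
    for (f in trainFields) {
      d <- fieldDim(f)
      for (p in seq_len(nPaths)) {
        path <- randomPath(d, coverage, adjacency = adjacency)
        visited <- matrix(FALSE, d[1L], d[2L])
        prevState <- NULL; prevAcc <- NA_real_
        for (i in seq_len(nrow(path))) {
          pos <- path[i, ]
          visited[pos[1L], pos[2L]] <- TRUE
          part <- partitionField(visited)
          win <- extractWindow(f, part, pos, windowSize)
          fw <- fillWindow(win, ensemble, ref)
          acc <- .windowAccuracy(fw, f@truth)
          st <- if (encoding == "window") encodeState(fw)
                else localFeatures(zoneTile(f, pos))
          if (i > 1L) {
            prev <- path[i - 1L, ]
            a <- .dirIndex(sign(pos[1L] - prev[1L]),
                           sign(pos[2L] - prev[2L]))
            states[[length(states) + 1L]] <- prevState
            actions <- c(actions, a)
            gains <- c(gains, acc - prevAcc)
            nexts[[length(nexts) + 1L]] <- .nextLabels8(f@truth, prev)
          }
          prevState <- st; prevAcc <- acc
        }
      }
    }
  })
  gmax <- max(abs(gains))
  if (gmax > 0) gains <- gains / gmax
  new("RLDataset", states = do.call(rbind, states), actions = actions,
      gains = gains, nextLabels = do.call(rbind, nexts),
      windowSize = as.integer(windowSize), coverage = coverage,
      k = as.integer(k), encoding = encoding,
      stateNormSq = rowSums(do.call(rbind, states)^2))
}

#' @describeIn buildRLDataset Number of records in a dataset.
#' @param x An \code{RLDataset}.
#' @export
nRecords <- function(x) nrow(x@states)

setMethod("show", "RLDataset", function(object) {
  cat("RLDataset:", nrow(object@states), "records |", object@encoding,
      "encoding (", ncol(object@states), "dims ) | w =",
      object@windowSize, "| coverage", object@coverage, "| k =",
      object@k, "\n")
})

## indices of the k nearest records by L2 distance on encoded states
.knnIndices <- function(dataset, query, k = dataset@k) {
  d2 <- dataset@stateNormSq - 2 * as.vector(dataset@states %*% query)
  order(d2)[seq_len(k)]
}

## candidate flight directions: in-bounds, unvisited neighbours of center
.candidateDirs <- function(window, adjacency = 8L) {
  d <- dim(window@status)
  ci <- window@center[1L] - window@rowLo + 1L
  cj <- window@center[2L] - window@colLo + 1L
  gd <- window@gridDim
  out <- integer(0)
  for (a in .flightDirs(adjacency)) {
    gr <- window@center[1L] + .DIR_DROW[a]
    gc <- window@center[2L] + .DIR_DCOL[a]
    if (gr < 1L || gc < 1L || gr > gd[1L] || gc > gd[2L]) next
    li <- ci + .DIR_DROW[a]; lj <- cj + .DIR_DCOL[a]
    if (!window@observed[li, lj]) out <- c(out, a)
  }
  out
}

#' Choose the next flight action (largest KNN-vs-model discrepancy)
#'
#' Retrieves the k most similar prior states by L2 distance on the encoded
#' window state. For each candidate action, the KNN estimate of the
#' destination zone's health is the mean realized label of that direction
#' across the retrieved records; the model estimate is the directional
#' ensemble's probability for the destination. The action with the largest
#' absolute disagreement is chosen, steering the UAS toward the zones the
#' system understands least. Ties break in the fixed direction order N,
#' NE, ..., NW.
#'
#' @param window The current \emph{filled} \linkS4class{PredictionWindow}.
#' @param dataset An \linkS4class{RLDataset} with window encoding.
#' @param ensemble The \linkS4class{DirectionalEnsemble} used for the model
#'   estimate.
#' @param adjacency Flight adjacency (8 or 4).
#' @return Named integer direction index (1..8), or \code{NA} when no
#'   legal move exists (the mission layer then relocates).
#' @export
selectAction <- function(window, dataset, ensemble, adjacency = 8L) {
  if (dataset@encoding != "window")
    stop("selectAction needs a window-encoded dataset")
  if (nrow(dataset@states) < dataset@k)
    stop("dataset smaller than k")
  cands <- .candidateDirs(window, adjacency)
  if (length(cands) == 0L) return(NA_integer_)
  idx <- .knnIndices(dataset, encodeState(window))
  disc <- numeric(length(cands))
  for (j in seq_along(cands)) {
    a <- cands[j]
    dest <- window@center + c(.DIR_DROW[a], .DIR_DCOL[a])
    model <- .ensembleProbLocal(dest[1L] - window@rowLo + 1L,
                                dest[2L] - window@colLo + 1L,
                                window@observed, window@features, ensemble)
    knn <- mean(dataset@nextLabels[idx, a], na.rm = TRUE)
    disc[j] <- if (is.nan(knn)) 0 else abs(knn - model)
  }
  a <- cands[.argmaxStable(disc)]
  structure(a, names = .DIRECTIONS[a])
}

#' Choose the next flight action (highest mean utility gain)
#'
#' Alternative RL mode: among the k retrieved prior states, each candidate
#' action is scored by the mean normalized utility gain of the records that
#' took it (0 when none did), and the highest-scoring action is chosen.
#' Ties break in the fixed direction order.
#'
#' @inheritParams selectAction
#' @return Named integer direction index, or \code{NA} when no legal move
#'   exists.
#' @export
selectActionUtility <- function(window, dataset, ensemble = NULL,
                                adjacency = 8L) {
  cands <- .candidateDirs(window, adjacency)
  if (length(cands) == 0L) return(NA_integer_)
  .utilityChoice(encodeState(window), dataset, cands)
}

## shared KNN + mean-gain argmax on an arbitrary query encoding
.utilityChoice <- function(query, dataset, cands) {
  if (nrow(dataset@states) < dataset@k) stop("dataset smaller than k")
  idx <- .knnIndices(dataset, query)
  score <- vapply(cands, function(a) {
    g <- dataset@gains[idx][dataset@actions[idx] == a]
    if (length(g) == 0L) 0 else mean(g)
  }, numeric(1))
  a <- cands[.argmaxStable(score)]
  structure(a, names = .DIRECTIONS[a])
}
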