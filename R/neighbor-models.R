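## ---- predictor backends -------------------------------------------------
##
## A backend is a list with a `type` field:
##   "logistic" - standardized logistic regression on tile features
##   "const"    - constant probability (degenerate one-class training, and
##                the stub used in algorithm tests)

.fitBackend <- function(X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    ## one-class training: Laplace-smoothed class rate, never exactly 0/1
    return(list(type = "const",
                p = (sum(y) + 1) / (length(y) + 2)))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Xs), y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  list(type = "logistic", beta = beta, center = ctr, scale = scl)
}

.predictBackend <- function(backend, X) {
  if (backend$type == "const") return(rep(backend$p, nrow(X)))
  Xs <- sweep(sweep(X, 2L, backend$center), 2L, backend$scale, "/")
  as.vector(stats::plogis(cbind(1, Xs) %*% backend$beta))
}

#' A constant-probability directional ensemble (stub backend)
#'
#' All eight directions predict the same fixed probability-of-healthy,
#' regardless of input. Useful for exercising the fill and policy machinery
#' independently of any trained model.
#'
#' @param p Probability of healthy returned everywhere.
#' @return A \linkS4class{DirectionalEnsemble}.
#' @export
constantEnsemble <- function(p = 0.9) {
  new("DirectionalEnsemble",
      backends = rep(list(list(type = "const", p = p)), 8L),
      featureNames = character(0))
}

## ---- training -----------------------------------------------------------

#' Train the eight directional spatial predictors
#'
#' For each compass direction d, training pairs are (features of the tile
#' at position center + d, truth label at center), over all interior
#' centers of all training fields. Predictor d thus learns to infer an
#' unobserved zone's health from the appearance of its neighbour lying at
#' offset d, exploiting the spatial correlation of crop stress.
#'
#' @param trainFields List of \linkS4class{FieldGrid}s with truth labels
#'   and tiles.
#' @return A \linkS4class{DirectionalEnsemble}.
#' @export
trainDirectional <- function(trainFields) {
  if (is(trainFields, "FieldGrid")) trainFields <- list(trainFields)
  if (length(trainFields) == 0L) stop("need at least one training field")
  for (f in trainFields)
    if (any(is.na(f@truth)))
      stop("training fields must be fully labeled")
  trainFields <- lapply(trainFields, computeTileFeatures)
  backends <- vector("list", 8L)
  for (d in seq_len(8L)) {
    Xs <- list(); ys <- list()
    for (f in trainFields) {
      dd <- fieldDim(f)
      rs <- 2L:(dd[1L] - 1L); cs <- 2L:(dd[2L] - 1L)
      ctr <- as.matrix(expand.grid(row = rs, col = cs))
      nb <- cbind(ctr[, 1L] + .DIR_DROW[d], ctr[, 2L] + .DIR_DCOL[d])
      Xs[[length(Xs) + 1L]] <-
        f@features[.zoneIndex(nb[, 1L], nb[, 2L], dd[1L]), , drop = FALSE]
      ys[[length(ys) + 1L]] <- f@truth[ctr]
    }
    backends[[d]] <- .fitBackend(do.call(rbind, Xs), unlist(ys))
  }
  new("DirectionalEnsemble", backends = backends,
      featureNames = .FEATURE_NAMES)
}

#' @describeIn trainDirectional Probability-of-healthy from one directional
#'   backend for a feature matrix (one tile per row). \code{direction} is
#'   an index 1..8 in canonical order or a direction name.
#' @param ensemble A \code{DirectionalEnsemble}.
#' @param direction Direction index or name.
#' @param features Feature matrix (or single feature vector).
#' @export
predictDirection <- function(ensemble, direction, features) {
  if (is.character(direction)) direction <- match(direction, .DIRECTIONS)
  if (is.null(dim(features))) features <- rbind(features)
  .predictBackend(ensemble@backends[[direction]], features)
}

setMethod("show", "DirectionalEnsemble", function(object) {
  types <- vapply(object@backends, function(b) b$type, character(1))
  cat("DirectionalEnsemble: 8 predictors (",
      paste(unique(types), collapse = "/"), ") on",
      length(object@featureNames), "tile features\n")
})

## ---- ensemble prediction ------------------------------------------------

## mean probability over the visible in-window 8-neighbours of a local
## target cell; `visMask`/`feats` are the window's current state
.ensembleProbLocal <- function(ti, tj, visMask, feats, ensemble) {
  d <- dim(visMask)
  ps <- numeric(0)
  for (k in seq_len(8L)) {
    ## observed neighbour at offset k relative to the target
    ni <- ti + .DIR_DROW[k]; nj <- tj + .DIR_DCOL[k]
    if (ni < 1L || nj < 1L || ni > d[1L] || nj > d[2L]) next
    if (!visMask[ni, nj]) next
    fr <- feats[ni + (nj - 1L) * d[1L], , drop = FALSE]
    ps <- c(ps, .predictBackend(ensemble@backends[[k]], fr))
  }
  if (length(ps) == 0L)
    stop("target has no visible neighbour in the window")
  mean(ps)
}

#' Ensemble prediction for one unobserved zone
#'
#' Averages the probability-of-healthy over all visible 8-neighbours of the
#' target, each queried through the predictor matching its direction
#' relative to the target. The label is healthy iff the mean probability is
#' at least 0.5.
#'
#' @param target Parent-grid \code{c(row, col)} of the zone to predict.
#' @param window A \linkS4class{PredictionWindow} containing the target.
#' @param ensemble A \linkS4class{DirectionalEnsemble}.
#' @return List with \code{label} (1/0), \code{confHealthy} (mean
#'   probability of healthy) and \code{confidence} (probability of the
#'   returned label, in [0.5, 1]).
#' @export
ensemblePredict <- function(target, window, ensemble) {
  ti <- target[1L] - window@rowLo + 1L
  tj <- target[2L] - window@colLo + 1L
  d <- dim(window@status)
  if (ti < 1L || tj < 1L || ti > d[1L] || tj > d[2L])
    stop("target lies outside the window")
  p <- .ensembleProbLocal(ti, tj, window@status == ZONE_VISIBLE,
                          window@features, ensemble)
  lab <- if (p >= 0.5) 1L else 0L
  list(label = lab, confHealthy = p, confidence = max(p, 1 - p))
}

## ---- reference set ------------------------------------------------------

#' Build a reference set from held-out tiles
#'
#' Scores each tile with the mean probability-of-healthy over all eight
#' directional backends applied to the tile itself (a symmetric,
#' direction-free score), and stores the tile features for later
#' substitution during window filling.
#'
#' @param tiles List of RGB tile arrays from fields not used in training.
#' @param ensemble A trained \linkS4class{DirectionalEnsemble}.
#' @param keepTiles Store the tiles themselves (needed only for image
#'   output).
#' @return A \linkS4class{ReferenceSet}.
#' @export
buildReference <- function(tiles, ensemble, keepTiles = FALSE) {
  if (length(tiles) == 0L) stop("empty reference tile list")
  feats <- do.call(rbind, lapply(tiles, tileFeatures))
  probs <- vapply(seq_len(8L),
                  function(d) .predictBackend(ensemble@backends[[d]], feats),
                  numeric(nrow(feats)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  conf <- rowMeans(probs)
  conf[conf < 0] <- 0; conf[conf > 1] <- 1
  new("ReferenceSet", conf = conf, features = feats,
      tiles = if (keepTiles) tiles else list())
}

#' Construct a reference set directly from scores
#'
#' Low-level constructor for tests and precomputed stores.
#'
#' @param conf Numeric vector of probability-of-healthy scores.
#' @param features Feature matrix, one row per entry (defaults to a
#'   zero-column matrix for feature-free stub pipelines).
#' @param tiles Optional list of tiles.
#' @return A \linkS4class{ReferenceSet}.
#' @export
ReferenceSet <- function(conf, features = NULL, tiles = list()) {
  if (is.null(features))
    features <- matrix(numeric(0), length(conf), 0L)
  new("ReferenceSet", conf = conf, features = features, tiles = tiles)
}

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet:", length(object@conf), "entries | confidence range [",
      round(min(object@conf), 3), ",", round(max(object@conf), 3), "]\n")
})

#' Nearest reference entry by prediction confidence
#'
#' Returns the index of the entry whose stored confidence is closest to the
#' query; ties break to the lowest index (stable).
#'
#' @param ref A \linkS4class{ReferenceSet}.
#' @param confidence Query probability-of-healthy.
#' @return Integer index into the reference set.
#' @examples
#' r <- ReferenceSet(c(0.6, 0.9))
#' nearestReference(r, 0.70)  # 1
#' nearestReference(r, 0.75)  # tie: first entry
#' @export
nearestReference <- function(ref, confidence) {
  which.min(abs(ref@conf - confidence))
}
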