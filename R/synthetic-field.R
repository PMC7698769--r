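#' Construct a synthetic field specification
#'
#' Defaults emulate the corn dataset the method was developed on: a 32 x 42
#' grid of 4.3 m2 zones with spatially clustered unhealthy regions and zone
#' textures whose ExG separates the classes imperfectly, so that
#' single-tile classification lands near 90\% accuracy rather than being
#' trivially solvable.
#'
#' @param rows,cols Grid dimensions.
#' @param unhealthyFraction Target unhealthy fraction (default 0.3).
#' @param clusterScale Gaussian correlation length in zones (default 4).
#' @param tilePx Tile side in pixels (default 32; texture statistics, not
#'   resolution, carry the signal).
#' @param healthyVigor,unhealthyVigor Mean vigor of the two classes.
#' @param vigorSd Between-tile vigor sd (default 0.234, which places the
#'   optimal single-tile ExG classifier near 90\% accuracy).
#' @param pixelNoiseSd Per-pixel channel noise sd.
#' @param zoneArea Zone area in square metres.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return A \linkS4class{SyntheticFieldSpec}.
#' @export
syntheticFieldSpec <- function(rows = 32L, cols = 42L,
                               unhealthyFraction = 0.3, clusterScale = 4,
                               tilePx = 32L, healthyVigor = 0.8,
                               unhealthyVigor = 0.2, vigorSd = 0.234,
                               pixelNoiseSd = 0.05, zoneArea = 4.3,
                               seed = 1L) {
  new("SyntheticFieldSpec", rows = as.integer(rows), cols = as.integer(cols),
      unhealthyFraction = unhealthyFraction, clusterScale = clusterScale,
      tilePx = as.integer(tilePx), healthyVigor = healthyVigor,
      unhealthyVigor = unhealthyVigor, vigorSd = vigorSd,
      pixelNoiseSd = pixelNoiseSd, zoneArea = zoneArea,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticFieldSpec", function(object) {
  cat("SyntheticFieldSpec:", object@rows, "x", object@cols, "zones |",
      "unhealthy", object@unhealthyFraction, "| clusterScale",
      object@clusterScale, "| tile", object@tilePx, "px | seed",
      object@seed, "\n")
})

## separable Gaussian smoothing with reflection padding (radius may
## exceed the grid side on small grids; indices fold back and forth)
.smooth2d <- function(m, sigma) {
  rad <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  reflect <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    p <- (i - 1L) %% (2L * n - 2L)
    ifelse(p < n, p + 1L, 2L * n - p - 1L)
  }
  smooth1 <- function(v) {
    n <- length(v)
    pad <- v[reflect(seq.int(1L - rad, n + rad), n)]
    stats::convolve(pad, rev(k), type = "filter")
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

## truth map inside an already-seeded RNG context
.truthMapImpl <- function(spec) {
  n <- spec@rows * spec@cols
  z <- matrix(stats::rnorm(n), spec@rows, spec@cols)
  sm <- .smooth2d(z, spec@clusterScale)
  k <- round(spec@unhealthyFraction * n)
  truth <- matrix(1L, spec@rows, spec@cols)
  if (k > 0L) truth[order(sm)[seq_len(k)]] <- 0L
  truth
}

#' Generate a clustered ground-truth health map
#'
#' Samples iid Gaussian noise per zone, smooths it with a Gaussian kernel
#' of width \code{clusterScale}, and marks the lowest
#' \code{unhealthyFraction} quantile of zones unhealthy. The realized
#' unhealthy count equals \code{round(fraction * zones)} exactly, and like
#' labels cluster spatially (first law of geography).
#'
#' @param spec A \linkS4class{SyntheticFieldSpec}.
#' @return Integer label matrix (1 healthy, 0 unhealthy).
#' @export
generateTruthMap <- function(spec) {
  withSeed(spec@seed, .truthMapImpl(spec))
}

## base colours: green-dominant canopy vs soil tone
.HEALTHY_RGB <- c(0.25, 0.55, 0.20)
.UNHEALTHY_RGB <- c(0.45, 0.42, 0.33)

## one tile inside an already-seeded RNG context
.renderTileImpl <- function(spec, label) {
  mu <- if (label == 1L) spec@healthyVigor else spec@unhealthyVigor
  v <- min(1, max(0, stats::rnorm(1L, mu, spec@vigorSd)))
  base <- v * .HEALTHY_RGB + (1 - v) * .UNHEALTHY_RGB
  px <- spec@tilePx
  tile <- array(rep(base, each = px * px), c(px, px, 3L))
  if (spec@pixelNoiseSd > 0)
    tile <- tile + stats::rnorm(length(tile), 0, spec@pixelNoiseSd)
  tile[tile < 0] <- 0; tile[tile > 1] <- 1
  tile
}

#' Render one zone tile for a health label
#'
#' Healthy tiles are green-dominant (high ExG), unhealthy tiles soil-toned
#' (low ExG); a per-tile vigor draw plus per-pixel noise makes the two ExG
#' distributions overlap. Uses the current RNG stream: seed the caller (or
#' use \code{\link{withSeed}}) for reproducible tiles.
#'
#' @param spec A \linkS4class{SyntheticFieldSpec}.
#' @param label Health label (1 healthy, 0 unhealthy).
#' @return RGB array \code{tilePx x tilePx x 3} in [0, 1].
#' @export
renderZoneTile <- function(spec, label) .renderTileImpl(spec, label)

#' Generate a complete synthetic field
#'
#' Truth map plus one rendered tile per zone, all as a pure function of the
#' spec (same spec, same bits).
#'
#' @param spec A \linkS4class{SyntheticFieldSpec}.
#' @param tiles If FALSE, generate the truth map only (fast; sufficient for
#'   policies driven by stub predictors).
#' @return A \linkS4class{FieldGrid}.
#' @export
generateField <- function(spec, tiles = TRUE) {
  withSeed(spec@seed, {
    truth <- .truthMapImpl(spec)
    tl <- list()
    if (tiles)
      tl <- lapply(seq_along(truth),
                   function(i) .renderTileImpl(spec, truth[[i]]))
    FieldGrid(truth = truth, tiles = tl, zoneArea = spec@zoneArea)
  })
}

#' Generate train/test/reference splits of synthetic fields
#'
#' Mirrors the aerial-image dataset split the pipeline expects: training
#' fields for fitting the directional predictors, test fields for flying
#' missions, and reference tiles drawn from additional fields that are in
#' neither split (the reference set must be disjoint from training data).
#' Each field gets its own seed derived from \code{spec@seed}, so splits
#' are disjoint and reproducible.
#'
#' @param spec Base \linkS4class{SyntheticFieldSpec}.
#' @param nTrainFields,nTestFields Number of fields per split (full-scale
#'   call: 30 and 6).
#' @param nReferenceTiles Number of held-out reference tiles (full-scale:
#'   about 14 fields' worth).
#' @return List with elements \code{train} (list of FieldGrid), \code{test}
#'   (list of FieldGrid), \code{referenceTiles} (list of RGB arrays) and
#'   \code{referenceLabels} (their generating truth labels).
#' @export
makeScoutingDataset <- function(spec, nTrainFields = 3L, nTestFields = 1L,
                                nReferenceTiles = 400L) {
  stopifnot(nTrainFields >= 1L, nTestFields >= 1L, nReferenceTiles >= 1L)
  fieldAt <- function(offset) {
    s <- spec
    s@seed <- spec@seed + as.integer(offset)
    generateField(s)
  }
  train <- lapply(seq_len(nTrainFields), function(i) fieldAt(i))
  test <- lapply(seq_len(nTestFields), function(i) fieldAt(100000L + i))
  refTiles <- vector("list", nReferenceTiles)
  refLabels <- integer(nReferenceTiles)
  got <- 0L; fi <- 0L
  while (got < nReferenceTiles) {
    fi <- fi + 1L
    f <- fieldAt(200000L + fi)
    take <- min(nReferenceTiles - got, length(f@tiles))
    refTiles[got + seq_len(take)] <- f@tiles[seq_len(take)]
    refLabels[got + seq_len(take)] <- f@truth[seq_len(take)]
    got <- got + take
  }
  list(train = train, test = test, referenceTiles = refTiles,
       referenceLabels = refLabels)
}
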