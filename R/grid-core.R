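#' Construct a FieldGrid
#'
#' @param truth Integer matrix of health labels (1 healthy, 0 unhealthy),
#'   or NULL for an unlabeled field of dimension \code{rows x cols}.
#' @param tiles Optional list of RGB tile arrays, one per zone in
#'   column-major zone order.
#' @param rows,cols Grid dimensions, used when \code{truth} is NULL.
#'   Defaults give the canonical 32 x 42 field tile (1344 zones).
#' @param zoneArea Zone area in square metres.
#' @return A \linkS4class{FieldGrid}.
#' @examples
#' fg <- FieldGrid(matrix(1L, 5, 5))
#' fieldDim(fg)
#' @export
FieldGrid <- function(truth = NULL, tiles = list(), rows = 32L, cols = 42L,
                      zoneArea = 4.3) {
  if (is.null(truth)) {
    truth <- matrix(NA_integer_, rows, cols)
  } else {
    storage.mode(truth) <- "integer"
  }
  new("FieldGrid", truth = truth, tiles = tiles,
      features = matrix(numeric(0), 0L, 0L), zoneArea = zoneArea)
}

#' @describeIn FieldGrid Grid dimensions \code{c(rows, cols)}.
#' @param x,object A \code{FieldGrid}.
#' @export
fieldDim <- function(x) dim(x@truth)

#' @describeIn FieldGrid Ground-truth label matrix.
#' @export
truthMap <- function(x) x@truth

#' @describeIn FieldGrid Number of management zones.
#' @export
nZones <- function(x) length(x@truth)

#' @describeIn FieldGrid Zone area in square metres.
#' @export
zoneArea <- function(x) x@zoneArea

#' @describeIn FieldGrid RGB tile of one zone.
#' @param coord Zone coordinate \code{c(row, col)}.
#' @export
zoneTile <- function(x, coord) {
  d <- fieldDim(x)
  x@tiles[[coord[1L] + (coord[2L] - 1L) * d[1L]]]
}

setMethod("show", "FieldGrid", function(object) {
  d <- fieldDim(object)
  nlab <- sum(!is.na(object@truth))
  cat("FieldGrid:", d[1L], "x", d[2L], "zones (", length(object@truth),
      "total ),", object@zoneArea, "m2 each\n")
  cat("  labels:", nlab, "| tiles:", length(object@tiles),
      "| feature cache:", nrow(object@features), "rows\n")
  if (nlab > 0L)
    cat("  unhealthy fraction:",
        round(mean(object@truth == 0L, na.rm = TRUE), 3), "\n")
})

#' Partition a grid into visible, neighbour and unknown areas
#'
#' The zones visited by the UAS form the visible (observed) area; the
#' unobserved zones 8-adjacent to it form the neighbour area, which the
#' directional predictors can reach directly; everything else is unknown.
#'
#' @param visited Either a logical matrix of visited zones or a two-column
#'   (row, col) matrix of visited coordinates.
#' @param gridDim Grid dimensions \code{c(rows, cols)} (required when
#'   \code{visited} is a coordinate matrix).
#' @return An \linkS4class{AreaPartition}.
#' @examples
#' p <- partitionField(rbind(c(3, 3)), c(5, 5))
#' table(statusMap(p))
#' @export
partitionField <- function(visited, gridDim = NULL) {
  if (is.logical(visited)) {
    mask <- visited
  } else {
    visited <- rbind(visited)
    if (is.null(gridDim)) stop("gridDim required for coordinate input")
    if (nrow(visited) == 0L)
      stop("cannot partition with no visited zone: nothing to extrapolate from")
    if (any(visited[, 1L] < 1L) || any(visited[, 2L] < 1L) ||
        any(visited[, 1L] > gridDim[1L]) || any(visited[, 2L] > gridDim[2L]))
      stop("visited coordinates out of bounds")
    mask <- matrix(FALSE, gridDim[1L], gridDim[2L])
    mask[visited] <- TRUE
  }
  if (!any(mask))
    stop("cannot partition with no visited zone: nothing to extrapolate from")
  status <- matrix(ZONE_UNKNOWN, nrow(mask), ncol(mask))
  status[.dilate8(mask) & !mask] <- ZONE_NEIGHBOR
  status[mask] <- ZONE_VISIBLE
  new("AreaPartition", status = status)
}

#' @describeIn partitionField Status matrix of a partition.
#' @param x An \code{AreaPartition}.
#' @export
statusMap <- function(x) x@status

setMethod("show", "AreaPartition", function(object) {
  s <- object@status
  cat("AreaPartition:", nrow(s), "x", ncol(s), "zones |",
      sum(s == ZONE_VISIBLE), "visible,",
      sum(s == ZONE_NEIGHBOR), "neighbour,",
      sum(s == ZONE_UNKNOWN), "unknown\n")
})

## features for all zones of a field (computed lazily, cached on the object)

#' Compute and cache per-zone tile features
#'
#' Extracts the summary features the predictor backends consume (mean and
#' quantiles of per-pixel ExG, channel means, texture standard deviations)
#' for every zone tile and caches them on the field object.
#'
#' @param field A \linkS4class{FieldGrid} with tiles.
#' @return The field with its \code{features} slot populated.
#' @export
computeTileFeatures <- function(field) {
  if (nrow(field@features) > 0L) return(field)
  if (length(field@tiles) == 0L)
    stop("field has no tiles to extract features from")
  feats <- do.call(rbind, lapply(field@tiles, tileFeatures))
  field@features <- feats
  field
}

.zoneIndex <- function(r, c, nr) r + (c - 1L) * nr

#' Extract a prediction window around the UAS
#'
#' Cuts the w x w sub-grid (clipped at field borders) centred on the
#' current UAS position out of the field and its area partition. Observed
#' zones carry their ground-truth label (probability 1 or 0) and their tile
#' features; all other zones are undetermined until
#' \code{\link{fillWindow}} runs.
#'
#' @param field A \linkS4class{FieldGrid}.
#' @param partition The \linkS4class{AreaPartition} of the current flight
#'   path.
#' @param center UAS position \code{c(row, col)}; must be visible.
#' @param w Odd window size (7, 11, 15, 19 or 23 in the standard sweeps).
#' @return A \linkS4class{PredictionWindow}.
#' @export
extractWindow <- function(field, partition, center, w) {
  w <- as.integer(w)
  if (w %% 2L != 1L) stop("window size must be odd, got ", w)
  d <- fieldDim(field)
  center <- as.integer(center)
  if (partition@status[center[1L], center[2L]] != ZONE_VISIBLE)
    stop("window center must be a visible (visited) zone")
  h <- (w - 1L) %/% 2L
  rlo <- max(1L, center[1L] - h); rhi <- min(d[1L], center[1L] + h)
  clo <- max(1L, center[2L] - h); chi <- min(d[2L], center[2L] + h)
  status <- partition@status[rlo:rhi, clo:chi, drop = FALSE]
  obs <- status == ZONE_VISIBLE
  labels <- matrix(NA_integer_, nrow(obs), ncol(obs))
  labels[obs] <- field@truth[rlo:rhi, clo:chi, drop = FALSE][obs]
  prob <- matrix(NA_real_, nrow(obs), ncol(obs))
  prob[obs] <- as.numeric(labels[obs])
  nfeat <- if (nrow(field@features)) ncol(field@features) else 0L
  feats <- matrix(NA_real_, length(obs), nfeat)
  if (nfeat > 0L) {
    zi <- outer(rlo:rhi, clo:chi, function(r, c) .zoneIndex(r, c, d[1L]))
    feats[which(obs), ] <- field@features[zi[obs], , drop = FALSE]
  }
  new("PredictionWindow", size = w, center = center, rowLo = rlo, colLo = clo,
      gridDim = as.integer(d), status = status, labels = labels, prob = prob,
      observed = obs, features = feats,
      refIdx = matrix(NA_integer_, nrow(obs), ncol(obs)),
      nVisited = sum(partition@status == ZONE_VISIBLE))
}

#' @describeIn extractWindow Label matrix of a window (parent-grid aligned,
#'   clipped).
#' @param x A \code{PredictionWindow}.
#' @export
windowLabels <- function(x) x@labels

#' @describeIn extractWindow Status matrix of a window.
#' @export
windowStatus <- function(x) x@status

#' @describeIn extractWindow Parent-grid coordinates covered by a window, as
#'   \code{list(rows =, cols =)}.
#' @export
windowSpan <- function(x) {
  d <- dim(x@status)
  list(rows = x@rowLo:(x@rowLo + d[1L] - 1L),
       cols = x@colLo:(x@colLo + d[2L] - 1L))
}

setMethod("show", "PredictionWindow", function(object) {
  d <- dim(object@status)
  cat("PredictionWindow: size", object@size, "( clipped to", d[1L], "x",
      d[2L], ") centred at (", object@center[1L], ",", object@center[2L],
      ")\n  visible:", sum(object@status == ZONE_VISIBLE),
      "| neighbour:", sum(object@status == ZONE_NEIGHBOR),
      "| unknown:", sum(object@status == ZONE_UNKNOWN),
      "| observed:", sum(object@observed), "\n")
})
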