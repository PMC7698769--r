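#' @import methods
NULL

#' Zone status codes
#'
#' Integer codes for the flight-path area partition: zones observed by the
#' UAS are \emph{visible}, unobserved zones 8-adjacent to a visible zone are
#' \emph{neighbour}, and all remaining zones are \emph{unknown}.
#'
#' @name zoneStatus
#' @aliases ZONE_UNKNOWN ZONE_NEIGHBOR ZONE_VISIBLE
#' @export ZONE_UNKNOWN ZONE_NEIGHBOR ZONE_VISIBLE
ZONE_UNKNOWN <- 0L

#' @rdname zoneStatus
ZONE_NEIGHBOR <- 1L

#' @rdname zoneStatus
ZONE_VISIBLE <- 2L

## Health labels are stored as integer matrices: 1 = healthy (positive),
## 0 = unhealthy (negative), NA = not yet determined.

#' FieldGrid: a gridded crop field
#'
#' The world model: a rows x cols lattice of management zones, each with an
#' optional ground-truth health label (1 = healthy, 0 = unhealthy) and an
#' optional RGB image tile. Tiles are numeric arrays \code{px x px x 3} with
#' values in [0, 1], stored column-major by zone index
#' (\code{row + (col - 1) * rows}).
#'
#' @slot truth Integer matrix (rows x cols) of health labels, possibly NA.
#' @slot tiles List of RGB tile arrays (length 0 or rows * cols).
#' @slot features Numeric matrix of cached per-zone tile features
#'   (0 rows until \code{\link{computeTileFeatures}} is called).
#' @slot zoneArea Zone area in square metres (default 4.3).
#' @export
setClass("FieldGrid", representation(
  truth = "matrix", tiles = "list", features = "matrix",
  zoneArea = "numeric"))

setValidity("FieldGrid", function(object) {
  msg <- character()
  tr <- object@truth
  if (nrow(tr) < 1L || ncol(tr) < 1L)
    msg <- c(msg, "field must have at least one zone")
  bad <- !is.na(tr) & !(tr %in% c(0L, 1L))
  if (any(bad)) msg <- c(msg, "truth labels must be 0, 1 or NA")
  nt <- length(object@tiles)
  if (nt != 0L && nt != length(tr))
    msg <- c(msg, "tiles must be absent or one per zone")
  if (length(object@zoneArea) != 1L || object@zoneArea <= 0)
    msg <- c(msg, "zoneArea must be a positive scalar")
  nf <- nrow(object@features)
  if (nf != 0L && nf != length(tr))
    msg <- c(msg, "feature cache must have one row per zone")
  if (length(msg)) msg else TRUE
})

#' AreaPartition: visible / neighbour / unknown status raster
#'
#' Derived from the set of zones visited by the UAS. The three areas are
#' disjoint and cover the grid; every neighbour zone is 8-adjacent to at
#' least one visible zone and no unknown zone is.
#'
#' @slot status Integer matrix with values \code{ZONE_UNKNOWN},
#'   \code{ZONE_NEIGHBOR}, \code{ZONE_VISIBLE}.
#' @export
setClass("AreaPartition", representation(status = "matrix"))

setValidity("AreaPartition", function(object) {
  s <- object@status
  if (!all(s %in% c(ZONE_UNKNOWN, ZONE_NEIGHBOR, ZONE_VISIBLE)))
    return("status values must be 0 (unknown), 1 (neighbour) or 2 (visible)")
  if (!any(s == ZONE_VISIBLE))
    return("partition must contain at least one visible zone")
  vis <- s == ZONE_VISIBLE
  adj <- .dilate8(vis)
  if (any((s == ZONE_NEIGHBOR) & !adj))
    return("every neighbour zone must be 8-adjacent to a visible zone")
  if (any((s == ZONE_UNKNOWN) & adj))
    return("no unknown zone may be 8-adjacent to a visible zone")
  TRUE
})

#' PredictionWindow: UAS-centred square sub-grid
#'
#' An odd-sized w x w window centred on the current UAS position, clipped at
#' field borders. It carries, per in-bounds zone, the partition status, the
#' health label (ground truth for observed zones, predictions once filled),
#' the probability-of-healthy, the tile feature vector used by the
#' directional predictors, and the index of any substituted reference tile.
#'
#' @slot size Odd window side length w.
#' @slot center Parent-grid (row, col) of the UAS position.
#' @slot rowLo,colLo Parent-grid coordinates of the window's top-left
#'   in-bounds zone.
#' @slot gridDim Parent grid dimensions \code{c(rows, cols)}.
#' @slot status Integer status matrix over the clipped window.
#' @slot labels Integer label matrix (NA until predicted).
#' @slot prob Numeric probability-of-healthy matrix (NA until predicted).
#' @slot observed Logical matrix: TRUE for zones physically visited by the
#'   UAS (these keep their ground truth through filling).
#' @slot features Numeric matrix, one row per window zone (column-major over
#'   the clipped window), NA rows until the zone is observed or filled.
#' @slot refIdx Integer matrix of substituted reference-set indices (NA for
#'   observed zones).
#' @slot nVisited Number of zones visited in the whole field (used to encode
#'   the coverage fraction into the RL state).
#' @export
setClass("PredictionWindow", representation(
  size = "integer", center = "integer", rowLo = "integer", colLo = "integer",
  gridDim = "integer", status = "matrix", labels = "matrix", prob = "matrix",
  observed = "matrix", features = "matrix", refIdx = "matrix",
  nVisited = "integer"))

setValidity("PredictionWindow", function(object) {
  msg <- character()
  w <- object@size
  if (w %% 2L != 1L) msg <- c(msg, "window size must be odd")
  d <- dim(object@status)
  if (any(d > w)) msg <- c(msg, "clipped window larger than its size")
  if (!identical(dim(object@labels), d) || !identical(dim(object@prob), d) ||
      !identical(dim(object@observed), d) || !identical(dim(object@refIdx), d))
    msg <- c(msg, "window layer dimensions disagree")
  if (nrow(object@features) != prod(d))
    msg <- c(msg, "feature matrix must have one row per window zone")
  ctr <- object@center - c(object@rowLo, object@colLo) + 1L
  if (any(ctr < 1L) || ctr[1L] > d[1L] || ctr[2L] > d[2L])
    msg <- c(msg, "center must lie inside the clipped window")
  else if (object@status[ctr[1L], ctr[2L]] != ZONE_VISIBLE)
    msg <- c(msg, "center zone must be visible")
  if (length(msg)) msg else TRUE
})

#' DirectionalEnsemble: the eight directional spatial predictors
#'
#' One predictor per compass direction d. Predictor d answers: given the
#' appearance (tile features) of an observed zone lying at offset d from an
#' unobserved target zone, what is the probability that the target is
#' healthy? Predictions from several observed neighbours of a target are
#' averaged (\code{\link{ensemblePredict}}).
#'
#' @slot backends List of 8 fitted backends, in canonical direction order.
#' @slot featureNames Names of the tile features the backends consume.
#' @export
setClass("DirectionalEnsemble", representation(
  backends = "list", featureNames = "character"))

setValidity("DirectionalEnsemble", function(object) {
  if (length(object@backends) != 8L)
    return("need exactly eight directional backends")
  TRUE
})

#' ReferenceSet: held-out tiles scored with prediction confidence
#'
#' Zone images not used in training, each scored once with a
#' probability-of-healthy by the trained ensemble. During window filling, a
#' predicted zone is backfilled with the reference tile of closest
#' confidence so it can serve as pseudo-observed input for further
#' predictions.
#'
#' @slot conf Numeric vector of probability-of-healthy scores in [0, 1].
#' @slot features Numeric matrix of tile features, one row per entry.
#' @slot tiles Optional list of the RGB tiles themselves.
#' @export
setClass("ReferenceSet", representation(
  conf = "numeric", features = "matrix", tiles = "list"))

setValidity("ReferenceSet", function(object) {
  if (length(object@conf) == 0L) return("reference set must be nonempty")
  if (any(!is.finite(object@conf)) || any(object@conf < 0) ||
      any(object@conf > 1))
    return("confidences must be finite and in [0, 1]")
  if (nrow(object@features) != length(object@conf))
    return("one feature row per reference entry required")
  TRUE
})

#' RLDataset: prior flight experience for the KNN policy
#'
#' One record per flight transition of a simulated random path: the encoded
#' window state before the move, the action taken, the realized
#' (normalized) utility gain, and the realized health labels of all eight
#' candidate destination zones.
#'
#' @slot states Numeric matrix, one encoded state per row.
#' @slot actions Integer vector of direction indices (1..8).
#' @slot gains Numeric utility gains, normalized to [-1, 1].
#' @slot nextLabels Numeric N x 8 matrix of destination-zone labels
#'   (1 healthy, 0 unhealthy, NA out of bounds), one column per direction.
#' @slot windowSize Window size w shared by all records.
#' @slot coverage Coverage rate the paths were generated at.
#' @slot k Neighbour count for retrieval (default 11).
#' @slot encoding "window" (whole-field RL) or "local" (local-field RL).
#' @slot stateNormSq Precomputed squared row norms of \code{states}.
#' @export
setClass("RLDataset", representation(
  states = "matrix", actions = "integer", gains = "numeric",
  nextLabels = "matrix", windowSize = "integer", coverage = "numeric",
  k = "integer", encoding = "character", stateNormSq = "numeric"))

setValidity("RLDataset", function(object) {
  n <- nrow(object@states)
  if (length(object@actions) != n || length(object@gains) != n ||
      nrow(object@nextLabels) != n)
    return("record fields must have one entry per state")
  if (ncol(object@nextLabels) != 8L)
    return("nextLabels must have eight columns")
  if (object@k > n)
    return("k may not exceed the number of records")
  if (any(!is.finite(object@gains)))
    return("utility gains must be finite")
  TRUE
})

#' BatteryModel: UAS battery drain and recharge policy
#'
#' Battery starts at \code{capacity} (percent), drains
#' \code{drainPerStep} percent per zone step, and recharges to
#' \code{rechargeTo} whenever it is at or below \code{rechargeThreshold}
#' after a step, incrementing the charge count.
#'
#' @slot capacity Initial battery percentage (100).
#' @slot drainPerStep Drain per zone-step in percent (5).
#' @slot rechargeThreshold Recharge trigger level in percent (30).
#' @slot rechargeTo Post-recharge level in percent (100).
#' @export
setClass("BatteryModel", representation(
  capacity = "numeric", drainPerStep = "numeric",
  rechargeThreshold = "numeric", rechargeTo = "numeric"))

setValidity("BatteryModel", function(object) {
  if (object@drainPerStep <= 0 || object@drainPerStep >= object@capacity)
    return("drain per step must be in (0, capacity)")
  if (object@rechargeThreshold >= object@capacity)
    return("recharge threshold must be below capacity")
  TRUE
})

#' EconParams: cost-benefit model constants
#'
#' Corn economics for the cost-benefit assessment. Per-zone constants are
#' derived from per-acre constants by area conversion with one-decimal
#' rounding (see \code{\link{perZoneConstants}}).
#'
#' @slot revenuePerAcre Corn revenue per acre in USD (763.8).
#' @slot fertilizerPerAcre Fertilizer cost per acre in USD (130).
#' @slot zoneAreaM2 Management-zone area in square metres (4.3).
#' @slot m2PerAcre Square metres per acre (4046.86).
#' @slot wageUnskilled,wageSkilled Hourly wages in USD (10, 20).
#' @slot hoursPerCharge Flight hours obtained from one charge (0.33).
#' @export
setClass("EconParams", representation(
  revenuePerAcre = "numeric", fertilizerPerAcre = "numeric",
  zoneAreaM2 = "numeric", m2PerAcre = "numeric",
  wageUnskilled = "numeric", wageSkilled = "numeric",
  hoursPerCharge = "numeric"))

setValidity("EconParams", function(object) {
  vals <- c(object@revenuePerAcre, object@fertilizerPerAcre,
            object@zoneAreaM2, object@m2PerAcre, object@wageUnskilled,
            object@wageSkilled, object@hoursPerCharge)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all economic constants must be positive and finite")
  TRUE
})

#' MissionResult: outcome of one scouting mission
#'
#' @slot policy Scouting policy name.
#' @slot path Two-column (row, col) matrix of visited zones, in flight
#'   order (zero rows for non-scouting).
#' @slot batteryTrace Battery percentage after each flight step.
#' @slot charges Total charges used (1 initial + recharges).
#' @slot predictedMap Complete integer health map (1 healthy, 0 unhealthy).
#' @slot coverage Achieved coverage fraction.
#' @slot relocations Number of relocation flights to the nearest unsampled
#'   zone.
#' @export
setClass("MissionResult", representation(
  policy = "character", path = "matrix", batteryTrace = "numeric",
  charges = "integer", predictedMap = "matrix", coverage = "numeric",
  relocations = "integer"))

setValidity("MissionResult", function(object) {
  if (any(is.na(object@predictedMap)))
    return("predicted map must be complete")
  if (length(object@batteryTrace) &&
      (any(object@batteryTrace <= 0) || any(object@batteryTrace > 100)))
    return("battery trace values must lie in (0, 100]")
  TRUE
})

#' SyntheticFieldSpec: parameters of the synthetic corn-field generator
#'
#' All generation is a pure function of the spec (including its seed).
#' Health clusters follow the first law of geography: a smoothed Gaussian
#' noise field is thresholded at the \code{unhealthyFraction} quantile, so
#' unhealthy zones form spatially coherent patches of correlation length
#' \code{clusterScale}. Tiles are rendered from a per-zone "vigor" draw that
#' interpolates between a green healthy base colour and a soil-toned
#' unhealthy base colour; \code{vigorSd} controls how much the two ExG
#' distributions overlap (calibrated so a single-tile ExG classifier lands
#' near 90\% accuracy, the regime the directional predictors operate in).
#'
#' @slot rows,cols Grid dimensions (default 32 x 42).
#' @slot unhealthyFraction Target fraction of unhealthy zones.
#' @slot clusterScale Gaussian smoothing sigma, in zones.
#' @slot tilePx Tile side length in pixels.
#' @slot healthyVigor,unhealthyVigor Mean vigor of the two classes.
#' @slot vigorSd Between-tile vigor standard deviation.
#' @slot pixelNoiseSd Per-pixel channel noise standard deviation.
#' @slot zoneArea Zone area in square metres.
#' @slot seed RNG seed; same spec implies bit-identical output.
#' @export
setClass("SyntheticFieldSpec", representation(
  rows = "integer", cols = "integer", unhealthyFraction = "numeric",
  clusterScale = "numeric", tilePx = "integer", healthyVigor = "numeric",
  unhealthyVigor = "numeric", vigorSd = "numeric", pixelNoiseSd = "numeric",
  zoneArea = "numeric", seed = "integer"))

setValidity("SyntheticFieldSpec", function(object) {
  if (object@unhealthyFraction < 0 || object@unhealthyFraction > 1)
    return("unhealthyFraction must lie in [0, 1]")
  if (object@clusterScale < 1) return("clusterScale must be >= 1")
  if (object@rows < 3L || object@cols < 3L)
    return("grid must be at least 3 x 3")
  TRUE
})
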