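#' Construct a battery model
#'
#' Defaults reproduce the empirical battery traces of the reference
#' missions: 5\% drain per zone-step, recharge to 100\% triggered whenever
#' the battery is at or below 30\% after a step.
#'
#' @param capacity Initial battery percentage.
#' @param drainPerStep Percent drained per zone-step.
#' @param rechargeThreshold Percent at or below which the UAS lands and
#'   recharges before the next step.
#' @param rechargeTo Post-recharge percentage.
#' @return A \linkS4class{BatteryModel}.
#' @export
batteryModel <- function(capacity = 100, drainPerStep = 5,
                         rechargeThreshold = 30, rechargeTo = 100) {
  new("BatteryModel", capacity = capacity, drainPerStep = drainPerStep,
      rechargeThreshold = rechargeThreshold, rechargeTo = rechargeTo)
}

## simulate battery over steps with possibly multi-drain steps
## (relocation flights drain one step per zone of Chebyshev distance)
.simulateBattery <- function(subSteps, battery) {
  n <- length(subSteps)
  trace <- numeric(n)
  level <- battery@capacity
  charges <- 1L
  for (i in seq_len(n)) {
    for (s in seq_len(subSteps[i])) {
      if (level <= battery@rechargeThreshold) {
        level <- battery@rechargeTo
        charges <- charges + 1L
      }
      level <- level - battery@drainPerStep
    }
    trace[i] <- level
  }
  list(trace = trace, charges = charges)
}

#' Battery trace over a number of flight steps
#'
#' @param nSteps Number of zone-steps flown.
#' @param battery A \linkS4class{BatteryModel}.
#' @return List with \code{trace} (battery percentage after each step) and
#'   \code{charges} (1 initial charge + recharges).
#' @examples
#' tr <- batteryTrace(25)
#' tr$trace[c(13, 17, 21, 25)]  # 35 85 65 45
#' @export
batteryTrace <- function(nSteps, battery = batteryModel()) {
  if (nSteps < 0L) stop("nSteps must be non-negative")
  .simulateBattery(rep(1L, nSteps), battery)
}

## serpentine (boustrophedon) visit order over all zones
.boustrophedon <- function(gridDim) {
  nr <- gridDim[1L]; nc <- gridDim[2L]
  rows <- rep(seq_len(nr), each = nc)
  cols <- unlist(lapply(seq_len(nr), function(r)
    if (r %% 2L == 1L) seq_len(nc) else rev(seq_len(nc))))
  cbind(row = rows, col = cols)
}

#' Extrapolate a complete whole-field map from the visited zones
#'
#' Runs the window-fill algorithm with a window large enough to cover the
#' entire field, centred on a visited zone: the same code path as in-flight
#' filling, applied to the full-field partition after the mission.
#'
#' @param field A labeled \linkS4class{FieldGrid}.
#' @param visited Logical matrix of visited zones.
#' @param ensemble A \linkS4class{DirectionalEnsemble}.
#' @param ref A \linkS4class{ReferenceSet}.
#' @param center Optional visited \code{c(row, col)} to centre on (any
#'   visited zone gives the same coverage of the field).
#' @return Complete integer health map; visited zones carry ground truth.
#' @export
predictWholeField <- function(field, visited, ensemble, ref, center = NULL) {
  d <- fieldDim(field)
  if (is.null(center)) {
    i <- which(visited)[1L]
    center <- c(((i - 1L) %% d[1L]) + 1L, ((i - 1L) %/% d[1L]) + 1L)
  }
  w <- 2L * max(d) + 1L
  part <- partitionField(visited)
  win <- extractWindow(field, part, center, w)
  fw <- fillWindow(win, ensemble, ref)
  fw@labels
}

## per-step drain counts along a path (relocations cost their distance)
.pathSubSteps <- function(path) {
  n <- nrow(path)
  subs <- rep(1L, n)
  if (n > 1L)
    subs[2L:n] <- pmax(1L, .chebyshev(path[2L:n, 1L], path[2L:n, 2L],
                                      path[1L:(n - 1L), 1L],
                                      path[1L:(n - 1L), 2L]))
  subs
}

#' Run a scouting mission
#'
#' Executes one of the five scouting policies on a labeled field and
#' returns the flight path, battery trace, charge count and the final
#' whole-field health map.
#'
#' \describe{
#'   \item{whole_field}{RL policy on the filled prediction window
#'     (\code{\link{selectAction}}), with window-fill extrapolation for the
#'     final map.}
#'   \item{local_field}{RL policy on last-zone image features, with
#'     recursive-dilation extrapolation.}
#'   \item{random}{Random walk to the coverage target; same window-fill
#'     extrapolation as whole_field when models are supplied, dilation
#'     otherwise.}
#'   \item{exhaustive}{Visits every zone in serpentine order; the map is
#'     the ground truth (assumed 100\% accurate).}
#'   \item{non_scouting}{No flight; every zone is treated as unhealthy.}
#' }
#'
#' @param policy Policy name (see Details).
#' @param field A labeled \linkS4class{FieldGrid} (tiles required for the
#'   RL policies with trained models).
#' @param coverage Target coverage fraction (ignored by exhaustive and
#'   non_scouting).
#' @param ensemble,ref Trained \linkS4class{DirectionalEnsemble} and
#'   \linkS4class{ReferenceSet} (whole_field, random).
#' @param dataset Window-encoded \linkS4class{RLDataset} (whole_field).
#' @param localDataset Local-encoded \linkS4class{RLDataset} (local_field).
#' @param windowSize Prediction window size w (default 15, the most
#'   accurate size in the standard sweeps).
#' @param battery A \linkS4class{BatteryModel}.
#' @param adjacency Flight adjacency (8 or 4).
#' @param actionRule "discrepancy" (default: largest KNN-vs-model
#'   disagreement) or "utility" (highest mean utility gain).
#' @param seed RNG seed; missions are reproducible under seed.
#' @return A \linkS4class{MissionResult}.
#' @export
runMission <- function(policy = c("whole_field", "local_field", "random",
                                  "exhaustive", "non_scouting"),
                       field, coverage = 0.4, ensemble = NULL, ref = NULL,
                       dataset = NULL, localDataset = NULL, windowSize = 15L,
                       battery = batteryModel(), adjacency = 8L,
                       actionRule = c("discrepancy", "utility"), seed = 1L) {
  policy <- match.arg(policy)
  actionRule <- match.arg(actionRule)
  d <- fieldDim(field)
  nz <- prod(d)
  if (any(is.na(field@truth)))
    stop("mission simulation needs a fully labeled field")

  if (policy == "non_scouting") {
    return(new("MissionResult", policy = policy,
               path = matrix(integer(0), 0L, 2L), batteryTrace = numeric(0),
               charges = 1L, predictedMap = matrix(0L, d[1L], d[2L]),
               coverage = 0, relocations = 0L))
  }
  if (policy == "exhaustive") {
    path <- .boustrophedon(d)
    bt <- .simulateBattery(rep(1L, nz), battery)
    return(new("MissionResult", policy = policy, path = path,
               batteryTrace = bt$trace, charges = bt$charges,
               predictedMap = field@truth, coverage = 1,
               relocations = 0L))
  }

  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  needsModels <- policy == "whole_field"
  if (needsModels && (is.null(ensemble) || is.null(ref) || is.null(dataset)))
    stop("whole_field policy needs ensemble, ref and dataset")
  if (policy == "local_field" && is.null(localDataset))
    stop("local_field policy needs a local-encoded dataset")
  if (length(field@tiles) && (policy != "random" || !is.null(ensemble)))
    field <- computeTileFeatures(field)

  target <- ceiling(coverage * nz)
  withSeed(seed, {
    if (policy == "random") {
      path <- randomPath(d, coverage, adjacency = adjacency)
      visited <- matrix(FALSE, d[1L], d[2L])
      visited[path] <- TRUE
      reloc <- sum(.pathSubSteps(path) > 1L)
    } else {
      border <- which(matrix(seq_len(d[1L]) %in% c(1L, d[1L]), d[1L], d[2L]) |
                      matrix(rep(seq_len(d[2L]) %in% c(1L, d[2L]),
                                 each = d[1L]), d[1L], d[2L]))
      s <- border[sample.int(length(border), 1L)]
      pos <- c(((s - 1L) %% d[1L]) + 1L, ((s - 1L) %/% d[1L]) + 1L)
      visited <- matrix(FALSE, d[1L], d[2L])
      visited[pos[1L], pos[2L]] <- TRUE
      path <- matrix(0L, target, 2L)
      path[1L, ] <- pos
      reloc <- 0L
      n <- 1L
      while (n < target) {
        part <- partitionField(visited)
        win <- extractWindow(field, part, pos, windowSize)
        a <- if (policy == "whole_field") {
          fw <- fillWindow(win, ensemble, ref)
          if (actionRule == "discrepancy")
            selectAction(fw, dataset, ensemble, adjacency)
          else selectActionUtility(fw, dataset, adjacency = adjacency)
        } else {
          localSelectAction(localFeatures(zoneTile(field, pos)),
                            localDataset, .candidateDirs(win, adjacency))
        }
        if (is.na(a)) {
          pos <- .nearestUnvisited(visited, pos)
          reloc <- reloc + 1L
        } else {
          pos <- pos + c(.DIR_DROW[a], .DIR_DCOL[a])
        }
        visited[pos[1L], pos[2L]] <- TRUE
        n <- n + 1L
        path[n, ] <- pos
      }
      colnames(path) <- c("row", "col")
    }

    map <- if (policy == "local_field" ||
               (policy == "random" && (is.null(ensemble) || is.null(ref)))) {
      partial <- matrix(NA_integer_, d[1L], d[2L])
      partial[visited] <- field@truth[visited]
      dilateMap(partial)
    } else {
      predictWholeField(field, visited, ensemble, ref,
                        center = path[nrow(path), ])
    }
    bt <- .simulateBattery(.pathSubSteps(path), battery)
    new("MissionResult", policy = policy, path = path,
        batteryTrace = bt$trace, charges = bt$charges, predictedMap = map,
        coverage = nrow(path) / nz, relocations = as.integer(reloc))
  })
}

#' @describeIn runMission Final predicted health map of a mission.
#' @param x A \code{MissionResult}.
#' @export
predictedMap <- function(x) x@predictedMap

#' @describeIn runMission Flight path of a mission.
#' @export
flightPath <- function(x) x@path

#' @describeIn runMission Charges used by a mission.
#' @export
chargesUsed <- function(x) x@charges

setMethod("show", "MissionResult", function(object) {
  cat("MissionResult [", object@policy, "]:", nrow(object@path),
      "steps | coverage", round(object@coverage, 3), "| charges",
      object@charges, "| relocations", object@relocations, "\n")
  if (length(object@batteryTrace))
    cat("  final battery:", object@batteryTrace[length(object@batteryTrace)],
        "%\n")
})
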