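## Two-stage crop-health prediction: iteratively predict the neighbour
## area of the window from the visible area, substitute the
## closest-confidence reference tile for every newly predicted zone, and
## promote those zones to visible, until no undetermined zone remains.

## recompute window-local status from the current visible mask
.localStatus <- function(vis) {
  status <- matrix(ZONE_UNKNOWN, nrow(vis), ncol(vis))
  status[.dilate8(vis) & !vis] <- ZONE_NEIGHBOR
  status[vis] <- ZONE_VISIBLE
  status
}

#' One synchronous wavefront step of the fill algorithm
#'
#' Predicts every zone of the window's current neighbour area from the
#' pre-iteration visible set (so fills within an iteration cannot feed each
#' other), substitutes the closest-confidence reference tile for each, and
#' promotes them to visible.
#'
#' @param window A \linkS4class{PredictionWindow} with a nonempty neighbour
#'   area.
#' @param ensemble A \linkS4class{DirectionalEnsemble}.
#' @param ref A \linkS4class{ReferenceSet}.
#' @return The updated window, one Chebyshev ring further determined.
#' @export
fillIteration <- function(window, ensemble, ref) {
  vis <- window@status == ZONE_VISIBLE
  status <- .localStatus(vis)
  targets <- which(status == ZONE_NEIGHBOR)
  if (length(targets) == 0L) {
    if (any(!vis))
      stop("internal: unknown zones remain but no neighbour area exists")
    stop("window is already fully determined")
  }
  d <- dim(vis)
  ti <- ((targets - 1L) %% d[1L]) + 1L
  tj <- ((targets - 1L) %/% d[1L]) + 1L
  psum <- numeric(length(targets))
  pcnt <- integer(length(targets))
  for (k in seq_len(8L)) {
    ni <- ti + .DIR_DROW[k]; nj <- tj + .DIR_DCOL[k]
    ok <- ni >= 1L & nj >= 1L & ni <= d[1L] & nj <= d[2L]
    ok[ok] <- vis[cbind(ni[ok], nj[ok])]
    if (!any(ok)) next
    rows <- ni[ok] + (nj[ok] - 1L) * d[1L]
    psum[ok] <- psum[ok] +
      .predictBackend(ensemble@backends[[k]],
                      window@features[rows, , drop = FALSE])
    pcnt[ok] <- pcnt[ok] + 1L
  }
  stopifnot(all(pcnt > 0L))  # guaranteed by the local partition
  p <- psum / pcnt
  ## closest-confidence reference substitution, stable ties
  refIdx <- vapply(p, function(x) which.min(abs(ref@conf - x)), integer(1))
  window@labels[targets] <- as.integer(p >= 0.5)
  window@prob[targets] <- p
  window@refIdx[targets] <- refIdx
  if (ncol(window@features) > 0L) {
    if (ncol(ref@features) != ncol(window@features))
      stop("reference features incompatible with window features")
    window@features[targets, ] <- ref@features[refIdx, , drop = FALSE]
  }
  vis[targets] <- TRUE
  window@status <- .localStatus(vis)
  window
}

#' Fill a prediction window completely
#'
#' Runs \code{\link{fillIteration}} until every in-bounds zone of the
#' window carries a label and a confidence. Originally observed zones keep
#' their ground truth untouched; predicted zones also carry the reference
#' tile substituted for them, which is what allows the wavefront to reach
#' zones far from the flight path. Starting from a visible center, the fill
#' terminates in at most ceil((w - 1) / 2) iterations.
#'
#' @param window A \linkS4class{PredictionWindow} with at least one visible
#'   zone.
#' @param ensemble A \linkS4class{DirectionalEnsemble}.
#' @param ref A \linkS4class{ReferenceSet}.
#' @return The fully determined window (a fixed point: filling again
#'   changes nothing).
#' @export
fillWindow <- function(window, ensemble, ref) {
  if (!any(window@status == ZONE_VISIBLE))
    stop("window has no visible zone to extrapolate from")
  if (missing(ref) || is.null(ref))
    stop("a reference set is required to fill a window")
  maxIter <- sum(dim(window@status))  # generous; wavefront needs far fewer
  it <- 0L
  while (any(window@status != ZONE_VISIBLE)) {
    it <- it + 1L
    if (it > maxIter) stop("internal: fill failed to terminate")
    window <- fillIteration(window, ensemble, ref)
  }
  window
}
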