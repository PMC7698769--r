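## Local-field RL baseline: last-zone image features drive the policy, and
## the final map is completed by recursive dilation instead of model-based
## extrapolation.

#' Complete a partial health map by recursive dilation
#'
#' Synchronous passes: every unlabeled zone with at least one labeled
#' 8-neighbour receives the majority label of its labeled neighbours (ties
#' go to healthy); zones labeled in a pass participate only from the next
#' pass on. Repeats until the map is complete. This consensus rule tends to
#' reinforce solid clusters of like labels across nearby unpredicted zones,
#' which is the characteristic failure mode of the approach on patchy
#' fields.
#'
#' @param partial Integer matrix with 1 (healthy), 0 (unhealthy) and NA
#'   (unassigned) entries; at least one zone must be labeled.
#' @param tieBreak Label assigned on a tied neighbour vote: "healthy"
#'   (default) or "unhealthy".
#' @return A complete integer label matrix.
#' @examples
#' m <- matrix(NA_integer_, 1, 5); m[1] <- 1L; m[5] <- 0L
#' dilateMap(m)  # H H H U U: the center tie resolves to healthy
#' @export
dilateMap <- function(partial, tieBreak = c("healthy", "unhealthy")) {
  tieBreak <- match.arg(tieBreak)
  if (all(is.na(partial)))
    stop("cannot dilate an entirely unlabeled map")
  lab <- partial
  maxPass <- nrow(lab) + ncol(lab)
  for (pass in seq_len(maxPass)) {
    todo <- is.na(lab)
    if (!any(todo)) break
    h <- matrix(0L, nrow(lab), ncol(lab))
    u <- matrix(0L, nrow(lab), ncol(lab))
    for (k in seq_len(8L)) {
      s <- .shiftMat(lab, .DIR_DROW[k], .DIR_DCOL[k], fill = NA_integer_)
      h <- h + (!is.na(s) & s == 1L)
      u <- u + (!is.na(s) & s == 0L)
    }
    voted <- todo & (h + u) > 0L
    win <- if (tieBreak == "healthy") h >= u else h > u
    lab[voted] <- ifelse(win[voted], 1L, 0L)
  }
  if (any(is.na(lab))) stop("internal: dilation failed to complete the map")
  lab
}

#' Choose the next flight action from local image features
#'
#' The local-field policy: retrieves the k most similar prior states by L2
#' distance on the last-zone feature vector and picks the candidate action
#' with the highest mean normalized utility gain among the retrieved
#' records that took it (ties in the fixed direction order N, NE, ..., NW).
#'
#' @param features Local feature vector of the current zone
#'   (\code{\link{localFeatures}}).
#' @param dataset An \linkS4class{RLDataset} built with
#'   \code{encoding = "local"}.
#' @param candidates Integer indices of the legal flight directions
#'   (default: all eight).
#' @return Named integer direction index.
#' @export
localSelectAction <- function(features, dataset, candidates = seq_len(8L)) {
  if (dataset@encoding != "local")
    stop("localSelectAction needs a local-encoded dataset")
  if (length(candidates) == 0L) return(NA_integer_)
  .utilityChoice(as.numeric(features), dataset, candidates)
}
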