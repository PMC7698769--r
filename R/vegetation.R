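#' Excess green index (ExG) of RGB pixels
#'
#' Computes ExG on chromatic coordinates: with r' = R/(R+G+B), g' and b'
#' likewise, ExG = 2g' - r' - b'. The index is dimensionless and bounded in
#' [-1, 2]; black pixels (R+G+B = 0) return 0 by convention.
#'
#' @param r,g,b Numeric vectors of non-negative channel values (any common
#'   scale: raw 8-bit or [0, 1]).
#' @param normalize If FALSE, returns the non-normalized variant
#'   2G - R - B on the raw channel values instead (sensitivity checks).
#' @return Numeric vector of ExG values.
#' @examples
#' exgPixel(0, 255, 0)      # pure green: 2
#' exgPixel(100, 100, 100)  # achromatic: 0
#' @export
exgPixel <- function(r, g, b, normalize = TRUE) {
  if (any(r < 0) || any(g < 0) || any(b < 0))
    stop("channel values must be non-negative")
  if (!normalize) return(2 * g - r - b)
  s <- r + g + b
  out <- numeric(length(s))
  nz <- s > 0
  out[nz] <- (2 * g[nz] - r[nz] - b[nz]) / s[nz]
  out
}

#' Mean ExG of a zone tile
#'
#' @param tile RGB array \code{h x w x 3}.
#' @param normalize Passed to \code{\link{exgPixel}}.
#' @return Scalar mean ExG over all pixels.
#' @export
zoneExg <- function(tile, normalize = TRUE) {
  if (is.null(dim(tile)) || length(dim(tile)) != 3L || dim(tile)[3L] != 3L)
    stop("tile must be an h x w x 3 RGB array")
  if (length(tile) == 0L) stop("empty tile")
  mean(exgPixel(as.vector(tile[, , 1L]), as.vector(tile[, , 2L]),
                as.vector(tile[, , 3L]), normalize = normalize))
}

#' Label zones by the 80\%-of-field-mean ExG rule
#'
#' A zone is unhealthy iff its mean ExG is below 80\% of the mean ExG over
#' all zones of the field; a zone at exactly 80\% of the field mean is
#' healthy (the boundary is inclusive on the healthy side). The reference
#' mean is taken over the field tile being labeled.
#'
#' @param zoneExgValues Numeric matrix (or vector) of per-zone mean ExG.
#' @param threshold Fraction of the field mean below which a zone is
#'   unhealthy (default 0.8).
#' @return Integer labels of the same shape: 1 healthy, 0 unhealthy.
#' @examples
#' labelField(c(1, 1, 1, 0.4))  # mean 0.85, cutoff 0.68: H H H U
#' @export
labelField <- function(zoneExgValues, threshold = 0.8) {
  if (any(!is.finite(zoneExgValues))) stop("non-finite zone ExG values")
  m <- mean(zoneExgValues)
  if (m <= 0)
    stop("field mean ExG is not positive (", signif(m, 3),
         "): the relative threshold rule is undefined; supply labels directly")
  lab <- ifelse(zoneExgValues < threshold * m, 0L, 1L)
  if (is.matrix(zoneExgValues))
    lab <- matrix(as.integer(lab), nrow(zoneExgValues), ncol(zoneExgValues))
  else lab <- as.integer(lab)
  lab
}

#' Label a field's zones from its tiles
#'
#' Convenience wrapper: computes each zone's mean ExG and applies
#' \code{\link{labelField}}.
#'
#' @param field A \linkS4class{FieldGrid} with tiles.
#' @param threshold Passed to \code{labelField}.
#' @return The field with its truth labels replaced by the ExG rule's
#'   output.
#' @export
labelFieldFromTiles <- function(field, threshold = 0.8) {
  if (length(field@tiles) == 0L) stop("field has no tiles")
  d <- fieldDim(field)
  ze <- matrix(vapply(field@tiles, zoneExg, numeric(1)), d[1L], d[2L])
  field@truth <- labelField(ze, threshold = threshold)
  field
}
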