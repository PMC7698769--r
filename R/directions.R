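## Compass directions in fixed order. Row index decreases towards north so
## that printed matrices read like a map. This order is also the RL
## tie-break order.
.DIRECTIONS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
.DIR_DROW <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
.DIR_DCOL <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Compass directions used for flight moves and directional predictors
#'
#' Returns the eight compass directions in the package's canonical order
#' (N, NE, E, SE, S, SW, W, NW) together with their (row, col) offsets.
#' North decreases the row index.
#'
#' @return A data.frame with columns \code{direction}, \code{drow},
#'   \code{dcol}.
#' @examples
#' compassDirections()
#' @export
compassDirections <- function() {
  data.frame(direction = .DIRECTIONS, drow = .DIR_DROW, dcol = .DIR_DCOL,
             stringsAsFactors = FALSE)
}

## direction index for an offset (drow, dcol); NA if not a unit offset
.dirIndex <- function(drow, dcol) {
  i <- which(.DIR_DROW == drow & .DIR_DCOL == dcol)
  if (length(i) == 0L) NA_integer_ else i
}

#' In-bounds 8-neighbours of a zone
#'
#' @param coord Integer vector \code{c(row, col)} (1-based).
#' @param gridDim Integer vector \code{c(rows, cols)}.
#' @return A two-column integer matrix of neighbouring (row, col) pairs, in
#'   the canonical direction order. Interior zones have 8 neighbours, edge
#'   zones 5, corner zones 3.
#' @examples
#' neighbors8(c(1, 1), c(5, 5))   # corner: 3 neighbours
#' neighbors8(c(3, 3), c(5, 5))   # interior: 8 neighbours
#' @export
neighbors8 <- function(coord, gridDim) {
  r <- as.integer(coord[1L]); cc <- as.integer(coord[2L])
  if (r < 1L || cc < 1L || r > gridDim[1L] || cc > gridDim[2L])
    stop("coordinate (", r, ",", cc, ") out of bounds for ",
         gridDim[1L], " x ", gridDim[2L], " grid")
  rr <- r + .DIR_DROW; ccs <- cc + .DIR_DCOL
  ok <- rr >= 1L & rr <= gridDim[1L] & ccs >= 1L & ccs <= gridDim[2L]
  cbind(row = rr[ok], col = ccs[ok])
}
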