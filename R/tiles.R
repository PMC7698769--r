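## Per-tile summary features consumed by the predictor backends.
.FEATURE_NAMES <- c("meanExG", "q10ExG", "q90ExG", "sdExG",
                    "meanR", "meanG", "meanB", "sdG")

#' Summary features of a zone tile
#'
#' The feature vector the directional-predictor backends consume: mean,
#' 10th/90th percentile and standard deviation of per-pixel ExG, the three
#' channel means, and the green-channel standard deviation (texture).
#'
#' @param tile RGB array \code{h x w x 3}, values in [0, 1].
#' @return Named numeric vector of length 8.
#' @export
tileFeatures <- function(tile) {
  r <- as.vector(tile[, , 1L]); g <- as.vector(tile[, , 2L])
  b <- as.vector(tile[, , 3L])
  e <- exgPixel(r, g, b)
  q <- stats::quantile(e, c(0.1, 0.9), names = FALSE)
  out <- c(mean(e), q[1L], q[2L], stats::sd(e),
           mean(r), mean(g), mean(b), stats::sd(g))
  names(out) <- .FEATURE_NAMES
  out
}

#' Local image features used by the local-field baseline
#'
#' The last-zone image summary that local-field RL feeds to its policy:
#' mean ExG, mean HSV saturation, and the three channel means.
#'
#' @param tile RGB array \code{h x w x 3}, values in [0, 1].
#' @return Named numeric vector of length 5.
#' @examples
#' gray <- array(0.5, c(2, 2, 3))
#' localFeatures(gray)["meanSat"]  # 0: achromatic pixels have no saturation
#' @export
localFeatures <- function(tile) {
  if (is.null(dim(tile)) || length(dim(tile)) != 3L || length(tile) == 0L)
    stop("tile must be a nonempty h x w x 3 RGB array")
  r <- as.vector(tile[, , 1L]); g <- as.vector(tile[, , 2L])
  b <- as.vector(tile[, , 3L])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  out <- c(mean(exgPixel(r, g, b)), mean(sat), mean(r), mean(g), mean(b))
  names(out) <- c("meanExG", "meanSat", "meanR", "meanG", "meanB")
  out
}
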