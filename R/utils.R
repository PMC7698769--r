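#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores
#' the previous RNG state afterwards, so seeded simulator calls do not
#' disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## shift a matrix by (dr, dc), padding with `fill`
.shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  rs <- seq.int(max(1L, 1L + dr), min(nr, nr + dr))
  cs <- seq.int(max(1L, 1L + dc), min(nc, nc + dc))
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

## logical dilation by the 8-neighbourhood (zone itself excluded)
.dilate8 <- function(mask) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (d in seq_len(8L))
    out <- out | .shiftMat(mask, .DIR_DROW[d], .DIR_DCOL[d])
  out
}

.chebyshev <- function(r1, c1, r2, c2) pmax(abs(r1 - r2), abs(c1 - c2))

## first index of the maximum within tolerance (stable argmax)
.argmaxStable <- function(x, tol = 1e-12) {
  m <- max(x)
  which(x >= m - tol)[1L]
}
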