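## Helix-axis estimation and inter-axis distances.
##
## The bisector construction: for three consecutive CA positions the vector
## CA(i-1) + CA(i+1) - 2 CA(i) points exactly at the local helix axis of an
## ideal helix, and the local twist follows from the angle between adjacent
## bisectors. Exact for ideal helices, a close approximation for slowly
## supercoiled ones.

#' @describeIn helixAxis bisector-window axis estimate; end points are
#'   linearly extrapolated so one axis point is returned per residue.
#' @export
setMethod("helixAxis", "BackboneChain", function(chain) {
  P <- chain@CA
  n <- nrow(P)
  if (n < 4) stop("helix axis estimation needs at least 4 residues")
  idx <- 2:(n - 1)
  D <- P[idx - 1, , drop = FALSE] + P[idx + 1, , drop = FALSE] - 2 * P[idx, , drop = FALSE]
  dn <- sqrt(rowSums(D^2))
  if (any(dn < 1e-9)) stop("degenerate (collinear) CA trace; cannot fit a helix axis")
  B <- D / dn
  m <- nrow(B)
  cosw <- vapply(seq_len(m), function(j) {
    ks <- c(j - 1, j + 1)
    ks <- ks[ks >= 1 & ks <= m]
    mean(vapply(ks, function(k) sum(B[j, ] * B[k, ]), numeric(1)))
  }, numeric(1))
  cosw <- pmin(cosw, 1 - 1e-9)
  r <- dn / (2 * (1 - cosw))
  A <- P[idx, , drop = FALSE] + B * r
  rbind(2 * A[1, ] - A[2, ], A, 2 * A[m, ] - A[m - 1, ])
})

#' Mean closest-approach distance between two helix axes
#'
#' Fits the axis of each helix and averages, over the overlapping span, the
#' closest distance from each axis point of one helix to the axis polyline
#' of the other. Symmetric in its arguments.
#'
#' @param a,b \linkS4class{BackboneChain} objects with >= 4 residues.
#' @return distance in Angstrom.
#' @examples
#' h1 <- generateHelix(CrickParams(length = 17))
#' h2 <- transformChain(h1, t = c(10, 0, 0))
#' neighborDistance(h1, h2)
#' @export
neighborDistance <- function(a, b) {
  axA <- helixAxis(a)
  axB <- helixAxis(b)
  directed <- function(X, Y) {
    hits <- t(apply(X, 1, pointToPolyline, poly = Y))
    keep <- hits[, "interior"] > 0
    if (!any(keep)) keep <- rep(TRUE, nrow(hits))  # no overlap: use all points
    mean(hits[keep, "dist"])
  }
  (directed(axA, axB) + directed(axB, axA)) / 2
}
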