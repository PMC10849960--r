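## Small geometric helpers shared across the package. All angles at the API
## surface are degrees; conversion to radians happens here, once.

deg2rad <- function(x) x * pi / 180

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: right-handed rotation by `angle` degrees about the
#' direction `axis` (need not be unit length).
#'
#' @param axis numeric(3) rotation axis.
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  u <- unitVector(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

applyRigid <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

## Distance from points to a polyline (sequence of segments), with a flag for
## whether the nearest projection fell strictly inside a segment.
pointToPolyline <- function(p, poly) {
  best <- Inf
  interior <- FALSE
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    s <- if (L2 < 1e-12) 0 else sum((p - a) * ab) / L2
    sc <- min(max(s, 0), 1)
    d <- sqrt(sum((p - (a + sc * ab))^2))
    if (d < best) {
      best <- d
      interior <- (s > 0 && s < 1) || (k > 1 && s <= 0) || (k < nrow(poly) - 1 && s >= 1)
    }
  }
  c(dist = best, interior = as.numeric(interior))
}

## Approximately even points on the unit sphere (golden-spiral lattice).
sphereLattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## all-pairs squared distances between two coordinate matrices (n x 3, m x 3)
crossDist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * (A %*% t(B))
}

minCrossDist <- function(A, B) sqrt(max(0, min(crossDist2(A, B))))
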