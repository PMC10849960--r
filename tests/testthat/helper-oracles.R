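## Independent re-implementations used as oracles. These deliberately share
## no code with the package internals.

## Crick generating equations, coded separately for cross-checking
refCrickCA <- function(n, R0, omega0, phi0, R1, omega1, phi1, rise = 1.51,
                       zOffset = 0) {
  t <- 0:(n - 1)
  w0 <- omega0 * pi / 180; w1 <- omega1 * pi / 180
  p0 <- phi0 * pi / 180; p1 <- phi1 * pi / 180
  a1 <- w1 * t + p1
  if (abs(w0) < 1e-12 || R0 < 1e-12) {
    x <- R0 * cos(p0) + R1 * cos(a1 + p0)
    y <- R0 * sin(p0) + R1 * sin(a1 + p0)
    z <- rise * t
  } else {
    al <- asin(R0 * w0 / rise)
    a0 <- w0 * t + p0
    x <- R0 * cos(a0) + R1 * cos(a0) * cos(a1) - R1 * cos(al) * sin(a0) * sin(a1)
    y <- R0 * sin(a0) + R1 * sin(a0) * cos(a1) + R1 * cos(al) * cos(a0) * sin(a1)
    z <- w0 * t * R0 / tan(al) - R1 * sin(al) * sin(a1)
  }
  cbind(x, y, z + zOffset)
}

## brute-force minimum distance between two dense polylines
refPolylineMinDist <- function(A, B, k = 25) {
  densify <- function(P) {
    out <- NULL
    for (i in seq_len(nrow(P) - 1)) {
      w <- seq(0, 1, length.out = k)
      out <- rbind(out, outer(1 - w, P[i, ]) + outer(w, P[i + 1, ]))
    }
    out
  }
  A2 <- densify(A); B2 <- densify(B)
  sqrt(min(outer(rowSums(A2^2), rowSums(B2^2), "+") - 2 * A2 %*% t(B2)))
}

## brute-force radius of gyration, straight from the definition
refRg <- function(X) {
  ctr <- c(mean(X[, 1]), mean(X[, 2]), mean(X[, 3]))
  s <- 0
  for (i in seq_len(nrow(X))) s <- s + sum((X[i, ] - ctr)^2)
  sqrt(s / nrow(X))
}

## helper: a peptide of n repeats of one letter
polySeq <- function(letter, n) paste(rep(letter, n), collapse = "")
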