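## Crick-parameterized backbone generation.
##
## CA positions come straight from the generating equations; N, C and O are
## placed by expressing the atoms of an ideal alpha-helix in the local frame
## of each CA triplet and replaying those offsets on the generated trace.

crickCA <- function(params) {
  t <- seq_len(params@length) - 1
  w0 <- deg2rad(params@omega0); w1 <- deg2rad(params@omega1)
  p0 <- deg2rad(params@phi0); p1 <- deg2rad(params@phi1)
  R0 <- params@R0; R1 <- params@R1; d <- params@rise
  ph1 <- w1 * t + p1
  if (abs(w0) < 1e-12 || R0 < 1e-12) {
    ph0 <- rep(p0, length(t))
    z <- d * t
  } else {
    ph0 <- w0 * t + p0
    alpha <- asin(R0 * w0 / d)
    z <- (w0 * t * R0) / tan(alpha) - R1 * sin(alpha) * sin(ph1)
  }
  ca <- if (abs(w0) < 1e-12 || R0 < 1e-12) {
    cbind(R0 * cos(ph0) + R1 * (cos(ph0) * cos(ph1) - sin(ph0) * sin(ph1)),
          R0 * sin(ph0) + R1 * (sin(ph0) * cos(ph1) + cos(ph0) * sin(ph1)),
          z)
  } else {
    alpha <- asin(R0 * w0 / d)
    cbind(R0 * cos(ph0) + R1 * cos(ph0) * cos(ph1) - R1 * cos(alpha) * sin(ph0) * sin(ph1),
          R0 * sin(ph0) + R1 * sin(ph0) * cos(ph1) + R1 * cos(alpha) * cos(ph0) * sin(ph1),
          z)
  }
  ## sense -1: the same spatial helix traversed C-to-N (residues run down
  ## the axis), keeping every helix on the same superhelical winding
  if (params@sense < 0) ca <- ca[rev(seq_len(nrow(ca))), , drop = FALSE]
  ca[, 3] <- ca[, 3] + params@zOffset
  unname(ca)
}

## ---- ideal-template backbone completion --------------------------------

## NeRF placement of atom D given A-B-C and internal coordinates.
placeAtom <- function(A, B, C, bond, angle, dihedral) {
  th <- deg2rad(angle); chi <- deg2rad(dihedral)
  bc <- unitVector(C - B)
  n <- unitVector(crossProduct(B - A, bc))
  m <- crossProduct(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Ideal alpha-helix backbone (phi = -57.8, psi = -47.0, omega = 180).
idealHelixBackbone <- function(n) {
  stopifnot(n >= 2)
  phi <- -57.8; psi <- -47.0; omg <- 180
  N <- matrix(0, 3 * n, 3)  # interleaved N, CA, C
  N[1, ] <- c(0, 0, 0)
  N[2, ] <- c(1.458, 0, 0)
  N[3, ] <- N[2, ] + 1.525 * c(cos(deg2rad(180 - 111.2)), sin(deg2rad(180 - 111.2)), 0)
  k <- 3
  for (i in 2:n) {
    N[k + 1, ] <- placeAtom(N[k - 2, ], N[k - 1, ], N[k, ], 1.329, 116.2, psi)
    N[k + 2, ] <- placeAtom(N[k - 1, ], N[k, ], N[k + 1, ], 1.458, 121.7, omg)
    N[k + 3, ] <- placeAtom(N[k, ], N[k + 1, ], N[k + 2, ], 1.525, 111.2, phi)
    k <- k + 3
  }
  idx <- function(j) 3 * (seq_len(n) - 1) + j
  Nn <- N[idx(1), , drop = FALSE]
  CA <- N[idx(2), , drop = FALSE]
  Cc <- N[idx(3), , drop = FALSE]
  ## carbonyl O in the peptide plane: build from CA(i), C(i), N(i+1)
  O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n - 1))
    O[i, ] <- placeAtom(Nn[i + 1, ], CA[i, ], Cc[i, ], 1.231, 120.5, 180)
  ## terminal O: copy the local offset of the previous residue's O
  O[n, ] <- Cc[n, ] + (O[n - 1, ] - Cc[n - 1, ])
  list(N = Nn, CA = CA, C = Cc, O = O)
}

## Orthonormal frame of the junction between residues j and j+1. Interior
## junctions (j >= 2) use the triplet (j-1, j, j+1) with x along the
## outgoing CA step; the first junction uses (1, 2, 3) with x along its own
## step. The same recipe is applied to the ideal template when the local
## atom offsets are derived, so helical traces reproduce the ideal backbone
## exactly while non-helical (loop) traces still get valid bond geometry.
junctionFrame <- function(ca, j) {
  n <- nrow(ca)
  if (j == 1) {
    v1 <- ca[2, ] - ca[1, ]; v2 <- ca[3, ] - ca[2, ]
    u <- unitVector(v1)
  } else {
    v1 <- ca[j, ] - ca[j - 1, ]; v2 <- ca[j + 1, ] - ca[j, ]
    u <- unitVector(v2)
  }
  nr <- crossProduct(v1, v2)
  if (sqrt(sum(nr^2)) < 1e-8) {  # collinear: any perpendicular will do
    nr <- crossProduct(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  }
  nh <- unitVector(nr)
  nh <- unitVector(nh - sum(nh * u) * u)
  cbind(u, crossProduct(nh, u), nh)
}

## template-derived local offsets (computed once)
peptideOffsets <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tpl <- idealHelixBackbone(9)
    d0 <- sqrt(sum((tpl$CA[5, ] - tpl$CA[4, ])^2))
    inF <- function(F, v) drop(t(F) %*% v)
    Fi <- junctionFrame(tpl$CA, 4)
    F1 <- junctionFrame(tpl$CA, 1)
    cache <<- list(
      d0 = d0,
      ## interior junction (j, j+1): C_j, O_j, N_{j+1}; last junction also
      ## places C_{j+1}, O_{j+1}
      C_self = inF(Fi, tpl$C[4, ] - tpl$CA[4, ]),
      O_self = inF(Fi, tpl$O[4, ] - tpl$C[4, ]),
      N_next = inF(Fi, tpl$N[5, ] - tpl$CA[5, ]),
      C_end = inF(Fi, tpl$C[5, ] - tpl$CA[5, ]),
      O_end = inF(Fi, tpl$O[5, ] - tpl$C[5, ]),
      ## first junction: N_1, C_1, O_1, N_2
      N_first = inF(F1, tpl$N[1, ] - tpl$CA[1, ]),
      C_first = inF(F1, tpl$C[1, ] - tpl$CA[1, ]),
      O_first = inF(F1, tpl$O[1, ] - tpl$C[1, ]),
      N_second = inF(F1, tpl$N[2, ] - tpl$CA[2, ]))
    cache
  }
})

#' Complete N, C, O backbone atoms from a CA trace
#'
#' Places the remaining heavy backbone atoms by replaying ideal alpha-helix
#' peptide-plane offsets in the local frame of each CA-CA junction; the
#' along-chain offset components scale with the local CA step so bond
#' lengths stay valid for mildly non-ideal (loop) geometry.
#'
#' @param ca numeric (n x 3) CA coordinate matrix, n >= 3.
#' @return list with N, C, O matrices (n x 3).
#' @export
completeBackbone <- function(ca) {
  n <- nrow(ca)
  if (n < 3) stop("backbone completion needs at least 3 residues")
  off <- peptideOffsets()
  N <- C <- O <- matrix(NA_real_, n, 3)
  place <- function(F, origin, o, scale = 1)
    origin + drop(F %*% c(o[1] * scale, o[2], o[3]))
  for (j in seq_len(n - 1)) {
    F <- junctionFrame(ca, j)
    sc <- sqrt(sum((ca[j + 1, ] - ca[j, ])^2)) / off$d0
    if (j == 1) {
      N[1, ] <- place(F, ca[1, ], off$N_first, sc)
      C[1, ] <- place(F, ca[1, ], off$C_first, sc)
      O[1, ] <- place(F, C[1, ], off$O_first)
      N[2, ] <- place(F, ca[2, ], off$N_second, sc)
    } else {
      C[j, ] <- place(F, ca[j, ], off$C_self, sc)
      O[j, ] <- place(F, C[j, ], off$O_self)
      N[j + 1, ] <- place(F, ca[j + 1, ], off$N_next, sc)
    }
    if (j == n - 1) {
      C[n, ] <- place(F, ca[n, ], off$C_end, sc)
      O[n, ] <- place(F, C[n, ], off$O_end)
    }
  }
  list(N = N, C = C, O = O)
}

#' Generate a helix backbone from Crick parameters
#'
#' Evaluates the Crick generating equations to obtain the CA trace (a
#' superhelical circle of radius R0 traversed at omega0 per residue carrying
#' a minor helix of radius R1 at omega1 per residue; axial rise fixed by the
#' per-residue rise along the minor-helix axis), then completes N, C, O by
#' ideal-template placement. \code{zOffset} is added to all z coordinates;
#' \code{sense = -1} flips the helix through a 180-degree rotation about x
#' before the offset is applied.
#'
#' @param params a valid \linkS4class{CrickParams}.
#' @param chain chain identifier for the result.
#' @return a \linkS4class{BackboneChain} of \code{params@length} residues.
#' @examples
#' h <- generateHelix(CrickParams(length = 19, R0 = 7, omega0 = -2.85))
#' range(sqrt(rowSums(diff(caCoords(h))^2)))
#' @export
generateHelix <- function(params, chain = "A") {
  validObject(params)
  ca <- crickCA(params)
  if (nrow(ca) < 3) {
    ## too short for triplet frames: lay template atoms along fixed axes
    tpl <- idealHelixBackbone(3)
    rel <- sweep(rbind(tpl$N[1, ], tpl$C[1, ], tpl$O[1, ]), 2, tpl$CA[1, ])
    N <- ca + matrix(rel[1, ], nrow(ca), 3, byrow = TRUE)
    C <- ca + matrix(rel[2, ], nrow(ca), 3, byrow = TRUE)
    O <- ca + matrix(rel[3, ], nrow(ca), 3, byrow = TRUE)
    return(BackboneChain(N, ca, C, O, chain))
  }
  bb <- completeBackbone(ca)
  BackboneChain(bb$N, ca, bb$C, bb$O, chain)
}

#' Rigidly transform a backbone chain
#'
#' @param chain a \linkS4class{BackboneChain}.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (Angstrom).
#' @return the transformed \linkS4class{BackboneChain}.
#' @export
transformChain <- function(chain, R = diag(3), t = c(0, 0, 0)) {
  BackboneChain(applyRigid(chain@N, R, t), applyRigid(chain@CA, R, t),
                applyRigid(chain@C, R, t), applyRigid(chain@O, R, t),
                chain@chain)
}

#' Reverse the traversal direction of a chain's CA trace
#'
#' Returns a chain whose residues run over the same CA positions in reverse
#' order, with N/C/O rebuilt for the new direction. Used when wiring helices
#' into a single chain.
#'
#' @param chain a \linkS4class{BackboneChain}.
#' @return a \linkS4class{BackboneChain}.
#' @export
reverseChain <- function(chain) {
  ca <- chain@CA[rev(seq_len(nResidues(chain))), , drop = FALSE]
  bb <- completeBackbone(ca)
  BackboneChain(bb$N, ca, bb$C, bb$O, chain@chain)
}

#' Ideal side-chain proxy (CB) positions from backbone atoms
#'
#' Builds a C-beta position at ideal tetrahedral geometry from N, CA and C.
#' Positions flagged as glycine return the CA position instead.
#'
#' @param chain a \linkS4class{BackboneChain}.
#' @param isGly logical vector (recycled) marking glycine positions.
#' @return numeric (n x 3) matrix of proxy points.
#' @export
buildCBProxy <- function(chain, isGly = FALSE) {
  n <- nResidues(chain)
  isGly <- rep_len(isGly, n)
  b <- chain@CA - chain@N
  c_ <- chain@C - chain@CA
  a <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
             b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
             b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  cb <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c_ + chain@CA
  cb[isGly, ] <- chain@CA[isGly, ]
  cb
}
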