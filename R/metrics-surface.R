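## Dot-surface machinery: Shrake-Rupley solvent accessibility, the
## Lawrence-Colman shape complementarity statistic, and the distance-weighted
## contact molecular surface. Surfaces are dot lattices on atom spheres with
## radial normals; occluded dots (inside a neighbouring sphere) are removed.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

elementRadius <- function(elety) {
  el <- substr(gsub("^[0-9 ]+", "", elety), 1, 1)
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic dot-lattice SASA: test points on each atom's solvent-expanded
#' sphere (vdW + probe) are kept when outside every neighbour's expanded
#' sphere; each atom's accessible area is the surviving fraction of its
#' sphere area.
#'
#' @param coords numeric (n x 3) atom coordinates.
#' @param radii per-atom van der Waals radii (Angstrom), recycled.
#' @param probe probe radius (Angstrom).
#' @param nPoints test points per atom.
#' @return list with \code{area} (total, Angstrom^2) and \code{perAtom}.
#' @export
shrakeRupleySASA <- function(coords, radii = 1.7, probe = 1.4, nPoints = 92) {
  coords <- rbind(coords)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  lattice <- sphereLattice(nPoints)
  rExp <- radii + probe
  perAtom <- numeric(n)
  d2all <- crossDist2(coords, coords)
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < (rExp[i] + rExp)^2 & seq_len(n) != i)
    pts <- sweep(lattice * rExp[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      acc[acc] <- rowSums(sweep(pts[acc, , drop = FALSE], 2, coords[j, ])^2) >= rExp[j]^2
      if (!any(acc)) break
    }
    perAtom[i] <- 4 * pi * rExp[i]^2 * sum(acc) / nPoints
  }
  list(area = sum(perAtom), perAtom = perAtom)
}

#' Dot surface of a set of atoms
#'
#' Samples points on each atom sphere at its van der Waals radius (about
#' \code{density} points per square Angstrom) with outward radial normals,
#' discarding points buried inside any other atom.
#'
#' @param coords numeric (n x 3) atom coordinates.
#' @param radii per-atom vdW radii (Angstrom), recycled.
#' @param density surface point density (points per Angstrom^2).
#' @return list with \code{points}, \code{normals} (m x 3) and \code{areas}
#'   (per-point patch area, Angstrom^2).
#' @export
dotSurface <- function(coords, radii = 1.7, density = 5) {
  coords <- rbind(coords)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  d2all <- crossDist2(coords, coords)
  pts <- list(); nrm <- list(); ar <- list()
  for (i in seq_len(n)) {
    m <- max(12L, ceiling(density * 4 * pi * radii[i]^2))
    lat <- sphereLattice(m)
    p <- sweep(lat * radii[i], 2, coords[i, ], "+")
    keep <- rep(TRUE, m)
    for (j in which(d2all[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)) {
      keep[keep] <- rowSums(sweep(p[keep, , drop = FALSE], 2, coords[j, ])^2) >= radii[j]^2
      if (!any(keep)) break
    }
    if (any(keep)) {
      pts[[length(pts) + 1L]] <- p[keep, , drop = FALSE]
      nrm[[length(nrm) + 1L]] <- lat[keep, , drop = FALSE]
      ar[[length(ar) + 1L]] <- rep(4 * pi * radii[i]^2 / m, sum(keep))
    }
  }
  list(points = do.call(rbind, pts), normals = do.call(rbind, nrm),
       areas = unlist(ar))
}

## nearest-neighbour index of each row of A in B (brute force)
nearestIndex <- function(A, B) {
  d2 <- crossDist2(A, B)
  list(index = max.col(-d2, ties.method = "first"),
       dist = sqrt(pmax(0, apply(d2, 1, min))))
}

#' Shape complementarity from point-normal surfaces
#'
#' Lawrence-Colman Sc on precomputed surfaces: for every surface point of
#' one side within \code{patchDist} of the opposing surface, score
#' exp(-w d^2) (n_a . -n_b) against its nearest opposing point; the statistic
#' averages the two per-side medians.
#'
#' @param ptsA,nrmA points and outward normals of side A (m x 3).
#' @param ptsB,nrmB points and outward normals of side B.
#' @param w distance attenuation (1/Angstrom^2).
#' @param patchDist buried-patch distance (points within this distance of
#'   the opposing surface form the interface patch, Angstrom).
#' @return Sc in [-1, 1].
#' @export
scFromSurfaces <- function(ptsA, nrmA, ptsB, nrmB, w = 0.5, patchDist = 1.5) {
  nnA <- nearestIndex(ptsA, ptsB)
  nnB <- nearestIndex(ptsB, ptsA)
  inA <- nnA$dist <= patchDist
  inB <- nnB$dist <= patchDist
  if (!any(inA) || !any(inB))
    stop("undefined interface: no buried surface patch within ", patchDist, " A")
  sideScore <- function(pts, nrm, oppPts, oppNrm, nn, keep) {
    d <- nn$dist[keep]
    dots <- rowSums(nrm[keep, , drop = FALSE] * -oppNrm[nn$index[keep], , drop = FALSE])
    stats::median(exp(-w * d^2) * dots)
  }
  (sideScore(ptsA, nrmA, ptsB, nrmB, nnA, inA) +
   sideScore(ptsB, nrmB, ptsA, nrmA, nnB, inB)) / 2
}

## restrict a structure's atoms to those within `pad` of the other side,
## then build its dot surface (keeps Sc/CMS tractable on full structures)
interfaceSurface <- function(coordsA, radiiA, coordsB, pad = 8) {
  d2 <- crossDist2(coordsA, coordsB)
  near <- apply(d2, 1, min) <= pad^2
  if (!any(near)) return(NULL)
  ## include the near atoms' occluding neighbours so burial is computed right
  d2self <- crossDist2(coordsA, coordsA[near, , drop = FALSE])
  keep <- apply(d2self, 1, min) <= 6^2
  s <- dotSurface(coordsA[keep, , drop = FALSE], radiiA[keep])
  ## but report only dots originating from near-interface atoms region
  s
}

#' Interaction shape complementarity of two chains
#'
#' Builds dot molecular surfaces for both chains (atoms within 8 A of the
#' partner, plus their occluders) and evaluates the Lawrence-Colman Sc
#' statistic on the buried interface patches.
#'
#' @param coordsA,coordsB atom coordinates of the two sides (n x 3).
#' @param radiiA,radiiB per-atom vdW radii (Angstrom), recycled.
#' @param w,patchDist see \code{\link{scFromSurfaces}}.
#' @return Sc in [-1, 1].
#' @export
shapeComplementarity <- function(coordsA, coordsB,
                                 radiiA = 1.7, radiiB = 1.7,
                                 w = 0.5, patchDist = 1.5) {
  coordsA <- rbind(coordsA); coordsB <- rbind(coordsB)
  radiiA <- rep_len(radiiA, nrow(coordsA))
  radiiB <- rep_len(radiiB, nrow(coordsB))
  sA <- interfaceSurface(coordsA, radiiA, coordsB)
  sB <- interfaceSurface(coordsB, radiiB, coordsA)
  if (is.null(sA) || is.null(sB))
    stop("undefined interface: chains share no atoms within 8 A")
  scFromSurfaces(sA$points, sA$normals, sB$points, sB$normals,
                 w = w, patchDist = patchDist)
}

#' Contact molecular surface area
#'
#' Distance-weighted area of chain A's molecular surface in contact with
#' chain B's: every surface dot of A contributes its patch area times
#' exp(-(d/sigma)^2), where d is the distance to B's nearest surface dot.
#' Dots farther than \code{maxDist} contribute nothing.
#'
#' @param coordsA,coordsB atom coordinates of the two sides.
#' @param radiiA,radiiB per-atom vdW radii, recycled.
#' @param sigma Gaussian distance attenuation (Angstrom).
#' @param maxDist hard contact cutoff (Angstrom).
#' @return contact area in Angstrom^2 (0 when the chains do not touch).
#' @export
contactMolecularSurface <- function(coordsA, coordsB,
                                    radiiA = 1.7, radiiB = 1.7,
                                    sigma = 1.5, maxDist = 3) {
  coordsA <- rbind(coordsA); coordsB <- rbind(coordsB)
  radiiA <- rep_len(radiiA, nrow(coordsA))
  radiiB <- rep_len(radiiB, nrow(coordsB))
  sA <- interfaceSurface(coordsA, radiiA, coordsB)
  sB <- interfaceSurface(coordsB, radiiB, coordsA)
  if (is.null(sA) || is.null(sB)) return(0)
  nn <- nearestIndex(sA$points, sB$points)
  w <- ifelse(nn$dist <= maxDist, exp(-(nn$dist / sigma)^2), 0)
  sum(sA$areas * w)
}
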