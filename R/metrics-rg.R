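## Compactness metrics and the guiding potential used during generative
## refinement: radius of gyration, its length-normalized form, the analytic
## gradient, and the cubic decay law for the potential's weight.

#' Radius of gyration
#'
#' Root mean square distance of the atoms (typically CA) from their
#' unweighted centroid.
#'
#' @param coords numeric (n x 3) coordinate matrix, n >= 1.
#' @return radius of gyration in Angstrom.
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(4, 0, 0)))  # 2
#' @export
radiusOfGyration <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 1) stop("radius of gyration needs at least one atom")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Length-normalized radius of gyration
#'
#' Radius of gyration divided by the radius of a sphere whose volume matches
#' the chain length (n residues x \code{vRes} cubic Angstrom per residue),
#' giving an approximately length-independent compactness score.
#'
#' @param coords numeric (n x 3) coordinate matrix.
#' @param nResidues residue count used for the reference sphere.
#' @param vRes assumed volume per residue (Angstrom^3).
#' @return dimensionless compactness value (about 0.77 for a uniform ball).
#' @export
rgLossNormalized <- function(coords, nResidues, vRes = 110) {
  stopifnot(nResidues >= 1)
  rSphere <- (3 * nResidues * vRes / (4 * pi))^(1 / 3)
  radiusOfGyration(coords) / rSphere
}

#' Radius-of-gyration guiding potential
#'
#' Returns the radius of gyration together with its analytic gradient with
#' respect to every coordinate; the gradient sums to zero (translation
#' invariance).
#'
#' @param coords numeric (n x 3) coordinate matrix, n >= 2.
#' @return list with \code{value} (Angstrom) and \code{gradient} (n x 3).
#' @export
rgGuidingPotential <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 2) stop("gradient of rg needs at least two atoms")
  n <- nrow(coords)
  ctr <- colMeans(coords)
  dev <- sweep(coords, 2, ctr)
  rg <- sqrt(mean(rowSums(dev^2)))
  grad <- if (rg < 1e-12) matrix(0, n, 3) else dev / (n * rg)
  list(value = rg, gradient = grad)
}

#' Cubic decay of the guiding-potential weight
#'
#' The potential matters most early in a denoising trajectory, when the
#' quaternary arrangement is still forming: with \code{t} counting down from
#' \code{T} (full weight) to 0 (end), the scale is w0 (t/T)^3.
#'
#' @param t current timestep, counting down; 0 <= t <= T.
#' @param T total trajectory length.
#' @param w0 base weight at t = T.
#' @return the decayed weight.
#' @examples
#' cubicDecayScale(100, 200, 1)  # 1/8
#' @export
cubicDecayScale <- function(t, T, w0) {
  if (any(t < 0 | t > T)) stop("timestep t must lie in [0, T]")
  w0 * (t / T)^3
}
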