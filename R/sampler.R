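## Random sampling of five-helix groove arrangements: three groove helices
## share a sampled supercoil and sit around an imaginary central slot helix
## (where the target is later docked); two buttressing helices use the same
## parameterization moved radially outwards with an extra sampled tilt.

#' SamplingConfig: distributions governing groove-scaffold sampling
#'
#' @slot helixLengthRange inclusive integer range of helix lengths.
#' @slot supercoilRange range of |omega0| in degrees/residue.
#' @slot supercoilRate rate of the truncated-exponential bias over |omega0|
#'   (larger favours more supercoiled scaffolds more strongly).
#' @slot supercoilSign sign applied to sampled |omega0| (-1: left-handed).
#' @slot avgNeighborDist mean and sd (Angstrom) of the Gaussian over the
#'   per-candidate average helix neighbour distance.
#' @slot perHelixDistSD sd of the much tighter per-helix Gaussian centred on
#'   the candidate's sampled average (Angstrom).
#' @slot phi1Range uniform range of the per-helix minor phase (degrees).
#' @slot zOffsetRange uniform range of the per-helix axial offset (Angstrom).
#' @slot groovePhases superhelical phases (degrees) of the groove helices;
#'   the face between the first and last phase is left open.
#' @slot buttressPhases superhelical phases of the two buttressing helices.
#' @slot buttressRadialExtra extra radial distance of buttresses (Angstrom).
#' @slot buttressTiltRange uniform tilt range about the radial direction
#'   (degrees).
#' @slot slotLength residue count of the imaginary central helix.
#' @slot clashCutoff minimum allowed inter-helix CA-CA distance (Angstrom).
#' @slot seed RNG seed used by \code{sampleLibrary}.
#' @export
setClass("SamplingConfig",
  representation(helixLengthRange = "integer", supercoilRange = "numeric",
                 supercoilRate = "numeric", supercoilSign = "numeric",
                 avgNeighborDist = "numeric", perHelixDistSD = "numeric",
                 phi1Range = "numeric", zOffsetRange = "numeric",
                 groovePhases = "numeric", buttressPhases = "numeric",
                 buttressRadialExtra = "numeric", buttressTiltRange = "numeric",
                 slotLength = "integer", clashCutoff = "numeric",
                 seed = "integer"))

setValidity("SamplingConfig", function(object) {
  msg <- character()
  if (diff(object@helixLengthRange) < 0) msg <- c(msg, "empty helix length range")
  if (object@avgNeighborDist[2] < 0 || object@perHelixDistSD < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@clashCutoff <= 0) msg <- c(msg, "clashCutoff must be > 0")
  if (length(object@groovePhases) != 3L) msg <- c(msg, "need exactly 3 groove phases")
  if (length(object@buttressPhases) != 2L) msg <- c(msg, "need exactly 2 buttress phases")
  if (length(msg)) msg else TRUE
})

#' Construct a SamplingConfig
#'
#' Defaults: helix lengths uniform on 15-19 residues; |omega0| from a
#' truncated exponential on [0, 6] deg/residue biased towards larger values
#' (rate 0.4/deg, left-handed sign); average neighbour distance
#' N(9.5, 0.7) A with per-helix noise sd 0.2 A; minor phase uniform on
#' [0, 360); z offset uniform on [-2, 2] A; groove helices at superhelical
#' phases 90/180/270 deg (open face towards +x); buttresses at 135/225 deg,
#' 4 A further out, tilted uniformly on [-15, 15] deg.
#'
#' @param helixLengthRange integer length-2 vector.
#' @param supercoilRange,supercoilRate,supercoilSign supercoil bias law.
#' @param avgNeighborDist c(mean, sd) in Angstrom.
#' @param perHelixDistSD per-helix distance sd (Angstrom).
#' @param phi1Range,zOffsetRange per-helix uniform ranges.
#' @param groovePhases,buttressPhases superhelical phases (degrees).
#' @param buttressRadialExtra,buttressTiltRange buttress placement.
#' @param slotLength central-slot residue count.
#' @param clashCutoff CA-CA clash threshold (Angstrom).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SamplingConfig}.
#' @export
SamplingConfig <- function(helixLengthRange = c(15L, 19L),
                           supercoilRange = c(0, 6), supercoilRate = 0.4,
                           supercoilSign = -1,
                           avgNeighborDist = c(9.5, 0.7), perHelixDistSD = 0.2,
                           phi1Range = c(0, 360), zOffsetRange = c(-2, 2),
                           groovePhases = c(90, 180, 270),
                           buttressPhases = c(135, 225),
                           buttressRadialExtra = 4, buttressTiltRange = c(-15, 15),
                           slotLength = 17L, clashCutoff = 4, seed = 1L) {
  new("SamplingConfig", helixLengthRange = as.integer(helixLengthRange),
      supercoilRange = supercoilRange, supercoilRate = supercoilRate,
      supercoilSign = supercoilSign, avgNeighborDist = avgNeighborDist,
      perHelixDistSD = perHelixDistSD, phi1Range = phi1Range,
      zOffsetRange = zOffsetRange, groovePhases = groovePhases,
      buttressPhases = buttressPhases, buttressRadialExtra = buttressRadialExtra,
      buttressTiltRange = buttressTiltRange, slotLength = as.integer(slotLength),
      clashCutoff = clashCutoff, seed = as.integer(seed))
}

#' Draw |omega0| from the supercoil-biased distribution
#'
#' Truncated exponential with density proportional to exp(rate * x) on the
#' configured range: larger rates favour more supercoiled scaffolds.
#'
#' @param n number of draws.
#' @param config a \linkS4class{SamplingConfig}.
#' @return numeric vector of |omega0| values (degrees/residue).
#' @export
sampleSupercoil <- function(n, config) {
  a <- config@supercoilRange[1]; b <- config@supercoilRange[2]
  lam <- config@supercoilRate
  u <- stats::runif(n)
  if (abs(lam) < 1e-12) return(a + u * (b - a))
  a + log(1 + u * (exp(lam * (b - a)) - 1)) / lam
}

## helper: center a helix chain vertically on z = 0 before applying offsets
centerZ <- function(ca) {
  ca[, 3] <- ca[, 3] - mean(ca[, 3])
  ca
}

buildPlacedHelix <- function(len, R0, omega0, phi0, phi1, zOff, sense,
                             chain, tilt = 0) {
  p <- CrickParams(length = len, R0 = R0, omega0 = omega0, phi0 = phi0,
                   phi1 = phi1, sense = sense)
  ca <- crickCA(p)
  ca <- centerZ(ca)
  if (tilt != 0) {
    ## tilt about the radial direction through the helix centroid
    ctr <- colMeans(ca)
    radial <- c(cos(deg2rad(phi0)), sin(deg2rad(phi0)), 0)
    R <- rotationMatrix(radial, tilt)
    ca <- sweep((sweep(ca, 2, ctr) %*% t(R)), 2, ctr, "+")
  }
  ca[, 3] <- ca[, 3] + zOff
  bb <- completeBackbone(ca)
  list(params = p, chain = BackboneChain(bb$N, ca, bb$C, bb$O, chain),
       zOff = zOff, tilt = tilt)
}

#' Sample one groove-scaffold candidate
#'
#' Draws one five-helix arrangement from the configured distributions using
#' the current RNG state. The three groove helices share the sampled
#' supercoil, with per-helix neighbour distances drawn from the tight
#' Gaussian around the candidate's sampled average; the buttressing helices
#' reuse the parameterization moved radially outwards with an extra sampled
#' tilt. Clashing arrangements are returned as rejections, not errors.
#'
#' @param config a \linkS4class{SamplingConfig}.
#' @param index candidate index recorded in the provenance.
#' @return a \linkS4class{ScaffoldCandidate}, or a list with class
#'   \code{"grooveRejection"} carrying a \code{reason} code.
#' @export
sampleCandidate <- function(config, index = NA_integer_) {
  validObject(config)
  lr <- config@helixLengthRange
  lens <- sample(seq(lr[1], lr[2]), 5, replace = TRUE)
  omega0 <- config@supercoilSign * sampleSupercoil(1, config)
  avgD <- stats::rnorm(1, config@avgNeighborDist[1], config@avgNeighborDist[2])
  dists <- stats::rnorm(5, avgD, config@perHelixDistSD)
  phi1 <- stats::runif(5, config@phi1Range[1], config@phi1Range[2])
  zoff <- stats::runif(5, config@zOffsetRange[1], config@zOffsetRange[2])
  tilts <- stats::runif(2, config@buttressTiltRange[1], config@buttressTiltRange[2])
  senses <- c(1, -1, 1, -1, 1)
  phases <- c(config@groovePhases, config@buttressPhases)
  radii <- c(dists[1:3], dists[4:5] + config@buttressRadialExtra)
  rise <- 1.51
  prov <- list(index = index, lengths = lens, omega0 = omega0,
               avg_neighbor_dist = avgD, helix_dists = dists,
               phi1 = phi1, z_offsets = zoff, tilts = tilts,
               phases = phases, senses = senses)
  ## supercoil too steep for the outermost helix: no real pitch angle
  if (max(radii) * abs(deg2rad(omega0)) >= rise)
    return(structure(list(reason = "pitch_domain", provenance = prov),
                     class = "grooveRejection"))
  built <- lapply(1:5, function(i) {
    buildPlacedHelix(lens[i], radii[i], omega0, phases[i], phi1[i], zoff[i],
                     senses[i], chain = LETTERS[i],
                     tilt = if (i >= 4) tilts[i - 3] else 0)
  })
  chains <- lapply(built, `[[`, "chain")
  ## clash screen between all helix pairs
  for (i in 1:4) for (j in (i + 1):5) {
    if (minCrossDist(chains[[i]]@CA, chains[[j]]@CA) < config@clashCutoff)
      return(structure(list(reason = "clash_interhelix", provenance = prov),
                       class = "grooveRejection"))
  }
  ## central slot must stay unoccupied: keep scaffold CA off the slot
  ## cylinder (radius 2.3 A around the z axis) by at least the clash cutoff
  slotHalf <- (config@slotLength - 1) * 1.51 / 2
  for (ch in chains) {
    ca <- ch@CA
    span <- abs(ca[, 3]) <= slotHalf + 2
    if (any(span)) {
      rad <- sqrt(ca[span, 1]^2 + ca[span, 2]^2)
      if (any(rad - 2.3 < config@clashCutoff))
        return(structure(list(reason = "slot_occlusion", provenance = prov),
                         class = "grooveRejection"))
    }
  }
  slotParams <- CrickParams(length = config@slotLength, R0 = 0, omega0 = 0,
                            zOffset = -slotHalf)
  new("ScaffoldCandidate", params = lapply(built, `[[`, "params"),
      chains = chains, slotParams = slotParams, provenance = prov)
}

#' Sample a library of accepted groove candidates
#'
#' Repeats \code{sampleCandidate} (rejection sampling, no repair) until
#' \code{n} candidates are accepted, recording rejection counts by reason.
#'
#' @param n number of accepted candidates required.
#' @param config a \linkS4class{SamplingConfig}; its seed fixes the RNG.
#' @param maxAttempts attempts after which a sub-0.1% acceptance rate is
#'   treated as a configuration error.
#' @return list with \code{candidates} (length n), \code{rejections} (named
#'   counts by reason) and \code{attempts}.
#' @examples
#' lib <- sampleLibrary(3, SamplingConfig(seed = 7))
#' lib$rejections
#' @export
sampleLibrary <- function(n, config, maxAttempts = 1e6) {
  stopifnot(n >= 0)
  set.seed(config@seed)
  out <- vector("list", n)
  rej <- c(clash_interhelix = 0L, slot_occlusion = 0L, pitch_domain = 0L)
  got <- 0L; att <- 0L
  while (got < n) {
    att <- att + 1L
    if (att > maxAttempts && got / att < 0.001)
      stop("sampling configuration error: acceptance rate below 0.1% after ",
           maxAttempts, " attempts")
    cand <- sampleCandidate(config, index = got + 1L)
    if (inherits(cand, "grooveRejection")) {
      rej[cand$reason] <- rej[cand$reason] + 1L
    } else {
      got <- got + 1L
      out[[got]] <- cand
    }
  }
  list(candidates = out, rejections = rej, attempts = att)
}

#' Provenance table of a sampled library
#'
#' @param library result of \code{\link{sampleLibrary}}.
#' @return data.frame with one row per accepted candidate.
#' @export
provenanceTable <- function(library) {
  do.call(rbind, lapply(library$candidates, function(cand) {
    p <- cand@provenance
    data.frame(index = p$index, omega0 = p$omega0,
               avg_neighbor_dist = p$avg_neighbor_dist,
               t(stats::setNames(p$lengths, paste0("len_", c("g1", "g2", "g3", "b1", "b2")))),
               t(stats::setNames(p$helix_dists, paste0("dist_", c("g1", "g2", "g3", "b1", "b2")))),
               tilt_b1 = p$tilts[1], tilt_b2 = p$tilts[2])
  }))
}

#' Dock a target helix into a scaffold's central slot
#'
#' Places the target on the slot axis: a given sequence is first built as an
#' ideal straight helix of matching length, a given backbone is used as-is
#' after centring on the slot. Fails if the docked helix clashes with the
#' scaffold.
#'
#' @param candidate a \linkS4class{ScaffoldCandidate}.
#' @param target a peptide sequence (character) or a
#'   \linkS4class{BackboneChain}.
#' @return a \linkS4class{HelixComplex}.
#' @export
dockTarget <- function(candidate, target) {
  slotLen <- candidate@slotParams@length
  if (is.character(target)) {
    seqChars <- validateSequence(target)
    n <- length(seqChars)
    if (n > slotLen + 4)
      stop("target helix length ", n, " exceeds central slot length + 4 (", slotLen + 4, ")")
    p <- CrickParams(length = n, R0 = 0, omega0 = 0, zOffset = -(n - 1) * 1.51 / 2)
    helix <- generateHelix(p, chain = "P")
    seqStr <- target
  } else {
    stopifnot(is(target, "BackboneChain"))
    n <- nResidues(target)
    if (n > slotLen + 4)
      stop("target helix length ", n, " exceeds central slot length + 4 (", slotLen + 4, ")")
    ca <- target@CA
    helix <- transformChain(target, t = -colMeans(ca))
    helix@chain <- "P"
    seqStr <- NA_character_
  }
  clashCut <- 4
  offenders <- integer(0)
  for (ch in candidate@chains) {
    d2 <- crossDist2(helix@CA, ch@CA)
    hit <- which(d2 < clashCut^2, arr.ind = TRUE)
    if (nrow(hit)) offenders <- union(offenders, hit[, 1])
  }
  if (length(offenders))
    stop("docking clash: target residues ", paste(sort(offenders), collapse = ", "),
         " within ", clashCut, " A of scaffold CA")
  new("HelixComplex", scaffold = candidate@chains, slotHelix = helix,
      slotSequence = seqStr)
}
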