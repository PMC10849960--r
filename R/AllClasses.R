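## Central S4 data objects. Constructors with defaults live next to each
## class; validity methods encode the geometric/probabilistic contracts.

#' @include AllGenerics.R utils-geometry.R
NULL

#' CrickParams: parametric description of one helix
#'
#' Parameters of the Crick coiled-coil parameterization for a single helix:
#' a superhelical circle of radius \code{R0} traversed at \code{omega0}
#' degrees per residue (signed; 0 gives a straight helix), decorated by a
#' minor helix of radius \code{R1} winding at \code{omega1} degrees per
#' residue. \code{rise} is the per-residue rise along the minor-helix axis.
#'
#' @slot R0 superhelical radius (Angstrom, >= 0).
#' @slot omega0 superhelical frequency (degrees/residue, signed).
#' @slot phi0 superhelical phase (degrees).
#' @slot R1 minor-helix radius (Angstrom, > 0).
#' @slot omega1 minor-helix frequency (degrees/residue).
#' @slot phi1 minor-helix phase (degrees).
#' @slot zOffset axial displacement added to all z coordinates (Angstrom).
#' @slot length residue count (>= 1).
#' @slot sense axial direction, +1 or -1.
#' @slot rise per-residue rise along the minor-helix axis (Angstrom).
#' @export
setClass("CrickParams",
  representation(R0 = "numeric", omega0 = "numeric", phi0 = "numeric",
                 R1 = "numeric", omega1 = "numeric", phi1 = "numeric",
                 zOffset = "numeric", length = "integer", sense = "numeric",
                 rise = "numeric"))

setValidity("CrickParams", function(object) {
  msg <- character()
  if (object@R0 < 0) msg <- c(msg, "R0 must be >= 0")
  if (object@R1 <= 0) msg <- c(msg, "R1 must be > 0")
  if (object@length < 1L) msg <- c(msg, "length must be >= 1")
  if (!object@sense %in% c(-1, 1)) msg <- c(msg, "sense must be +1 or -1")
  if (object@rise <= 0) msg <- c(msg, "rise must be > 0")
  if (abs(object@R0 * deg2rad(object@omega0)) >= object@rise)
    msg <- c(msg, "|R0 * omega0| incompatible with a real pitch angle (|R0*omega0_rad| must be < rise)")
  if (length(msg)) msg else TRUE
})

#' Construct CrickParams
#'
#' Defaults follow canonical coiled-coil values: rise 1.51 A/residue, minor
#' radius 2.26 A, minor frequency 102.85 deg/residue for supercoiled helices
#' and 100 deg/residue for straight (omega0 = 0) helices.
#'
#' @param length residue count.
#' @param R0,omega0,phi0 superhelical radius (A), frequency and phase (deg).
#' @param R1,omega1,phi1 minor-helix radius (A), frequency and phase (deg);
#'   \code{omega1 = NULL} picks 100 (straight) or 102.85 (supercoiled).
#' @param zOffset axial displacement (A).
#' @param sense +1 or -1 axial direction.
#' @param rise per-residue rise (A).
#' @return a \linkS4class{CrickParams} object.
#' @examples
#' p <- CrickParams(length = 17)
#' generateHelix(p)
#' @export
CrickParams <- function(length, R0 = 0, omega0 = 0, phi0 = 0,
                        R1 = 2.26, omega1 = NULL, phi1 = 0,
                        zOffset = 0, sense = 1, rise = 1.51) {
  if (is.null(omega1)) omega1 <- if (omega0 == 0) 100 else 102.85
  new("CrickParams", R0 = R0, omega0 = omega0, phi0 = phi0, R1 = R1,
      omega1 = omega1, phi1 = phi1, zOffset = zOffset,
      length = as.integer(length), sense = sense, rise = rise)
}

#' BackboneChain: heavy backbone atoms of one chain
#'
#' Coordinate container for per-residue N, CA, C, O atoms. Residue numbering
#' is 1-based and contiguous.
#'
#' @slot N,CA,C,O numeric matrices (n x 3), Angstrom.
#' @slot chain single-character chain identifier.
#' @export
setClass("BackboneChain",
  representation(N = "matrix", CA = "matrix", C = "matrix", O = "matrix",
                 chain = "character"))

setValidity("BackboneChain", function(object) {
  n <- nrow(object@CA)
  msg <- character()
  for (at in c("N", "C", "O"))
    if (nrow(slot(object, at)) != n) msg <- c(msg, paste(at, "and CA row counts differ"))
  if (n >= 2) {
    dca <- sqrt(rowSums((object@CA[-1, , drop = FALSE] - object@CA[-n, , drop = FALSE])^2))
    if (any(dca < 3.6 - 1e-9 | dca > 4.0 + 1e-9))
      msg <- c(msg, sprintf("consecutive CA-CA distance outside [3.6, 4.0] A (range %.3f-%.3f)",
                            min(dca), max(dca)))
    dcn <- sqrt(rowSums((object@N[-1, , drop = FALSE] - object@C[-n, , drop = FALSE])^2))
    if (any(dcn < 1.2 - 1e-9 | dcn > 1.5 + 1e-9))
      msg <- c(msg, sprintf("peptide C-N distance outside [1.2, 1.5] A (range %.3f-%.3f)",
                            min(dcn), max(dcn)))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BackboneChain
#' @param N,CA,C,O numeric (n x 3) matrices.
#' @param chain chain identifier (single character).
#' @return a \linkS4class{BackboneChain}.
#' @export
BackboneChain <- function(N, CA, C, O, chain = "A") {
  ## note: slots are assigned, not passed to new(), because the slot name
  ## "C" would partially match new()'s Class argument
  obj <- new("BackboneChain")
  obj@N <- unname(N); obj@CA <- unname(CA)
  obj@C <- unname(C); obj@O <- unname(O)
  obj@chain <- chain
  validObject(obj)
  obj
}

#' @describeIn nResidues residue count of a backbone chain.
#' @export
setMethod("nResidues", "BackboneChain", function(x) nrow(x@CA))

#' @describeIn caCoords CA coordinates of a backbone chain.
#' @export
setMethod("caCoords", "BackboneChain", function(x) x@CA)

#' @describeIn atomCoords backbone atom coordinates of one atom type.
#' @export
setMethod("atomCoords", "BackboneChain", function(x, atom = "CA") {
  atom <- match.arg(atom, c("N", "CA", "C", "O"))
  slot(x, atom)
})

#' @describeIn chainID chain identifier of a backbone chain.
#' @export
setMethod("chainID", "BackboneChain", function(x) x@chain)

setMethod("show", "BackboneChain", function(object) {
  cat(sprintf("BackboneChain %s: %d residues, CA z-span %.1f A\n",
              object@chain, nResidues(object),
              diff(range(object@CA[, 3]))))
})

#' ScaffoldCandidate: a sampled five-helix groove arrangement
#'
#' Three groove helices (g1-g3) around an unoccupied central slot plus two
#' buttressing helices (b1, b2), with the full sampling provenance.
#'
#' @slot params list of five \linkS4class{CrickParams} (g1, g2, g3, b1, b2).
#' @slot chains list of five \linkS4class{BackboneChain}.
#' @slot slotParams \linkS4class{CrickParams} of the imaginary central helix.
#' @slot provenance named list of every sampled value plus seed and index.
#' @export
setClass("ScaffoldCandidate",
  representation(params = "list", chains = "list",
                 slotParams = "CrickParams", provenance = "list"))

setValidity("ScaffoldCandidate", function(object) {
  if (length(object@chains) != 5L || length(object@params) != 5L)
    return("a scaffold candidate holds exactly five helices")
  TRUE
})

setMethod("show", "ScaffoldCandidate", function(object) {
  lens <- vapply(object@chains, nResidues, integer(1))
  cat(sprintf("ScaffoldCandidate: 5 helices (%s residues), omega0 = %.2f deg/res, avg neighbour dist = %.2f A\n",
              paste(lens, collapse = "/"),
              object@params[[1]]@omega0,
              object@provenance$avg_neighbor_dist))
})

#' HelixComplex: scaffold chains plus a docked target helix
#'
#' @slot scaffold list of \linkS4class{BackboneChain} (scaffold chains).
#' @slot slotHelix \linkS4class{BackboneChain} occupying the central slot.
#' @slot slotSequence sequence of the docked helix (NA if backbone-only).
#' @export
setClass("HelixComplex",
  representation(scaffold = "list", slotHelix = "BackboneChain",
                 slotSequence = "character"))

setMethod("show", "HelixComplex", function(object) {
  cat(sprintf("HelixComplex: %d scaffold chain(s) (%d residues) + slot helix of %d residues\n",
              length(object@scaffold),
              sum(vapply(object@scaffold, nResidues, integer(1))),
              nResidues(object@slotHelix)))
})

#' ThreadedComplex: a peptide threaded onto the slot helix
#'
#' @slot complex the underlying \linkS4class{HelixComplex}.
#' @slot peptide peptide sequence (one-letter).
#' @slot offset 0-based register offset along the slot helix.
#' @slot orientation "parallel" or "antiparallel" to slot numbering.
#' @slot annotation data.frame per peptide position: slot index, hydrophobic
#'   flag, in-contact flag (NA until scored).
#' @export
setClass("ThreadedComplex",
  representation(complex = "HelixComplex", peptide = "character",
                 offset = "integer", orientation = "character",
                 annotation = "data.frame"))

setValidity("ThreadedComplex", function(object) {
  np <- nchar(object@peptide)
  ns <- nResidues(object@complex@slotHelix)
  msg <- character()
  if (object@offset < 0L || object@offset > ns - np)
    msg <- c(msg, "offset out of range for slot/peptide lengths")
  if (!object@orientation %in% c("parallel", "antiparallel"))
    msg <- c(msg, "orientation must be parallel or antiparallel")
  if (nrow(object@annotation) != np)
    msg <- c(msg, "annotation length must equal peptide length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ThreadedComplex", function(object) {
  cat(sprintf("ThreadedComplex: %d-mer at offset %d (%s), %s\n",
              nchar(object@peptide), object@offset, object@orientation,
              if (all(is.na(object@annotation$in_contact))) "unscored"
              else sprintf("%d hydrophobic contact position(s)",
                           sum(object@annotation$hydrophobic &
                               object@annotation$in_contact, na.rm = TRUE))))
})

#' Distogram: per-pair probability over inter-residue distance bins
#'
#' @slot probs numeric array (n x n x B); each pair's vector sums to 1.
#' @slot edges bin edges in Angstrom, strictly increasing, length B + 1
#'   (last may be Inf).
#' @slot binderIdx,targetIdx integer residue indices of the two chains.
#' @export
setClass("Distogram",
  representation(probs = "array", edges = "numeric",
                 binderIdx = "integer", targetIdx = "integer"))

setValidity("Distogram", function(object) {
  msg <- character()
  d <- dim(object@probs)
  if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "probs must be an n x n x B array")
  if (length(object@edges) != d[3] + 1L) msg <- c(msg, "edges must have B + 1 entries")
  if (any(diff(object@edges) <= 0)) msg <- c(msg, "edges must be strictly increasing")
  s <- rowSums(matrix(object@probs, ncol = d[3]))
  if (any(abs(s - 1) > 1e-6)) msg <- c(msg, "per-pair probabilities must sum to 1 (+- 1e-6)")
  if (length(intersect(object@binderIdx, object@targetIdx)) > 0)
    msg <- c(msg, "binder and target index sets overlap")
  if (length(msg)) msg else TRUE
})

#' Construct a Distogram
#' @param probs n x n x B probability array.
#' @param edges B + 1 ascending bin edges (Angstrom).
#' @param binderIdx,targetIdx residue indices of the binder and target chains.
#' @return a \linkS4class{Distogram}.
#' @export
Distogram <- function(probs, edges, binderIdx, targetIdx) {
  new("Distogram", probs = probs, edges = as.numeric(edges),
      binderIdx = as.integer(binderIdx), targetIdx = as.integer(targetIdx))
}

#' PaeMatrix: pairwise aligned-error estimates
#'
#' @slot values non-negative square matrix of aligned errors (Angstrom).
#' @slot binderIdx,targetIdx integer residue indices of the two chains.
#' @export
setClass("PaeMatrix",
  representation(values = "matrix", binderIdx = "integer", targetIdx = "integer"))

setValidity("PaeMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != ncol(object@values)) msg <- c(msg, "pAE matrix must be square")
  if (any(object@values < 0)) msg <- c(msg, "pAE values must be non-negative")
  if (length(c(object@binderIdx, object@targetIdx)) != nrow(object@values))
    msg <- c(msg, "partition does not match matrix size")
  if (length(msg)) msg else TRUE
})

#' Construct a PaeMatrix
#' @param values square non-negative matrix (Angstrom).
#' @param binderIdx,targetIdx residue indices of the binder and target chains.
#' @return a \linkS4class{PaeMatrix}.
#' @export
PaeMatrix <- function(values, binderIdx, targetIdx) {
  new("PaeMatrix", values = values,
      binderIdx = as.integer(binderIdx), targetIdx = as.integer(targetIdx))
}

#' OraclePrediction: output contract of a structure-prediction oracle
#'
#' Any component that can predict a binder-target complex from sequence can
#' drive the annealing engine by returning this object.
#'
#' @slot plddt per-residue confidence, 0-100.
#' @slot ptm global complex confidence, 0-1.
#' @slot pae a \linkS4class{PaeMatrix}.
#' @slot distogram a \linkS4class{Distogram}.
#' @slot coords predicted CA coordinates (n x 3, Angstrom).
#' @slot binderLength,targetLength chain lengths.
#' @export
setClass("OraclePrediction",
  representation(plddt = "numeric", ptm = "numeric", pae = "PaeMatrix",
                 distogram = "Distogram", coords = "matrix",
                 binderLength = "integer", targetLength = "integer"))

setValidity("OraclePrediction", function(object) {
  n <- object@binderLength + object@targetLength
  msg <- character()
  if (length(object@plddt) != n) msg <- c(msg, "plddt length mismatch")
  if (any(object@plddt < 0 | object@plddt > 100)) msg <- c(msg, "plddt must be in [0, 100]")
  if (object@ptm < 0 || object@ptm > 1) msg <- c(msg, "ptm must be in [0, 1]")
  if (nrow(object@coords) != n) msg <- c(msg, "coords row count mismatch")
  if (nrow(object@pae@values) != n) msg <- c(msg, "pAE size mismatch")
  if (dim(object@distogram@probs)[1] != n) msg <- c(msg, "distogram size mismatch")
  if (length(msg)) msg else TRUE
})

#' Construct an OraclePrediction
#' @param plddt per-residue confidence (0-100).
#' @param ptm complex confidence (0-1).
#' @param pae a \linkS4class{PaeMatrix}.
#' @param distogram a \linkS4class{Distogram}.
#' @param coords CA coordinates (n x 3).
#' @param binderLength,targetLength chain lengths.
#' @return an \linkS4class{OraclePrediction}.
#' @export
OraclePrediction <- function(plddt, ptm, pae, distogram, coords,
                             binderLength, targetLength) {
  new("OraclePrediction", plddt = plddt, ptm = ptm, pae = pae,
      distogram = distogram, coords = coords,
      binderLength = as.integer(binderLength),
      targetLength = as.integer(targetLength))
}

#' AnnealSchedule: phase plan and temperature law for annealing
#'
#' @slot phases data.frame with columns \code{steps} and \code{mutations}
#'   (simultaneous substitutions per proposal).
#' @slot T0 starting temperature.
#' @slot halfLife temperature half-life in steps.
#' @export
setClass("AnnealSchedule",
  representation(phases = "data.frame", T0 = "numeric", halfLife = "numeric"))

setValidity("AnnealSchedule", function(object) {
  msg <- character()
  if (!all(c("steps", "mutations") %in% names(object@phases)))
    msg <- c(msg, "phases needs columns steps and mutations")
  else if (any(object@phases$steps <= 0) || any(object@phases$mutations < 1))
    msg <- c(msg, "step counts must be positive and mutations >= 1")
  if (object@T0 <= 0) msg <- c(msg, "T0 must be > 0")
  if (object@halfLife <= 0) msg <- c(msg, "halfLife must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnealSchedule
#' @param phases data.frame(steps, mutations).
#' @param T0 starting temperature.
#' @param halfLife half-life of the exponential temperature decay, in steps.
#' @return an \linkS4class{AnnealSchedule}.
#' @export
AnnealSchedule <- function(phases, T0 = 0.01, halfLife = 500) {
  new("AnnealSchedule", phases = phases, T0 = T0, halfLife = halfLife)
}

#' Default annealing schedule
#'
#' 1,250 steps proposing 3 simultaneous substitutions, 2,500 proposing 2,
#' then 1,250 proposing 1 (5,000 steps total), with starting temperature
#' 0.01 halving every 500 steps.
#'
#' @return an \linkS4class{AnnealSchedule}.
#' @examples
#' totalSteps(defaultSchedule())
#' @export
defaultSchedule <- function() {
  AnnealSchedule(data.frame(steps = c(1250, 2500, 1250), mutations = c(3, 2, 1)),
                 T0 = 0.01, halfLife = 500)
}

#' @describeIn totalSteps sum of phase step counts.
#' @export
setMethod("totalSteps", "AnnealSchedule", function(x) sum(x@phases$steps))

setMethod("show", "AnnealSchedule", function(object) {
  cat(sprintf("AnnealSchedule: %d steps (%s), T0 = %g, half-life = %g steps\n",
              totalSteps(object),
              paste(sprintf("%dx%d", object@phases$steps, object@phases$mutations),
                    collapse = ", "),
              object@T0, object@halfLife))
})

#' TrajectoryRecord: full bookkeeping of one annealing run
#'
#' @slot steps data.frame with one row per step: step index, proposed and
#'   current sequence hashes, loss components, total, temperature, accept flag.
#' @slot bestSeq lowest-loss sequence seen.
#' @slot bestLoss its total loss.
#' @slot finalPrediction oracle prediction for the final accepted sequence.
#' @slot seed RNG seed of the run.
#' @export
setClass("TrajectoryRecord",
  representation(steps = "data.frame", bestSeq = "character",
                 bestLoss = "numeric", finalPrediction = "OraclePrediction",
                 seed = "integer"))

#' @describeIn trajectorySteps per-step table.
#' @export
setMethod("trajectorySteps", "TrajectoryRecord", function(x) x@steps)

#' @describeIn bestSequence lowest-loss sequence.
#' @export
setMethod("bestSequence", "TrajectoryRecord", function(x) x@bestSeq)

setMethod("show", "TrajectoryRecord", function(object) {
  cat(sprintf("TrajectoryRecord: %d steps, %d accepted, best loss %.4f\n",
              nrow(object@steps), sum(object@steps$accepted), object@bestLoss))
})
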