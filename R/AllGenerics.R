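#' @import methods
NULL

#' Number of residues in an object
#' @param x an object with residue content.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' C-alpha coordinates
#' @param x an object holding backbone coordinates.
#' @return numeric matrix (n x 3) of CA positions in Angstrom.
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' Backbone atom coordinates by atom name
#' @param x an object holding backbone coordinates.
#' @param atom one of "N", "CA", "C", "O".
#' @return numeric matrix (n x 3).
#' @export
setGeneric("atomCoords", function(x, atom = "CA") standardGeneric("atomCoords"))

#' Chain identifier
#' @param x an object with a chain ID.
#' @return single character.
#' @export
setGeneric("chainID", function(x) standardGeneric("chainID"))

#' Estimate the helix axis of a backbone chain
#'
#' Per-residue axis points estimated from sliding windows of consecutive CA
#' positions (the bisector construction, exact for an ideal helix).
#'
#' @param chain a \linkS4class{BackboneChain} with at least 4 residues.
#' @return numeric matrix (n x 3) of axis points, one per residue.
#' @export
setGeneric("helixAxis", function(chain) standardGeneric("helixAxis"))

#' Total number of annealing steps in a schedule
#' @param x an \linkS4class{AnnealSchedule}.
#' @return integer.
#' @export
setGeneric("totalSteps", function(x) standardGeneric("totalSteps"))

#' Per-step trajectory table of an annealing run
#' @param x a \linkS4class{TrajectoryRecord}.
#' @return data.frame with one row per step.
#' @export
setGeneric("trajectorySteps", function(x) standardGeneric("trajectorySteps"))

#' Best (lowest-loss) sequence found by an annealing run
#' @param x a \linkS4class{TrajectoryRecord}.
#' @return character scalar.
#' @export
setGeneric("bestSequence", function(x) standardGeneric("bestSequence"))
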