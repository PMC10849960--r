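## Threading a target peptide sequence onto the bound (slot) helix of a
## scaffold-helix complex, and scoring/filtering by interfacial hydrophobic
## contacts between side-chain proxy points (ideal C-beta; CA for glycine).

## peptide position p (1-based) -> slot residue index for a given register
threadSlotIndex <- function(p, offset, orientation, peptideLen) {
  if (orientation == "parallel") offset + p else offset + (peptideLen - p + 1L)
}

#' Enumerate all threadings of a peptide onto the slot helix
#'
#' Every register offset crossed with both orientations, in deterministic
#' order: offset ascending, parallel before antiparallel.
#'
#' @param complex a \linkS4class{HelixComplex}.
#' @param peptide peptide sequence (one-letter codes).
#' @return list of \linkS4class{ThreadedComplex}, length
#'   (slotLen - peptideLen + 1) x 2.
#' @export
enumerateThreadings <- function(complex, peptide) {
  aa <- validateSequence(peptide)
  np <- length(aa)
  ns <- nResidues(complex@slotHelix)
  if (np > ns) stop("peptide length ", np, " exceeds slot length ", ns)
  hydro <- aa %in% hydrophobicResidues()
  out <- list()
  for (off in 0:(ns - np)) {
    for (ori in c("parallel", "antiparallel")) {
      ann <- data.frame(position = seq_len(np),
                        slot_index = vapply(seq_len(np), threadSlotIndex,
                                            integer(1), offset = as.integer(off),
                                            orientation = ori, peptideLen = np),
                        residue = aa, hydrophobic = hydro,
                        in_contact = NA)
      out[[length(out) + 1L]] <-
        new("ThreadedComplex", complex = complex, peptide = peptide,
            offset = as.integer(off), orientation = ori, annotation = ann)
    }
  }
  out
}

#' Count peptide positions making hydrophobic interface contacts
#'
#' A peptide position counts when its residue is hydrophobic (A, V, L, I, M,
#' F, W, Y) and its side-chain proxy point on the slot helix lies within
#' \code{cutoff} of any scaffold proxy point.
#'
#' @param threaded a \linkS4class{ThreadedComplex}.
#' @param cutoff proxy-proxy distance cutoff (Angstrom).
#' @return integer in 0..peptide length.
#' @export
hydrophobicContactCount <- function(threaded, cutoff = 8) {
  ann <- annotateThreading(threaded, cutoff)@annotation
  sum(ann$hydrophobic & ann$in_contact)
}

#' Annotate a threading with interface contact flags
#'
#' @param threaded a \linkS4class{ThreadedComplex}.
#' @param cutoff proxy-proxy distance cutoff (Angstrom).
#' @return the \linkS4class{ThreadedComplex} with \code{in_contact} filled.
#' @export
annotateThreading <- function(threaded, cutoff = 8) {
  cx <- threaded@complex
  slotCB <- buildCBProxy(cx@slotHelix, isGly = FALSE)
  aa <- splitSeq(threaded@peptide)
  ann <- threaded@annotation
  pepCB <- slotCB[ann$slot_index, , drop = FALSE]
  pepCB[aa == "G", ] <- caCoords(cx@slotHelix)[ann$slot_index[aa == "G"], , drop = FALSE]
  scafCB <- do.call(rbind, lapply(cx@scaffold, buildCBProxy))
  d2 <- crossDist2(pepCB, scafCB)
  ann$in_contact <- apply(d2, 1, min) <= cutoff^2
  threaded@annotation <- ann
  threaded
}

#' Rank threadings by hydrophobic contact count and apply a floor
#'
#' Descending by count; ties broken by offset (ascending) then orientation
#' (parallel first). Entries below \code{minHydrophobic} are dropped.
#'
#' @param threadings list of \linkS4class{ThreadedComplex}.
#' @param minHydrophobic minimum contact count to retain.
#' @param cutoff proxy-proxy distance cutoff (Angstrom).
#' @return list of scored \linkS4class{ThreadedComplex}, ranked; the counts
#'   are attached as the \code{"counts"} attribute.
#' @export
filterThreadings <- function(threadings, minHydrophobic = 0, cutoff = 8) {
  scored <- lapply(threadings, annotateThreading, cutoff = cutoff)
  counts <- vapply(scored, function(th)
    sum(th@annotation$hydrophobic & th@annotation$in_contact), integer(1))
  offs <- vapply(scored, function(th) th@offset, integer(1))
  oris <- vapply(scored, function(th) th@orientation, character(1))
  ord <- order(-counts, offs, match(oris, c("parallel", "antiparallel")))
  keep <- ord[counts[ord] >= minHydrophobic]
  structure(scored[keep], counts = counts[keep])
}
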