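## Structure and sequence I/O. PDB parsing and writing go through bio3d
## (first altLoc kept, waters and heteroatoms skipped by default); FASTA
## through Biostrings.

#' Read a PDB file into backbone chains
#'
#' Chains are split by chain ID; only the first alternate location is kept;
#' waters and heteroatoms are skipped unless \code{includeHet}. Residues
#' missing any of N, CA or C are dropped (a missing carbonyl O is rebuilt
#' from the local CA frame); author residue numbers are preserved in a side
#' table.
#'
#' @param path PDB file path.
#' @param includeHet keep HETATM records.
#' @return list with \code{chains} (named list of
#'   \linkS4class{BackboneChain}), \code{numbering} (data.frame chain,
#'   position, author_resno) and \code{sequence} (named list of one-letter
#'   sequences where resolvable).
#' @export
readStructure <- function(path, includeHet = FALSE) {
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!includeHet) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records in ", path)
  chains <- list(); numbering <- list(); seqs <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    key <- paste(sub$resno, sub$insert)
    resKeys <- unique(key)
    getAtom <- function(k, name) {
      row <- sub[key == k & sub$elety == name, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      c(row$x[1], row$y[1], row$z[1])
    }
    N <- CA <- C <- O <- NULL
    keptResno <- integer(0); resid3 <- character(0)
    for (k in resKeys) {
      n <- getAtom(k, "N"); ca <- getAtom(k, "CA"); cc <- getAtom(k, "C")
      if (is.null(n) || is.null(ca) || is.null(cc)) next
      o <- getAtom(k, "O")
      N <- rbind(N, n); CA <- rbind(CA, ca); C <- rbind(C, cc)
      O <- rbind(O, if (is.null(o)) c(NA, NA, NA) else o)
      keptResno <- c(keptResno, sub$resno[key == k][1])
      resid3 <- c(resid3, sub$resid[key == k][1])
    }
    if (is.null(CA) || nrow(CA) < 1) next
    if (anyNA(O)) {
      if (nrow(CA) >= 3) {
        bb <- completeBackbone(CA)
        O[is.na(O[, 1]), ] <- bb$O[is.na(O[, 1]), ]
      } else O[is.na(O[, 1]), ] <- C[is.na(O[, 1]), ] + c(0, 0, 1.23)
    }
    ## crystal structures may break the ideal-geometry invariants (cis
    ## peptides, chain breaks); fall back to an unvalidated container
    chainObj <- tryCatch(
      BackboneChain(unname(N), unname(CA), unname(C), unname(O), chain = ch),
      error = function(e) {
        obj <- new("BackboneChain")
        obj@N <- unname(N); obj@CA <- unname(CA)
        obj@C <- unname(C); obj@O <- unname(O)
        obj@chain <- ch
        obj
      })
    chains[[ch]] <- chainObj
    numbering[[ch]] <- data.frame(chain = ch, position = seq_len(nrow(CA)),
                                  author_resno = keptResno)
    aa1 <- tryCatch(bio3d::aa321(resid3), warning = function(w)
      suppressWarnings(bio3d::aa321(resid3)))
    seqs[[ch]] <- paste(aa1, collapse = "")
  }
  if (length(chains) == 0) stop("no chains with complete backbone in ", path)
  list(chains = chains, numbering = do.call(rbind, numbering), sequence = seqs)
}

#' Write backbone chains to a PDB file
#'
#' ATOM records with TER between chains; chain IDs taken from the chains
#' themselves (A-F for scaffold models, P conventionally for the peptide).
#'
#' @param chains a \linkS4class{BackboneChain} or list of them.
#' @param path output file path.
#' @param sequences optional named list (by chain ID) of one-letter
#'   sequences used for residue names; defaults to ALA (GLY for G).
#' @return invisibly, the path.
#' @export
writeStructure <- function(chains, path, sequences = NULL) {
  if (is(chains, "BackboneChain")) chains <- list(chains)
  xyz <- c(); resno <- c(); resid <- c(); chainId <- c(); elety <- c()
  for (ch in chains) {
    n <- nResidues(ch)
    seqCh <- if (!is.null(sequences) && !is.null(sequences[[ch@chain]]))
      splitSeq(sequences[[ch@chain]]) else rep("A", n)
    res3 <- bio3d::aa123(seqCh)
    for (i in seq_len(n)) {
      for (at in c("N", "CA", "C", "O")) {
        xyz <- c(xyz, slot(ch, at)[i, ])
        resno <- c(resno, i); resid <- c(resid, res3[i])
        chainId <- c(chainId, ch@chain); elety <- c(elety, at)
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   chain = chainId, elety = elety, chainter = TRUE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), names(s))
}
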