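AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Hydrophobic residue set used for interface filtering
#'
#' One-letter codes of the residues counted as hydrophobic when scoring
#' threaded peptide interfaces.
#'
#' @return character vector of one-letter codes.
#' @export
hydrophobicResidues <- function() c("A", "V", "L", "I", "M", "F", "W", "Y")

#' Background amino acid frequencies of the BLOSUM62 construction
#'
#' The marginal amino acid probabilities underlying the BLOSUM62 substitution
#' matrix, used both for seeding random sequences and for drawing substitution
#' letters during annealing.
#'
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
blosum62Frequencies <- function() {
  f <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  f / sum(f)
}

## FNV-1a on the sequence string; returns a non-negative double < 2^31.
sequenceHash <- function(seq) {
  bytes <- utf8ToInt(seq)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  h
}

splitSeq <- function(seq) strsplit(seq, "")[[1]]

validateSequence <- function(seq) {
  aa <- splitSeq(seq)
  bad <- setdiff(unique(aa), AA_LETTERS)
  if (length(bad) > 0)
    stop("sequence contains non-standard letters: ", paste(bad, collapse = ", "))
  aa
}
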