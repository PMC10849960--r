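## A deterministic toy oracle: a pure function of the sequences that emits
## all the tensors of the oracle contract. Confidence grows with similarity
## to a planted optimal binder sequence, so the annealing mechanics can be
## exercised (and their convergence verified against a known optimum)
## without any neural network.

#' Build a deterministic toy oracle with a planted optimum
#'
#' Returns an oracle closure whose prediction quality is a pure function of
#' the per-position agreement between the binder sequence and
#' \code{optimum}: matching positions get high pLDDT, mismatches low, each
#' with a small deterministic per-position spread (as a real predictor
#' would produce); pTM, contact probability and interface pAE interpolate
#' between their worst and best values with overall similarity. Coordinates
#' are two ideal helices side by side, with the binder's minor phase set by
#' a hash of its sequence so coordinates are sequence-determined.
#'
#' @param optimum planted optimal binder sequence.
#' @param plddtHigh,plddtLow per-residue confidence baselines at matching
#'   and mismatching positions.
#' @return function(binderSeq, targetSeq, residueIndex) returning an
#'   \linkS4class{OraclePrediction}.
#' @export
makeToyOracle <- function(optimum, plddtHigh = 92, plddtLow = 35) {
  optAA <- validateSequence(optimum)
  edges <- c(0, 2, 4, 6, 8, 12, 16, 22, Inf)
  function(binderSeq, targetSeq, residueIndex = NULL) {
    aa <- splitSeq(binderSeq)
    if (length(aa) != length(optAA))
      stop("toy oracle expects binder length ", length(optAA))
    tl <- nchar(targetSeq)
    nb <- length(aa)
    n <- nb + tl
    match <- aa == optAA
    sim <- mean(match)
    jitter <- ((seq_len(nb) * 2654435761) %% 97) / 97  # fixed per position
    plddt <- c(ifelse(match, plddtHigh + 6 * jitter, plddtLow + 8 * jitter),
               rep(90, tl))
    ptm <- 0.4 + 0.6 * sim
    ## coordinates: binder helix on the z axis, target helix alongside;
    ## binder phase keyed to the sequence hash so coords are sequence-pure
    phase <- sequenceHash(binderSeq) %% 360
    binderCA <- crickCA(CrickParams(length = nb, phi1 = phase))
    targetCA <- crickCA(CrickParams(length = tl))
    targetCA[, 1] <- targetCA[, 1] + 9.5
    coords <- rbind(binderCA, targetCA)
    bi <- seq_len(nb); ti <- nb + seq_len(tl)
    ## pAE: confident diagonal blocks, interface error shrinking with sim
    pae <- matrix(1 + 0.5 * (1 - sim), n, n)
    inter <- 0.8 + 29 * (1 - sim)
    pae[bi, ti] <- inter; pae[ti, bi] <- inter
    diag(pae) <- 0.2
    ## distogram: inter-chain sub-8 mass equals sim, intra mass near truth
    B <- length(edges) - 1L
    probs <- array(0, c(n, n, B))
    d <- sqrt(pmax(crossDist2(coords, coords), 0))
    bins <- findInterval(pmin(as.vector(d), 21.9), edges)
    probs[cbind(rep(seq_len(n), times = n), rep(seq_len(n), each = n), bins)] <- 1
    ## inter-chain blocks: sub-8-A contact mass tracks the similarity
    probs[bi, ti, ] <- 0; probs[ti, bi, ] <- 0
    probs[bi, ti, 3] <- sim; probs[bi, ti, 6] <- 1 - sim
    probs[ti, bi, 3] <- sim; probs[ti, bi, 6] <- 1 - sim
    OraclePrediction(plddt = plddt, ptm = ptm,
                     pae = PaeMatrix(pae, bi, ti),
                     distogram = Distogram(probs, edges, bi, ti),
                     coords = coords, binderLength = nb, targetLength = tl)
  }
}
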