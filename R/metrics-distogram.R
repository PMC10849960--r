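## Probabilistic interface metrics computed from oracle output tensors.

#' Probability that the target is in contact with the binder
#'
#' For each target residue, the probability mass in the sub-8-Angstrom
#' distance bins against the most-contacting binder residue (max over binder
#' residues), averaged over target residues. A bin straddling 8 A
#' contributes fractional mass by linear interpolation.
#'
#' @param d a \linkS4class{Distogram} with a binder/target chain partition.
#' @param thresh contact distance threshold (Angstrom).
#' @return contact probability in [0, 1].
#' @export
contactProbabilityLoss <- function(d, thresh = 8) {
  validObject(d)
  if (d@edges[1] >= thresh)
    stop("distogram has no bin boundary below ", thresh,
         " A; cannot resolve sub-threshold contact mass")
  ## per-pair sub-threshold mass for all pairs at once
  lo <- d@edges[-length(d@edges)]
  hi <- d@edges[-1]
  frac <- pmin(pmax((thresh - lo) / (hi - lo), 0), 1)
  frac[is.infinite(hi)] <- 0
  n <- dim(d@probs)[1]
  mass <- matrix(matrix(d@probs, ncol = length(frac)) %*% frac, n, n)
  perTarget <- apply(mass[d@targetIdx, d@binderIdx, drop = FALSE], 1, max)
  mean(perTarget)
}

#' Mean inter-chain predicted aligned error
#'
#' Mean of the aligned-error values over both off-diagonal (binder x target
#' and target x binder) blocks.
#'
#' @param p a \linkS4class{PaeMatrix}.
#' @return mean interface pAE in Angstrom.
#' @export
interfacePae <- function(p) {
  validObject(p)
  if (length(p@binderIdx) == 0 || length(p@targetIdx) == 0)
    stop("interface pAE undefined: empty chain block")
  mean(c(p@values[p@binderIdx, p@targetIdx], p@values[p@targetIdx, p@binderIdx]))
}
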