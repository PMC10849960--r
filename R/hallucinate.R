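## Sequence-space Monte-Carlo simulated annealing against a pluggable
## structure-prediction oracle. The oracle is any function
## (binderSeq, targetSeq, residueIndex) -> OraclePrediction; the residue
## index encodes the chain break as a +32 positional offset on the target.

#' Draw a random seed sequence from background frequencies
#'
#' Letters are drawn i.i.d. from the BLOSUM62 background amino acid
#' frequencies.
#'
#' @param length sequence length (>= 1).
#' @return character scalar sequence.
#' @export
initSequence <- function(length) {
  if (length < 1) stop("sequence length must be >= 1")
  f <- blosum62Frequencies()
  paste(sample(names(f), length, replace = TRUE, prob = f), collapse = "")
}

#' Propose simultaneous substitutions at low-confidence positions
#'
#' Mutates exactly \code{k} distinct binder positions, drawn only from the
#' lowest-50%-pLDDT binder positions (positions at or below the median are
#' eligible, so a uniform profile makes every position eligible). New
#' letters are drawn from the background frequencies, renormalized to
#' exclude the current letter. If fewer than \code{k} positions are
#' eligible, k is reduced to the eligible count.
#'
#' @param sequence current binder sequence.
#' @param plddt per-binder-residue confidence from the last prediction.
#' @param k requested number of simultaneous substitutions.
#' @return proposed sequence (character scalar).
#' @export
proposeMutations <- function(sequence, plddt, k) {
  stopifnot(k >= 1)
  aa <- splitSeq(sequence)
  if (length(plddt) != length(aa))
    stop("plddt length must match binder sequence length")
  eligible <- which(plddt <= stats::median(plddt))
  k <- min(k, length(eligible))
  pos <- if (length(eligible) == 1) eligible else sample(eligible, k)
  f <- blosum62Frequencies()
  for (p in pos) {
    probs <- f[names(f) != aa[p]]
    aa[p] <- sample(names(probs), 1, prob = probs / sum(probs))
  }
  paste(aa, collapse = "")
}

#' Combined annealing loss from an oracle prediction
#'
#' total = w1 (1 - pLDDT/100) + w2 (1 - pTM) + w3 rgNorm +
#'         w4 (1 - contactProbability) + w5 (interfacePae / paeMax),
#' with default relative weights 1:1:0.1:3:5. Maximized quantities are
#' folded as (1 - x) with pLDDT scaled to [0, 1] and the interface pAE
#' normalized by \code{paeMax}; lower is better.
#'
#' @param pred an \linkS4class{OraclePrediction}.
#' @param weights named numeric: plddt, ptm, rg, contact, pae.
#' @param paeMax pAE normalization constant (Angstrom).
#' @return list with \code{total} and named \code{components} (unweighted).
#' @export
totalLoss <- function(pred,
                      weights = c(plddt = 1, ptm = 1, rg = 0.1, contact = 3, pae = 5),
                      paeMax = 31) {
  need <- c("plddt", "ptm", "rg", "contact", "pae")
  if (!all(need %in% names(weights)))
    stop("missing loss weight(s): ", paste(setdiff(need, names(weights)), collapse = ", "))
  comp <- c(
    plddt = 1 - mean(pred@plddt) / 100,
    ptm = 1 - pred@ptm,
    rg = rgLossNormalized(pred@coords, pred@binderLength + pred@targetLength),
    contact = 1 - contactProbabilityLoss(pred@distogram),
    pae = interfacePae(pred@pae) / paeMax)
  list(total = sum(weights[need] * comp[need]), components = comp)
}

#' Metropolis acceptance test
#'
#' Accept when the loss does not increase; otherwise accept with
#' probability exp(-delta / T).
#'
#' @param delta loss change (candidate minus current).
#' @param temperature current temperature (> 0).
#' @return logical accept flag.
#' @export
metropolisAccept <- function(delta, temperature) {
  stopifnot(temperature > 0)
  delta <= 0 || stats::runif(1) < exp(-delta / temperature)
}

#' Annealing temperature at a step
#'
#' Exponential decay: T0 2^(-step / halfLife).
#'
#' @param step step index (>= 0).
#' @param T0 starting temperature.
#' @param halfLife half-life in steps.
#' @return temperature.
#' @examples
#' temperatureAt(500, 0.01, 500)  # 0.005
#' @export
temperatureAt <- function(step, T0 = 0.01, halfLife = 500) {
  stopifnot(all(step >= 0))
  T0 * 2^(-step / halfLife)
}

## chain-break encoding: target residue indices are offset by +32
residueIndexWithBreak <- function(binderLength, targetLength, offset = 32L) {
  c(seq_len(binderLength), binderLength + offset + seq_len(targetLength))
}

#' Run simulated-annealing sequence design against an oracle
#'
#' Starting from a random background-frequency seed sequence, repeatedly
#' proposes substitutions at low-confidence binder positions, re-predicts
#' the binder-target complex with the oracle (the chain break is passed as
#' a +32 residue index offset) and accepts or rejects by the Metropolis
#' criterion under the schedule's exponentially decaying temperature.
#' The eligible-position confidence profile is refreshed only after
#' accepted steps.
#'
#' @param oracle function(binderSeq, targetSeq, residueIndex) returning an
#'   \linkS4class{OraclePrediction}.
#' @param targetSeq target peptide sequence (never mutated).
#' @param binderLength binder chain length (commonly 60, 70, 80, 90 or 100).
#' @param schedule an \linkS4class{AnnealSchedule}.
#' @param seed integer RNG seed.
#' @param weights,paeMax passed to \code{\link{totalLoss}}.
#' @return a \linkS4class{TrajectoryRecord}.
#' @examples
#' oracle <- makeToyOracle("LEIKKALEQAIK")
#' run <- runHallucination(oracle, targetSeq = "GSHLVEALYLV", binderLength = 12,
#'                         schedule = AnnealSchedule(data.frame(steps = 50, mutations = 1)),
#'                         seed = 1)
#' bestSequence(run)
#' @export
runHallucination <- function(oracle, targetSeq, binderLength,
                             schedule = defaultSchedule(), seed = 1,
                             weights = c(plddt = 1, ptm = 1, rg = 0.1,
                                         contact = 3, pae = 5),
                             paeMax = 31) {
  stopifnot(nchar(targetSeq) > 0, binderLength >= 1)
  validObject(schedule)
  set.seed(seed)
  ridx <- residueIndexWithBreak(binderLength, nchar(targetSeq))
  predictSafe <- function(seq, step) {
    tryCatch(oracle(seq, targetSeq, ridx), error = function(e)
      stop("oracle failure at step ", step, ": ", conditionMessage(e), call. = FALSE))
  }
  cur <- initSequence(binderLength)
  pred <- predictSafe(cur, 0L)
  curLoss <- totalLoss(pred, weights, paeMax)
  best <- cur; bestLoss <- curLoss$total
  kPerStep <- rep(schedule@phases$mutations, schedule@phases$steps)
  nSteps <- length(kPerStep)
  comp0 <- curLoss$components
  rec <- data.frame(step = seq_len(nSteps), temperature = NA_real_,
                    accepted = NA, total = NA_real_, sequence = NA_character_,
                    hash = NA_real_)
  for (nm in names(comp0)) rec[[paste0("loss_", nm)]] <- NA_real_
  binderPlddt <- pred@plddt[seq_len(binderLength)]
  for (s in seq_len(nSteps)) {
    temp <- temperatureAt(s - 1, schedule@T0, schedule@halfLife)
    candSeq <- proposeMutations(cur, binderPlddt, kPerStep[s])
    candPred <- predictSafe(candSeq, s)
    candLoss <- totalLoss(candPred, weights, paeMax)
    acc <- metropolisAccept(candLoss$total - curLoss$total, temp)
    if (acc) {
      cur <- candSeq; pred <- candPred; curLoss <- candLoss
      binderPlddt <- pred@plddt[seq_len(binderLength)]
      if (curLoss$total < bestLoss) { best <- cur; bestLoss <- curLoss$total }
    }
    rec$temperature[s] <- temp
    rec$accepted[s] <- acc
    rec$total[s] <- curLoss$total
    rec$sequence[s] <- cur
    rec$hash[s] <- sequenceHash(cur)
    for (nm in names(curLoss$components))
      rec[[paste0("loss_", nm)]][s] <- curLoss$components[nm]
  }
  new("TrajectoryRecord", steps = rec, bestSeq = best, bestLoss = bestLoss,
      finalPrediction = pred, seed = as.integer(seed))
}
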