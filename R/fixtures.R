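## Deterministic fixture generation: every module can be exercised without
## any download. All fixtures are pure functions of (kind, params, seed).

#' Generate a self-describing fixture
#'
#' Kinds:
#' \describe{
#'   \item{ideal_helix_peptide}{an ideal straight helix; params: length
#'     (default 17). Writes a PDB when \code{dir} is given.}
#'   \item{toy_complex}{a sampled groove scaffold with a docked poly-A
#'     target; params: slotLength.}
#'   \item{oracle_tensors}{an \linkS4class{OraclePrediction} with consistent
#'     shapes; params: binderLength (80), targetLength (34).}
#'   \item{sc_toy_surfaces}{complementary sphere-in-pocket point/normal
#'     surfaces for shape-complementarity checks; params: radius (5),
#'     gap (0.25), n (800).}
#' }
#'
#' @param kind fixture kind (see above).
#' @param params named list of kind-specific parameters.
#' @param seed integer seed (fixtures involving sampling are reproducible).
#' @param dir optional output directory; when given, files are written and
#'   their paths returned alongside the objects.
#' @return named list with the fixture object(s) and any file paths.
#' @export
makeFixture <- function(kind, params = list(), seed = 1, dir = NULL) {
  set.seed(seed)
  out <- switch(kind,
    ideal_helix_peptide = {
      len <- params$length %||% 17
      helix <- generateHelix(CrickParams(length = len), chain = "P")
      files <- NULL
      if (!is.null(dir)) {
        f <- file.path(dir, sprintf("ideal_helix_%d.pdb", len))
        writeStructure(helix, f)
        files <- f
      }
      list(helix = helix, files = files)
    },
    toy_complex = {
      cfg <- SamplingConfig(seed = as.integer(seed),
                            slotLength = as.integer(params$slotLength %||% 17L))
      lib <- sampleLibrary(1, cfg)
      cand <- lib$candidates[[1]]
      pep <- paste(rep("A", cfg@slotLength), collapse = "")
      cx <- dockTarget(cand, pep)
      files <- NULL
      if (!is.null(dir)) {
        f <- file.path(dir, "toy_complex.pdb")
        writeStructure(c(cx@scaffold, list(cx@slotHelix)), f)
        files <- f
      }
      list(candidate = cand, complex = cx, files = files)
    },
    oracle_tensors = {
      nb <- params$binderLength %||% 80
      nt <- params$targetLength %||% 34
      oracle <- makeToyOracle(initSequence(nb))
      pred <- oracle(initSequence(nb), paste(rep("A", nt), collapse = ""))
      files <- NULL
      if (!is.null(dir)) {
        f <- file.path(dir, "oracle_pae.tsv")
        utils::write.table(pred@pae@values, f, sep = "\t",
                           row.names = FALSE, col.names = FALSE)
        files <- f
      }
      list(prediction = pred, files = files)
    },
    sc_toy_surfaces = {
      r <- params$radius %||% 5
      gap <- params$gap %||% 0.25
      n <- params$n %||% 800
      dirs <- sphereLattice(n)
      half <- dirs[, 3] < 0  # lower hemisphere: the seated contact patch
      ptsA <- dirs[half, ] * r
      nrmA <- dirs[half, ]
      ptsB <- dirs[half, ] * (r + gap)
      nrmB <- -dirs[half, ]  # pocket surface faces inward
      list(ptsA = ptsA, nrmA = nrmA, ptsB = ptsB, nrmB = nrmB, files = NULL)
    },
    stop("unknown fixture kind: ", kind))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
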