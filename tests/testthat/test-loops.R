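## toy scaffolds for wiring tests are built from ideal helices moved rigidly

fiveParallel <- function(spacing = 45) {
  h <- generateHelix(CrickParams(length = 15))
  lapply(0:4, function(i) transformChain(h, t = c(i * spacing, 0, 0)))
}

test_that("plans are empty when every junction gap exceeds the loop budget", {
  plans <- enumeratePlans(fiveParallel(45), loopLenRange = c(2L, 5L))
  expect_length(plans, 0)
})

test_that("an adjacent antiparallel pair admits a 2-residue loop", {
  ## gap of ~6 A needs ceiling((6 - 2)/3.8) = 2 loop residues
  h1 <- generateHelix(CrickParams(length = 15))
  h2 <- transformChain(reverseChain(h1), t = c(6, 0, 0))
  plans <- enumeratePlans(list(h1, h2))
  expect_gt(length(plans), 0)
  best <- plans[[1]]
  expect_lt(sum(best@gaps), 7)
  expect_equal(best@loopLengths[1], 2L)
})

test_that("plan ranking matches an exhaustive independent enumeration", {
  set.seed(31)
  h <- generateHelix(CrickParams(length = 15))
  chains <- lapply(1:5, function(i)
    transformChain(h, rotationMatrix(rnorm(3), runif(1, 0, 180)),
                   rnorm(3, 0, 6)))
  plans <- enumeratePlans(chains, maxPlans = 1000L)
  ## independent brute force over all 5! x 2^5 combinations
  ends <- lapply(chains, function(ch) {
    ca <- caCoords(ch); list(f = ca[1, ], l = ca[nrow(ca), ])
  })
  refTotals <- c()
  perm <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))))
  for (ord in perm(1:5)) for (mask in 0:31) {
    rev5 <- as.logical(bitwAnd(mask, 2^(0:4)))
    gaps <- sapply(1:4, function(j) {
      a <- ord[j]; b <- ord[j + 1]
      ep <- if (rev5[a]) ends[[a]]$f else ends[[a]]$l
      sp <- if (rev5[b]) ends[[b]]$l else ends[[b]]$f
      sqrt(sum((ep - sp)^2))
    })
    if (all(gaps <= 5 * 3.8 + 2)) refTotals <- c(refTotals, sum(gaps))
  }
  expect_length(plans, length(refTotals))
  expect_equal(sapply(plans, function(p) sum(p@gaps)), sort(refTotals),
               tolerance = 1e-9)
})

test_that("closing two nearby helices yields a valid single chain preserving helix CAs", {
  h1 <- generateHelix(CrickParams(length = 15))
  h2 <- transformChain(reverseChain(h1), t = c(9, 0, 0))
  plans <- enumeratePlans(list(h1, h2))
  expect_gt(length(plans), 0)
  res <- closeLoops(list(h1, h2), new("ConnectionPlan", order = 1:2,
                                      reversed = c(FALSE, FALSE),
                                      loopLengths = 3L, gaps = 9))
  expect_false(inherits(res, "loopFailure"))
  ca <- caCoords(res$chain)
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(steps >= 3.6 - 1e-9 & steps <= 4.0 + 1e-9))
  expect_true(validObject(res$chain))
  ## helix residues are bit-identical to their source coordinates
  helixRows <- res$mapping$source == "helix1"
  expect_equal(ca[helixRows, ], caCoords(h1), tolerance = 0)
  expect_equal(nrow(ca), sum(grepl("helix", res$mapping$source)) +
                 sum(grepl("loop", res$mapping$source)))
})

test_that("an impossible junction fails at the offending 0-based index", {
  h1 <- generateHelix(CrickParams(length = 15))
  h2 <- transformChain(h1, t = c(40, 0, 0))
  res <- closeLoops(list(h1, h2), new("ConnectionPlan", order = 1:2,
                                      reversed = c(FALSE, FALSE),
                                      loopLengths = 5L, gaps = 40))
  expect_s3_class(res, "loopFailure")
  expect_equal(res$junction, 0L)
})

test_that("a full sampled scaffold can be closed into one valid chain", {
  lib <- sampleLibrary(4, SamplingConfig(seed = 7))
  closedAny <- FALSE
  for (cand in lib$candidates) {
    plans <- enumeratePlans(cand, maxPlans = 10L)
    for (pl in plans) {
      res <- closeLoops(cand, pl)
      if (!inherits(res, "loopFailure")) {
        closedAny <- TRUE
        expect_true(validObject(res$chain))
        expect_equal(nResidues(res$chain), nrow(res$mapping))
        break
      }
    }
    if (closedAny) break
  }
  expect_true(closedAny)
})
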