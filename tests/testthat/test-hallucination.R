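test_that("seed sequences follow the background amino acid frequencies", {
  expect_error(initSequence(0), ">= 1")
  set.seed(101)
  draws <- table(factor(strsplit(paste(replicate(100, initSequence(1000)),
                                       collapse = ""), "")[[1]],
                        levels = names(blosum62Frequencies())))
  n <- sum(draws)
  f <- blosum62Frequencies()
  z <- abs(draws - n * f) / sqrt(n * f * (1 - f))
  expect_true(all(z < 4))  # 3-sigma bounds with a Bonferroni margin
  set.seed(7); a <- initSequence(50)
  set.seed(7); b <- initSequence(50)
  expect_identical(a, b)
})

test_that("proposals mutate exactly k low-confidence positions", {
  set.seed(5)
  seqc <- initSequence(30)
  plddt <- runif(30, 0, 100)
  eligible <- which(plddt <= median(plddt))
  for (k in c(1, 2, 3)) {
    prop <- proposeMutations(seqc, plddt, k)
    diffPos <- which(strsplit(seqc, "")[[1]] != strsplit(prop, "")[[1]])
    expect_length(diffPos, k)
    expect_true(all(diffPos %in% eligible))
  }
  ## uniform confidence: every position is eligible
  hit <- integer(0)
  for (i in 1:300) {
    prop <- proposeMutations(seqc, rep(50, 30), 1)
    hit <- union(hit, which(strsplit(seqc, "")[[1]] != strsplit(prop, "")[[1]]))
  }
  expect_setequal(hit, 1:30)
  ## ties at the 50% cut are all included
  lop <- c(1, rep(100, 29))
  prop <- proposeMutations(seqc, lop, 3)
  expect_length(which(strsplit(seqc, "")[[1]] != strsplit(prop, "")[[1]]), 3)
  ## k larger than the eligible pool is clamped
  prop1 <- proposeMutations("L", 50, 3)
  expect_equal(nchar(prop1), 1)
  expect_false(prop1 == "L")
})

test_that("the combined loss reproduces its closed-form extremes and hand sums", {
  mkPred <- function(plddt, ptm, paeVal, contactMass, coords) {
    n <- nrow(coords)
    edges <- c(0, 4, 8, 16, Inf)
    probs <- array(0, c(n, n, 4))
    probs[, , 2] <- contactMass; probs[, , 4] <- 1 - contactMass
    pae <- matrix(paeVal, n, n)
    OraclePrediction(rep(plddt, n), ptm, PaeMatrix(pae, 1L, 2L),
                     Distogram(probs, edges, 1L, 2L), coords, 1L, 1L)
  }
  ## perfect prediction: only the compactness term remains
  coords <- rbind(c(0, 0, 0), c(4, 0, 0))
  perfect <- mkPred(100, 1, 0, 1, coords)
  c0 <- rgLossNormalized(coords, 2)
  expect_equal(totalLoss(perfect)$total, 0.1 * c0, tolerance = 1e-12)
  ## worst case engineered so every component is exactly 1
  rS <- (3 * 2 * 110 / (4 * pi))^(1 / 3)
  worstCoords <- rbind(c(0, 0, 0), c(2 * rS, 0, 0))
  worst <- mkPred(0, 0, 31, 0, worstCoords)
  expect_equal(totalLoss(worst)$total, 1 + 1 + 0.1 + 3 + 5, tolerance = 1e-12)
  ## random tensors against an independently computed weighted sum
  set.seed(9)
  oracle <- makeToyOracle("LEIKKALEQAIK")
  pred <- oracle(initSequence(12), "GSHLVEALYLVG")
  got <- totalLoss(pred)
  ref <- 1 * (1 - mean(pred@plddt) / 100) + 1 * (1 - pred@ptm) +
    0.1 * rgLossNormalized(pred@coords, 24) +
    3 * (1 - contactProbabilityLoss(pred@distogram)) +
    5 * interfacePae(pred@pae) / 31
  expect_equal(got$total, ref, tolerance = 1e-12)
  expect_error(totalLoss(pred, weights = c(plddt = 1)), "missing loss weight")
})

test_that("Metropolis criterion accepts downhill always and uphill at exp(-delta/T)", {
  set.seed(2)
  expect_true(all(replicate(100, metropolisAccept(-0.01, 0.01))))
  expect_true(all(replicate(100, metropolisAccept(0, 0.01))))
  Tt <- 0.02
  acc <- mean(replicate(10000, metropolisAccept(Tt * log(2), Tt)))
  expect_equal(acc, 0.5, tolerance = 0.02)
})

test_that("the annealing temperature starts at 0.01 and halves every 500 steps", {
  expect_equal(temperatureAt(0), 0.01)
  expect_equal(temperatureAt(500), 0.005)
  expect_equal(temperatureAt(1000), 0.0025)
})

test_that("annealing runs are reproducible and keep consistent bookkeeping", {
  oracle <- makeToyOracle("LEIKKALEQAIK")
  sched <- AnnealSchedule(data.frame(steps = c(30, 60), mutations = c(2, 1)))
  r1 <- runHallucination(oracle, "GSHLVEALYLVG", 12, sched, seed = 3)
  r2 <- runHallucination(oracle, "GSHLVEALYLVG", 12, sched, seed = 3)
  expect_identical(trajectorySteps(r1), trajectorySteps(r2))
  steps <- trajectorySteps(r1)
  expect_equal(nrow(steps), 90)
  w <- c(plddt = 1, ptm = 1, rg = 0.1, contact = 3, pae = 5)
  recomputed <- as.numeric(as.matrix(steps[, paste0("loss_", names(w))]) %*% w)
  expect_lt(max(abs(recomputed - steps$total)), 1e-12)
  expect_equal(r1@bestLoss, min(steps$total))
  ## acceptance rate decays with temperature on a fixed landscape
  early <- mean(steps$accepted[1:30])
  late <- mean(steps$accepted[61:90])
  expect_lte(late, early)
})

test_that("annealing recovers a planted optimal 12-mer across seeded runs", {
  optimum <- "LEIKKALEQAIK"
  oracle <- makeToyOracle(optimum)
  sched <- AnnealSchedule(data.frame(steps = c(150, 1350), mutations = c(2, 1)))
  hits <- sum(vapply(1:20, function(s)
    bestSequence(runHallucination(oracle, "GSHLVEAL", 12, sched, seed = s)) ==
      optimum, logical(1)))
  expect_gte(hits, 19)  # >= 95% of 20 runs
})

test_that("oracle failures abort with the step index", {
  flaky <- function(binderSeq, targetSeq, residueIndex = NULL) stop("boom")
  sched <- AnnealSchedule(data.frame(steps = 5, mutations = 1))
  expect_error(runHallucination(flaky, "GSHL", 8, sched, seed = 1),
               "oracle failure at step 0")
})
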