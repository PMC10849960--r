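test_that("radius of gyration matches closed forms and brute force", {
  expect_identical(radiusOfGyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(6, 0, 0))), 3)
  set.seed(4)
  X <- matrix(rnorm(150, sd = 8), 50, 3)
  expect_lt(abs(radiusOfGyration(X) - refRg(X)), 1e-9)
  expect_error(radiusOfGyration(matrix(numeric(0), 0, 3)), "at least one atom")
})

test_that("normalized rg is homogeneous and matches the uniform-ball constant", {
  expect_identical(rgLossNormalized(matrix(0, 1, 3), 1), 0)
  set.seed(8)
  X <- matrix(rnorm(90), 30, 3)
  expect_equal(rgLossNormalized(2 * X, 30), 2 * rgLossNormalized(X, 30),
               tolerance = 1e-12)
  ## points uniform in the reference sphere itself: expect sqrt(3/5)
  n <- 60
  rS <- (3 * n * 110 / (4 * pi))^(1 / 3)
  m <- 40000
  pts <- matrix(rnorm(3 * m), m, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * rS * runif(m)^(1 / 3)
  expect_equal(rgLossNormalized(pts, n), sqrt(3 / 5), tolerance = 0.01)
})

test_that("rg guiding potential gradient is analytic and translation-free", {
  set.seed(12)
  X <- matrix(rnorm(45, sd = 5), 15, 3)
  gp <- rgGuidingPotential(X)
  expect_equal(gp$value, radiusOfGyration(X))
  expect_lt(max(abs(colSums(gp$gradient))), 1e-12)
  ## central finite differences
  h <- 1e-4
  num <- matrix(NA_real_, 15, 3)
  for (i in 1:15) for (j in 1:3) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    num[i, j] <- (radiusOfGyration(Xp) - radiusOfGyration(Xm)) / (2 * h)
  }
  expect_lt(max(abs(gp$gradient - num)), 1e-5)
  ## coincident atoms: zero gradient
  expect_true(all(rgGuidingPotential(matrix(1, 4, 3))$gradient == 0))
})

test_that("cubic decay schedule has the stated boundary and midpoint values", {
  expect_equal(cubicDecayScale(200, 200, 2), 2)
  expect_equal(cubicDecayScale(0, 200, 2), 0)
  expect_equal(cubicDecayScale(100, 200, 2), 2 / 8)
  expect_error(cubicDecayScale(-1, 200, 2), "\\[0, T\\]")
  expect_error(cubicDecayScale(201, 200, 2), "\\[0, T\\]")
})

## a small random distogram with a straddling bin
makeToyDistogram <- function(n = 6, binder = 1:3, target = 4:6, seed = 1) {
  set.seed(seed)
  edges <- c(0, 3, 6, 7.5, 9, 12, Inf)
  probs <- array(runif(n * n * 6), c(n, n, 6))
  probs <- probs / rep(apply(probs, c(1, 2), sum), 6)
  Distogram(probs, edges, binder, target)
}

test_that("contact probability equals independent bin summation with interpolation", {
  d <- makeToyDistogram()
  got <- contactProbabilityLoss(d)
  ## brute force: mass of bins below 8 A, straddling bin (7.5, 9) counts
  ## fractionally as (8 - 7.5)/(9 - 7.5)
  frac <- c(1, 1, 1, (8 - 7.5) / (9 - 7.5), 0, 0)
  ref <- mean(sapply(4:6, function(ti)
    max(sapply(1:3, function(bi) sum(d@probs[ti, bi, ] * frac)))))
  expect_equal(got, ref, tolerance = 1e-12)
  ## extremes
  probsLo <- array(0, c(2, 2, 6)); probsLo[, , 1] <- 1
  expect_equal(contactProbabilityLoss(Distogram(probsLo, d@edges, 1L, 2L)), 1)
  probsHi <- array(0, c(2, 2, 6)); probsHi[, , 6] <- 1
  expect_equal(contactProbabilityLoss(Distogram(probsHi, d@edges, 1L, 2L)), 0)
  ## no boundary below the threshold
  probs1 <- array(1, c(2, 2, 1))
  expect_error(contactProbabilityLoss(Distogram(probs1, c(9, Inf), 1L, 2L)),
               "bin boundary")
})

test_that("contact probability is invariant to relabeling within chains", {
  d <- makeToyDistogram()
  perm <- c(2, 3, 1, 6, 4, 5)  # permutes within binder block and target block
  d2 <- Distogram(d@probs[perm, perm, ], d@edges, 1:3, 4:6)
  expect_equal(contactProbabilityLoss(d), contactProbabilityLoss(d2),
               tolerance = 1e-12)
})

test_that("interface pAE is the mean over both off-diagonal blocks", {
  M <- matrix(5, 6, 6)
  expect_equal(interfacePae(PaeMatrix(M, 1:3, 4:6)), 5)
  B <- matrix(1, 6, 6); B[1:3, 4:6] <- 7; B[4:6, 1:3] <- 7
  expect_equal(interfacePae(PaeMatrix(B, 1:3, 4:6)), 7)
  set.seed(3)
  R <- matrix(abs(rnorm(64)), 8, 8)
  got <- interfacePae(PaeMatrix(R, 1:5, 6:8))
  ref <- mean(c(as.vector(R[1:5, 6:8]), as.vector(R[6:8, 1:5])))
  expect_equal(got, ref, tolerance = 1e-12)
  perm <- c(sample(1:5), 5 + sample(1:3))
  expect_equal(interfacePae(PaeMatrix(R[perm, perm], 1:5, 6:8)), got,
               tolerance = 1e-12)
})
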