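test_that("Crick closed forms: single-residue placement and straight-helix extent", {
  p1 <- CrickParams(length = 1, R0 = 5, phi0 = 0, phi1 = 0)
  expect_equal(drop(caCoords(generateHelix(p1))), c(5 + 2.26, 0, 0),
               tolerance = 1e-9)
  p17 <- CrickParams(length = 17, omega1 = 100, rise = 1.5)
  ca <- caCoords(generateHelix(p17))
  expect_equal(diff(range(ca[, 3])), 24.0, tolerance = 1e-9)  # 16 x 1.5 A
})

test_that("supercoiled CA trace matches an independent evaluation of the equations", {
  p <- CrickParams(length = 19, R0 = 7, omega0 = -2.85, phi0 = 33, phi1 = 140)
  ca <- caCoords(generateHelix(p))
  ref <- refCrickCA(19, 7, -2.85, 33, 2.26, 102.85, 140)
  expect_lt(max(abs(ca - unname(ref))), 1e-9)
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(d >= 3.7 & d <= 3.9))
})

test_that("18-residue periodicity of the straight helix is a pure 27 A z-translation", {
  ca <- caCoords(generateHelix(CrickParams(length = 19, omega1 = 100, rise = 1.5)))
  shift <- ca[19, ] - ca[1, ]
  expect_equal(shift, c(0, 0, 27.0), tolerance = 1e-6)
})

test_that("invalid Crick parameters raise errors naming the violated constraint", {
  expect_error(CrickParams(length = 0), "length")
  expect_error(CrickParams(length = 9, R1 = -1), "R1")
  expect_error(CrickParams(length = 9, R0 = 20, omega0 = 6), "pitch")
})

test_that("backbone completion is rigid-motion equivariant", {
  ca <- caCoords(generateHelix(CrickParams(length = 15, R0 = 8, omega0 = -3)))
  R <- rotationMatrix(c(1, 2, 3), 61)
  t <- c(5, -2, 9)
  bb1 <- completeBackbone(ca %*% t(R) + matrix(t, nrow(ca), 3, byrow = TRUE))
  bb0 <- completeBackbone(ca)
  for (at in c("N", "C", "O")) {
    moved <- bb0[[at]] %*% t(R) + matrix(t, nrow(ca), 3, byrow = TRUE)
    expect_lt(max(abs(bb1[[at]] - moved)), 1e-6)
  }
})

test_that("generated chains satisfy backbone chemical sanity across sampler ranges", {
  set.seed(21)
  for (i in 1:25) {
    R0 <- runif(1, 0, 15)
    w0 <- -runif(1, 0, 6)
    if (R0 * abs(w0) * pi / 180 >= 1.51) next
    h <- generateHelix(CrickParams(length = sample(15:19, 1), R0 = R0, omega0 = w0,
                                   phi0 = runif(1, 0, 360), phi1 = runif(1, 0, 360),
                                   sense = sample(c(-1, 1), 1)))
    expect_true(validObject(h))  # CA-CA and C-N bond windows
  }
})

test_that("helix axis is exact for straight helices and tracks the superhelix", {
  hs <- generateHelix(CrickParams(length = 17))
  axS <- helixAxis(hs)
  expect_lt(max(sqrt(axS[, 1]^2 + axS[, 2]^2)), 0.1)
  ## rigid-motion equivariance of the axis
  ht <- transformChain(hs, t = c(10, 0, 0))
  expect_equal(helixAxis(ht), axS + matrix(c(10, 0, 0), nrow(axS), 3, byrow = TRUE),
               tolerance = 1e-9)
  hsc <- generateHelix(CrickParams(length = 19, R0 = 7, omega0 = -2.85))
  ax <- helixAxis(hsc)
  r <- sqrt(ax[, 1]^2 + ax[, 2]^2)
  expect_true(all(abs(r - 7) < 0.2))
  expect_error(helixAxis(generateHelix(CrickParams(length = 3))), "4 residues")
})

test_that("neighbor distance: identity, parallel offset, and supercoiled bundle", {
  h <- generateHelix(CrickParams(length = 17))
  expect_equal(neighborDistance(h, h), 0, tolerance = 1e-9)
  expect_equal(neighborDistance(h, transformChain(h, t = c(10, 0, 0))), 10,
               tolerance = 0.05)
  ## two helices of one supercoiled bundle at 60 deg phase separation on a
  ## 9.5 A superhelical circle: nominal axis spacing 2 * 9.5 * sin(30 deg)
  p1 <- CrickParams(length = 18, R0 = 9.5, omega0 = -3, phi0 = 0)
  p2 <- CrickParams(length = 18, R0 = 9.5, omega0 = -3, phi0 = 60)
  nominal <- 2 * 9.5 * sin(pi / 6)
  nd <- neighborDistance(generateHelix(p1), generateHelix(p2))
  expect_equal(nd, nominal, tolerance = 0.3)
  ## brute-force dense-polyline check on the fitted axes
  ref <- refPolylineMinDist(helixAxis(generateHelix(p1)), helixAxis(generateHelix(p2)))
  expect_lt(abs(nd - ref), 0.5)
})
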