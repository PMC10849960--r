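test_that("sampled helix lengths stay in the configured 15-19 window", {
  set.seed(5)
  cfg <- SamplingConfig()
  lens <- integer(0)
  for (i in 1:200) {
    cand <- sampleCandidate(cfg)
    prov <- if (inherits(cand, "grooveRejection")) cand$provenance else cand@provenance
    lens <- c(lens, prov$lengths)
  }
  expect_true(all(lens %in% 15:19))
  expect_setequal(unique(lens), 15:19)
})

test_that("degenerate per-helix Gaussian pins all distances to the sampled average", {
  set.seed(9)
  cfg <- SamplingConfig(perHelixDistSD = 0)
  for (i in 1:10) {
    cand <- sampleCandidate(cfg)
    prov <- if (inherits(cand, "grooveRejection")) cand$provenance else cand@provenance
    expect_lt(max(abs(prov$helix_dists - prov$avg_neighbor_dist)), 1e-6)
  }
})

test_that("library sampling is deterministic under a fixed seed", {
  lib1 <- sampleLibrary(4, SamplingConfig(seed = 11))
  lib2 <- sampleLibrary(4, SamplingConfig(seed = 11))
  expect_identical(provenanceTable(lib1), provenanceTable(lib2))
  expect_identical(lib1$rejections, lib2$rejections)
  coordsOf <- function(lib) lapply(lib$candidates, function(x) lapply(x@chains, caCoords))
  expect_identical(coordsOf(lib1), coordsOf(lib2))
})

test_that("empty library request returns no candidates", {
  lib <- sampleLibrary(0, SamplingConfig(seed = 3))
  expect_length(lib$candidates, 0)
})

test_that("sampled average neighbour distances track the configured Gaussian", {
  set.seed(2)
  cfg <- SamplingConfig()
  avgs <- replicate(400, {
    cand <- sampleCandidate(cfg)
    prov <- if (inherits(cand, "grooveRejection")) cand$provenance else cand@provenance
    prov$avg_neighbor_dist
  })
  se <- 0.7 / sqrt(length(avgs))
  expect_lt(abs(mean(avgs) - 9.5), 3 * se)
})

test_that("biased supercoil sampling stochastically dominates the uniform law", {
  set.seed(7)
  cfg <- SamplingConfig()
  biased <- sampleSupercoil(2000, cfg)
  unif <- runif(2000, 0, 6)
  expect_true(all(biased >= 0 & biased <= 6))
  p <- wilcox.test(biased, unif, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("accepted scaffolds leave the groove face solvent-open and buttresses outside", {
  lib <- sampleLibrary(6, SamplingConfig(seed = 13))
  for (cand in lib$candidates) {
    drift <- cand@provenance$omega0 * (mean(cand@provenance$lengths) - 1) / 2
    for (i in seq_along(cand@chains)) {
      ca <- caCoords(cand@chains[[i]])
      phase <- (atan2(ca[, 2], ca[, 1]) * 180 / pi - drift) %% 360
      rad <- sqrt(ca[, 1]^2 + ca[, 2]^2)
      ## open face: the wedge around phase 0 (between g1 and g3) is clear
      ## within 10 A of the slot axis
      inWedge <- pmin(phase, 360 - phase) < 40
      expect_false(any(inWedge & rad < 10))
    }
    grooveR <- sapply(cand@chains[1:3], function(ch) {
      ca <- caCoords(ch); mean(sqrt(ca[, 1]^2 + ca[, 2]^2))
    })
    buttressR <- sapply(cand@chains[4:5], function(ch) {
      ca <- caCoords(ch); mean(sqrt(ca[, 1]^2 + ca[, 2]^2))
    })
    expect_gt(min(buttressR), max(grooveR))
  }
})

test_that("docking fills the slot without clashes and rejects oversized peptides", {
  lib <- sampleLibrary(3, SamplingConfig(seed = 17))
  cand <- lib$candidates[[1]]
  cx <- dockTarget(cand, polySeq("A", 17))
  dmins <- sapply(cx@scaffold, function(ch) {
    A <- caCoords(cx@slotHelix); B <- caCoords(ch)
    sqrt(min(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  })
  expect_gte(min(dmins), 4)
  expect_lte(min(dmins), 12)
  expect_error(dockTarget(cand, polySeq("A", 34)), "slot length")
})
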