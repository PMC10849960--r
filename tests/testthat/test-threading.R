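## a small docked complex shared across threading tests
threadFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lib <- sampleLibrary(1, SamplingConfig(seed = 23, slotLength = 25L))
      cache <<- dockTarget(lib$candidates[[1]], polySeq("A", 25))
    }
    cache
  }
})

test_that("threading enumeration covers every register and both orientations", {
  cx <- threadFixture()
  th <- enumerateThreadings(cx, polySeq("L", 20))
  expect_length(th, (25 - 20 + 1) * 2)
  keys <- sapply(th, function(t) paste(t@offset, t@orientation))
  expect_length(unique(keys), length(th))
  expect_setequal(sapply(th, function(t) t@offset), 0:5)
  ## full-length peptide: just the two orientations
  expect_length(enumerateThreadings(cx, polySeq("L", 25)), 2)
  expect_error(enumerateThreadings(cx, polySeq("L", 30)), "exceeds slot length")
})

test_that("hydrophobic contact counting respects residue identity and geometry", {
  cx <- threadFixture()
  th <- enumerateThreadings(cx, polySeq("G", 20))[[1]]
  expect_identical(hydrophobicContactCount(th), 0L)
  thL <- enumerateThreadings(cx, polySeq("L", 20))[[1]]
  nL <- hydrophobicContactCount(thL)
  expect_lte(nL, 20)
  ## count never exceeds the number of hydrophobic residues in the peptide
  mixed <- "LLGGSSDDEEKKRRNNQQPP"
  thM <- enumerateThreadings(cx, mixed)[[1]]
  expect_lte(hydrophobicContactCount(thM), 2)
  ## monotone non-decreasing in the cutoff
  counts <- sapply(c(4, 6, 8, 10, 14), function(cut) hydrophobicContactCount(thL, cut))
  expect_true(all(diff(counts) >= 0))
})

test_that("a hand-built geometry yields exactly the planted contact count", {
  ## slot helix along z; one short scaffold helix close to the slot's lower
  ## third only, so only the first Leu block is in contact
  slot <- generateHelix(CrickParams(length = 18), chain = "S")
  scaf <- transformChain(generateHelix(CrickParams(length = 6)), t = c(7, 0, 0))
  cx <- new("HelixComplex", scaffold = list(scaf), slotHelix = slot,
            slotSequence = NA_character_)
  pep <- paste0("LLL", polySeq("S", 15))
  th <- enumerateThreadings(cx, pep)[[1]]  # offset 0, parallel
  expect_identical(th@offset, 0L)
  ## independent brute-force: which peptide positions are Leu AND have CB
  ## proxies within cutoff of any scaffold CB proxy
  cutoff <- 8
  slotCB <- buildCBProxy(slot)
  scafCB <- buildCBProxy(scaf)
  d <- sqrt(outer(rowSums(slotCB^2), rowSums(scafCB^2), "+") - 2 * slotCB %*% t(scafCB))
  inContact <- apply(d, 1, min) <= cutoff
  planted <- sum(inContact[1:3])
  expect_identical(hydrophobicContactCount(th, cutoff), as.integer(planted))
  expect_gt(planted, 0)
})

test_that("orientation flip of a uniform poly-Leu peptide preserves the count", {
  cx <- threadFixture()
  ths <- enumerateThreadings(cx, polySeq("L", 25))
  expect_identical(hydrophobicContactCount(ths[[1]]), hydrophobicContactCount(ths[[2]]))
})

test_that("threading filter ranks by count with documented tie-breaking", {
  cx <- threadFixture()
  ths <- enumerateThreadings(cx, "LLGGLLAAVVGGSSLLIIFF")
  ranked <- filterThreadings(ths, minHydrophobic = 0)
  counts <- attr(ranked, "counts")
  expect_length(ranked, length(ths))       # threshold 0 keeps everything
  expect_true(all(diff(counts) <= 0))      # descending
  ## top element equals the brute-force argmax
  ref <- sapply(ths, hydrophobicContactCount)
  expect_identical(counts[1], max(ref))
  ## ties: offset ascending, then parallel before antiparallel
  top <- which(ref == max(ref))
  offs <- sapply(ths[top], function(t) t@offset)
  expect_identical(ranked[[1]]@offset, as.integer(min(offs)))
  ## threshold above peptide length empties the list
  expect_length(filterThreadings(ths, minHydrophobic = 21), 0)
})
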