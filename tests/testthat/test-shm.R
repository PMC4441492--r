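## independent regex-based motif oracle scanning both strands
motifOracle <- function(reference, position) {
  pad <- paste0("NN", reference, "NN")
  ctx <- substr(pad, position, position + 4)     # 5-mer centered on position
  refBase <- substr(ctx, 3, 3)
  rcCtx <- revCompOracle(ctx)
  hasW <- function(x, i) substr(x, i, i) %in% c("A", "T")
  if (refBase == "C" && grepl("^[AT][AG]C[CT].$", ctx)) return("hotspot_WRCY")
  if (refBase == "G" && grepl("^[AT][AG]C[CT].$", rcCtx)) return("hotspot_RGYW")
  if (refBase == "A" && hasW(ctx, 2)) return("hotspot_WA")
  if (refBase == "T" && hasW(ctx, 4)) return("hotspot_TW")
  if (refBase == "C" && grepl("^[GC][CT]C..$", substr(pad, position, position + 4)))
    return("coldspot")
  if (refBase == "G" && grepl("^..G[AG][GC]$", ctx)) return("coldspot")
  "none"
}

test_that("hotspot motif classes agree with a regex oracle over both strands", {
  set.seed(401)
  ref <- randDNA(800)
  got <- vapply(1:800, function(p) motifClass(ref, p), character(1))
  want <- vapply(1:800, function(p) motifOracle(ref, p), character(1))
  expect_identical(got, want)
  ## strand symmetry: the C of AGCT (WRCY) and the G of its complement
  expect_identical(motifClass("AAGCTA", 4), "hotspot_WRCY")
  expect_identical(motifClass(revCompOracle("AAGCTA"), 3), "hotspot_RGYW")
})

test_that("a clone identical to the reference yields no calls", {
  ref <- randDNA(300, seed = 402)
  r <- callCloneMutations(ref, ref, "c0")
  expect_identical(nrow(r$calls), 0L)
  expect_identical(nrow(r$indels), 0L)
  expect_true(r$alignable)
})

test_that("a C>T mutation inside an AGCT core is called as a WRCY hotspot", {
  set.seed(403)
  left <- randDNA(140)
  ref <- paste0(left, "AAGCTA", randDNA(140))
  clone <- ref
  pos <- 140L + 4L   # the C of AAGCTA
  expect_identical(substr(ref, pos, pos), "C")
  substr(clone, pos, pos) <- "T"
  r <- callCloneMutations(clone, ref, "c1")
  expect_identical(nrow(r$calls), 1L)
  expect_identical(r$calls$position, pos)
  expect_identical(r$calls$refBase, "C")
  expect_identical(r$calls$altBase, "T")
  expect_identical(r$calls$motifClass, "hotspot_WRCY")
  expect_identical(r$calls$motifClass, motifOracle(ref, pos))
})

test_that("deletions are separated from substitutions in hand-constructed clones", {
  ref <- randDNA(300, seed = 404)
  clone <- ref
  substr(clone, 50, 50) <- if (substr(ref, 50, 50) == "A") "G" else "A"
  substr(clone, 200, 200) <- if (substr(ref, 200, 200) == "C") "T" else "C"
  clone <- paste0(substr(clone, 1, 119), substr(clone, 123, 300))  # 3-nt deletion
  r <- callCloneMutations(clone, ref, "c2")
  expect_identical(nrow(r$calls), 2L)
  expect_identical(sort(r$calls$position), c(50L, 200L))
  expect_identical(nrow(r$indels), 1L)
  expect_identical(r$indels$type, "deletion")
  expect_identical(r$indels$length, 3L)
})

test_that("unalignable clones are flagged and excluded, not fatal", {
  ref <- randDNA(300, seed = 405)
  junk <- randDNA(300)
  r <- callCloneMutations(junk, ref, "junk")
  expect_false(r$alignable)
  prof <- profileClones(c(good = ref, bad = junk), ref)
  expect_identical(prof$excluded, "bad")
  expect_identical(prof$nClones, 1L)
})

test_that("spectra tally the twelve substitution classes, Tr/Tv and F correctly", {
  ## one call in every off-diagonal class
  bases <- c("A", "C", "G", "T")
  calls <- do.call(rbind, lapply(bases, function(r) do.call(rbind, lapply(
    setdiff(bases, r), function(a)
      data.frame(cloneId = "x", position = 1L, refBase = r, altBase = a,
                 context = "NNNNN", motifClass = "none", gapAdjacent = FALSE)))))
  sp <- buildSpectrum(calls, nSequences = 12L, analyzedLen = 100L)
  expect_true(all(sp@subCounts[row(sp@subCounts) != col(sp@subCounts)] == 1L))
  expect_identical(sp@transitions, 4L)
  expect_identical(sp@transversions, 8L)
  expect_identical(sp@atFraction, 0.5)
  ## 25 mutations over 10 clones x 500 bp -> F = 5e-3
  c25 <- calls[rep(1, 25), ]
  expect_identical(frequencyPerBp(buildSpectrum(c25, 10L, 500L)), 5e-3)
  ## empty spectrum
  sp0 <- buildSpectrum(calls[0, ], 5L, 100L)
  expect_identical(sum(sp0@subCounts), 0L)
  expect_identical(frequencyPerBp(sp0), 0)
})

test_that("positional distribution sums to 100 percent and matches a hand histogram", {
  one <- data.frame(position = rep(1L, 7))
  d1 <- positionalDistribution(one, referenceLen = 50)
  expect_identical(d1[1], 100)
  expect_identical(sum(d1), 100)
  unif <- data.frame(position = 1:10)
  expect_true(all(positionalDistribution(unif, 10) == 10))
  set.seed(406)
  pos <- sample(1:200, 60, replace = TRUE)
  d <- positionalDistribution(data.frame(position = pos), 200)
  expect_equal(d, 100 * tabulate(pos, 200) / 60)
  expect_error(positionalDistribution(one[0, , drop = FALSE], 50), "no mutation")
})

test_that("spectrum comparison: identical spectra give chi2 0 / p 1; shifts are detected", {
  set.seed(407)
  mkCalls <- function(n, boost = NULL) {
    bases <- c("A", "C", "G", "T")
    r <- sample(bases, n, replace = TRUE)
    a <- vapply(r, function(b) sample(setdiff(bases, b), 1), character(1))
    if (!is.null(boost)) { r[1:80] <- boost[1]; a[1:80] <- boost[2] }
    data.frame(cloneId = "x", position = 1L, refBase = r, altBase = a,
               context = "NNNNN", motifClass = "none", gapAdjacent = FALSE)
  }
  a <- buildSpectrum(mkCalls(300), 30L, 500L)
  cmpSame <- compareSpectra(a, a)
  expect_identical(cmpSame$chisq$statistic, 0)
  expect_identical(cmpSame$chisq$p, 1)
  b <- buildSpectrum(mkCalls(300, boost = c("C", "T")), 30L, 500L)
  expect_lt(compareSpectra(a, b)$chisq$p, 0.05)
  ## indel 2x2 with identical margins -> Fisher p = 1
  a@insertionCount <- 5L; b2 <- a
  expect_identical(compareSpectra(a, b2)$fisher$p, 1)
})

test_that("clone collapsing removes clonally related duplicates only when asked", {
  ref <- randDNA(200, seed = 408)
  clone <- ref
  substr(clone, 77, 77) <- if (substr(ref, 77, 77) == "A") "C" else "A"
  clones <- c(a = clone, b = clone, c = ref)
  expect_identical(profileClones(clones, ref)$nClones, 3L)
  expect_identical(profileClones(clones, ref, collapseClones = TRUE)$nClones, 2L)
})
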