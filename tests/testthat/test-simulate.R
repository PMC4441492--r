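test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  cfg <- simJunctionConfig(seed = 601, nReads = 15)
  refs1 <- makeReference(cfg)
  refs2 <- makeReference(cfg)
  expect_identical(donorRegion(refs1), donorRegion(refs2))
  expect_identical(acceptorRegion(refs1), acceptorRegion(refs2))
  s1 <- simulateJunctions(cfg, refs1)
  s2 <- simulateJunctions(cfg, refs2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truthTable, s2$truthTable)
  cfgB <- simJunctionConfig(seed = 602, nReads = 15)
  refsB <- makeReference(cfgB)
  expect_false(identical(donorRegion(refs1), donorRegion(refsB)))
  expect_false(identical(s1$reads, simulateJunctions(cfgB, refsB)$reads))
})

test_that("with repeatDensity 0 the two regions share no long substring", {
  cfg <- simJunctionConfig(seed = 603, repeatDensity = 0, refLength = 1200)
  refs <- makeReference(cfg)
  D <- donorRegion(refs); A <- acceptorRegion(refs)
  k <- 20L
  kmers <- function(s) {
    n <- nchar(s)
    unique(vapply(1:(n - k + 1L), function(i) substr(s, i, i + k - 1L), character(1)))
  }
  expect_identical(length(intersect(kmers(D), kmers(A))), 0L)
  ## no tandem motif enrichment: each configured motif appears about as often
  ## as the background expectation (length / 4^5), never in long runs
  for (motif in cfg$repeatMotifs) {
    runs <- gregexpr(strrep(motif, 3), D, fixed = TRUE)[[1]]
    expect_identical(runs[1], -1L)
  }
})

test_that("planted seams agree with a string-walking homology oracle", {
  ## microhomology-only at fixed lengths spanning the configured range
  for (L in c(1L, 4L, 9L, 15L, 22L)) {
    cfg <- simJunctionConfig(seed = 610 + L, nReads = 8,
                             boundaryMix = c(blunt = 0, microhomology = 1,
                                             insertion = 0),
                             mhLenDist = "uniform", mhLenMax = L,
                             compoundFraction = 0)
    refs <- makeReference(cfg)
    sim <- simulateJunctions(cfg, refs)
    for (id in names(sim$truth)) {
      tr <- sim$truth[[id]]
      expect_identical(tr$boundaries$kind, "microhomology")
      expect_identical(truthRealizedOL(refs, tr), tr$boundaries$OL)
      expect_lte(tr$boundaries$OL, L)
    }
  }
})

test_that("blunt-only seams realize exactly zero homology", {
  cfg <- simJunctionConfig(seed = 620, nReads = 25,
                           boundaryMix = c(blunt = 1, microhomology = 0,
                                           insertion = 0),
                           compoundFraction = 0)
  refs <- makeReference(cfg)
  sim <- simulateJunctions(cfg, refs)
  expect_true(all(sim$truthTable$kind == "blunt"))
  for (id in names(sim$truth))
    expect_identical(truthRealizedOL(refs, sim$truth[[id]]), 0L)
})

test_that("insertion seams carry novel bases matching neither continuation", {
  cfg <- simJunctionConfig(seed = 630, nReads = 20,
                           boundaryMix = c(blunt = 0, microhomology = 0,
                                           insertion = 1),
                           insLenRange = c(2L, 8L), compoundFraction = 0)
  refs <- makeReference(cfg)
  sim <- simulateJunctions(cfg, refs)
  for (id in names(sim$truth)) {
    tr <- sim$truth[[id]]
    b <- tr$boundaries
    expect_identical(b$kind, "insertion")
    ins <- b$insertionSeq
    expect_gte(nchar(ins), 2L)
    expect_lte(nchar(ins), 8L)
    ## the insertion really sits in the read at the recorded seam position
    expect_identical(substr(tr$read, b$seamPos, b$seamPos + nchar(ins) - 1L), ins)
    ## first base differs from the donor continuation, last from the acceptor
    ## base preceding the resumption point
    a <- truthSeamAnchors(refs, tr$fragments[1, ], tr$fragments[2, ])
    expect_false(substr(ins, 1, 1) == substr(a$SL, a$iL + 1L, a$iL + 1L))
    expect_false(substr(ins, nchar(ins), nchar(ins)) ==
                   substr(a$SR, a$jR - 1L, a$jR - 1L))
    ## and the flanks realize zero homology
    expect_identical(bruteSeamOL(a$SL, a$iL, a$SR, a$jR) >= 0L, TRUE)
  }
})

test_that("compound architectures plant the requested event types", {
  cfg <- simJunctionConfig(seed = 640, nReads = 15, compoundFraction = 1,
                           eventMix = c(intra_donor = 0, intra_acceptor = 0,
                                        inversion = 1, microdeletion = 0))
  refs <- makeReference(cfg)
  sim <- simulateJunctions(cfg, refs)
  for (id in names(sim$truth)) {
    tr <- sim$truth[[id]]
    expect_identical(nrow(tr$fragments), 3L)
    expect_true("-" %in% tr$fragments$strand)
    expect_true("inversion" %in% tr$events)
  }
  cfgMd <- simJunctionConfig(seed = 641, nReads = 15, compoundFraction = 1,
                             eventMix = c(intra_donor = 0, intra_acceptor = 0,
                                          inversion = 0, microdeletion = 1))
  refsMd <- makeReference(cfgMd)
  simMd <- simulateJunctions(cfgMd, refsMd)
  for (id in names(simMd$truth)) {
    tr <- simMd$truth[[id]]
    expect_true("microdeletion" %in% tr$events)
    expect_true(tr$gap >= 5L && tr$gap <= 50L)
    ## the same-region reference gap equals the recorded gap
    fr <- tr$fragments
    expect_identical(fr$rstart[2] - fr$rend[1], as.integer(tr$gap))
  }
})

test_that("mutated reads record the planted mutation count away from seams", {
  cfg <- simJunctionConfig(seed = 650, nReads = 10, mutationRate = 0.02)
  refs <- makeReference(cfg)
  sim <- simulateJunctions(cfg, refs)
  expect_true(any(sim$truthTable$nMutations > 0))
  cfg0 <- simJunctionConfig(seed = 650, nReads = 10, mutationRate = 0)
  sim0 <- simulateJunctions(cfg0, makeReference(cfg0))
  expect_true(all(sim0$truthTable$nMutations == 0))
})

test_that("SHM simulator: zero target frequency leaves every clone germline", {
  cfg <- simSHMConfig(seed = 660, nClones = 10, targetFrequency = 0)
  sim <- simulateSHMClones(cfg)
  expect_true(all(sim$clones == sim$reference))
  expect_identical(nrow(sim$truth), 0L)
  expect_identical(nrow(sim$indelTruth), 0L)
})

test_that("SHM simulator hits the target frequency and responds to hotspot bias", {
  cfg <- simSHMConfig(seed = 661, nClones = 150, refLength = 600,
                      targetFrequency = 8e-3, hotspotBias = 1)
  sim <- simulateSHMClones(cfg)
  nBases <- cfg$nClones * cfg$refLength
  f <- nrow(sim$truth) / nBases
  se <- sqrt(8e-3 * (1 - 8e-3) / nBases)
  expect_lt(abs(f - 8e-3), 4 * se)
  ## stronger hotspot bias concentrates mutations in RGYW/WRCY positions
  hotFrac <- function(bias) {
    cfgB <- simSHMConfig(seed = 662, nClones = 150, refLength = 600,
                         targetFrequency = 8e-3, hotspotBias = bias)
    s <- simulateSHMClones(cfgB)
    mean(s$truth$motifClass %in% c("hotspot_RGYW", "hotspot_WRCY"))
  }
  expect_gt(hotFrac(8), hotFrac(1) + 0.1)
})

test_that("SHM profiling recovers the planted mutations exactly on indel-free clones", {
  cfg <- simSHMConfig(seed = 663, nClones = 25, refLength = 400,
                      targetFrequency = 6e-3, indelRate = 0)
  sim <- simulateSHMClones(cfg)
  prof <- profileClones(sim$clones, sim$reference)
  got <- prof$calls[order(prof$calls$cloneId, prof$calls$position),
                    c("cloneId", "position", "refBase", "altBase")]
  want <- sim$truth[order(sim$truth$clone, sim$truth$position),
                    c("clone", "position", "refBase", "altBase")]
  rownames(got) <- rownames(want) <- NULL
  names(want)[1] <- "cloneId"
  expect_identical(got, want)
  ## indel counts are recovered when indels are planted
  cfgI <- simSHMConfig(seed = 664, nClones = 30, refLength = 400,
                       targetFrequency = 4e-3, indelRate = 0.002)
  simI <- simulateSHMClones(cfgI)
  profI <- profileClones(simI$clones, simI$reference)
  expect_identical(nrow(profI$indels), nrow(simI$indelTruth))
})
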