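## seam fixture: donor ends ...AGGCT, acceptor begins GCTTA..., read carries
## AGGCTTA across the junction -> the longest stretch matching both germline
## continuations is GCT (OL = 3)
makeMhFixture <- function() {
  set.seed(101)
  dFlank <- paste0(randDNA(119), "C")          # pinned seam-adjacent bases keep
  donor <- paste0(dFlank, "AGGCT", "AAACAATAGACCA", randDNA(60))
  aFlank <- randDNA(110)
  acceptor <- paste0(randDNA(70), "CACCATTGCAATT", "GCTTA", aFlank)
  read <- paste0(dFlank, "AGGCTTA", aFlank)    # ...AGG[GCT shared]TA...
  list(refs = tinyRefs(donor, acceptor), read = read)
}

test_that("microhomology boundary: OL equals the longest shared perfect window", {
  fx <- makeMhFixture()
  call <- segmentJunction(fx$read, fx$refs, readId = "mh3")
  expect_true(call@callable)
  expect_identical(nrow(call@fragments), 2L)
  b <- call@boundaries
  expect_identical(b$kind, "microhomology")
  expect_identical(b$overlapLen, 3L)
  ## the window is the GCT straddling the seam
  expect_identical(substr(call@read, b$qWinStart + 1L, b$qWinEnd), "GCT")
  ## breakpoint coordinates bracket the ambiguity window
  expect_identical(b$leftBreakRef, 1000L + 120L + 5L - 1L)   # last donor base of AGGCT
  expect_identical(b$rightBreakRef, 5000L + 70L + 13L)       # first acceptor base of GCTTA
})

test_that("blunt and insertion boundaries are told apart at the seam", {
  set.seed(102)
  dFlank <- paste0(randDNA(99), "A")
  aFlank <- randDNA(100)
  donor <- paste0(dFlank, "CCCGGATTACA", randDNA(40))
  acceptor <- paste0(randDNA(39), "C", "TTGACCA", aFlank)
  refs <- tinyRefs(donor, acceptor)
  ## blunt: donor continuation after flank is C..., acceptor before start is A
  bluntRead <- paste0(dFlank, "TTGACCA", aFlank)
  cb <- segmentJunction(bluntRead, refs, readId = "blunt")
  expect_identical(cb@boundaries$kind, "blunt")
  expect_identical(cb@boundaries$overlapLen, 0L)
  expect_identical(cb@boundaries$insertionSeq, "")
  ## insertion: lower-case novel bases at the seam match neither reference
  insRead <- paste0(dFlank, "tt", "TTGACCA", aFlank)
  ci <- segmentJunction(insRead, refs, readId = "ins")
  expect_identical(ci@boundaries$kind, "insertion")
  expect_identical(ci@boundaries$insertionSeq, "TT")
  expect_identical(ci@boundaries$overlapLen, 0L)
})

test_that("OL is placement-invariant: nudging the nominal fragment ends never changes the call", {
  fx <- makeMhFixture()
  call <- segmentJunction(fx$read, fx$refs, readId = "mh3")
  left <- call@fragments[1, ]
  right <- call@fragments[2, ]
  base <- resolveBoundary(call@read, left, right, fx$refs)
  for (shift in -3:3) {
    l2 <- left; r2 <- right
    l2$qend <- l2$qend + shift; l2$rend <- l2$rend + shift
    r2$qstart <- r2$qstart - shift; r2$rstart <- r2$rstart - shift
    b2 <- resolveBoundary(call@read, l2, r2, fx$refs)
    expect_identical(b2$kind, base$kind)
    expect_identical(b2$overlapLen, base$overlapLen)
    expect_identical(b2$insertionSeq, base$insertionSeq)
  }
})

test_that("degenerate boundaries (same match twice) are rejected", {
  fx <- makeMhFixture()
  call <- segmentJunction(fx$read, fx$refs)
  expect_error(resolveBoundary(call@read, call@fragments[1, ], call@fragments[1, ]),
               "degenerate")
})

test_that("two- and three-fragment architectures are reconstructed from coordinates", {
  cfg <- simJunctionConfig(seed = 77, nReads = 1)
  refs <- makeReference(cfg)
  D <- donorRegion(refs); A <- acceptorRegion(refs)
  ## donor[1:300] + acceptor[101:400], clean
  read2 <- paste0(substr(D, 1, 300), substr(A, 101, 400))
  c2 <- segmentJunction(read2, refs, readId = "two")
  expect_true(c2@callable)
  expect_identical(nrow(c2@fragments), 2L)
  expect_identical(c2@fragments$region, c("Smu", "Sg1"))
  ## donor[1:200] + donor[901:1100] + acceptor[101:300]
  read3 <- paste0(substr(D, 1, 200), substr(D, 901, 1100), substr(A, 101, 300))
  c3 <- segmentJunction(read3, refs, readId = "three")
  expect_true(c3@callable)
  expect_identical(nrow(c3@fragments), 3L)
  expect_identical(nrow(c3@boundaries), 2L)
  expect_identical(c3@fragments$region, c("Smu", "Smu", "Sg1"))
  ## pure donor sequence is uncallable, carrying partial matches
  cd <- segmentJunction(substr(D, 1, 400), refs, readId = "donorOnly")
  expect_false(cd@callable)
  expect_true(nrow(cd@fragments) >= 1L)
})

test_that("reads are tried in both orientations; donor-forward-first wins", {
  cfg <- simJunctionConfig(seed = 78, nReads = 10)
  refs <- makeReference(cfg)
  sim <- simulateJunctions(cfg, refs)
  for (id in names(sim$reads)[1:5]) {
    fwd <- segmentJunction(sim$reads[[id]], refs, readId = id)
    rev <- segmentJunction(revCompOracle(sim$reads[[id]]), refs, readId = id)
    expect_true(rev@orientationFlipped)
    expect_identical(rev@boundaries$kind, fwd@boundaries$kind)
    expect_identical(rev@boundaries$overlapLen, fwd@boundaries$overlapLen)
    expect_identical(rev@fragments$region, fwd@fragments$region)
  }
})

test_that("dedup removes exact duplicates but keeps junction-identical reads that differ elsewhere", {
  x <- "ACGTACGTAAGGTTCC"
  y <- "TTTTACGTAAGGAAAA"
  expect_identical(dedupReads(c(x, x, y)), c(x, y))
  expect_identical(dedupReads(character(0)), character(0))
  ## same 8-nt junction core, different flanks: both retained
  core <- "ACGTAAGG"
  a <- paste0("GGGG", core, "CCCC")
  b <- paste0("TTTT", core, "AAAA")
  expect_identical(length(dedupReads(c(a, b))), 2L)
  ds <- Biostrings::DNAStringSet(c(r1 = x, r2 = x, r3 = y))
  expect_identical(length(dedupReads(ds)), 2L)
})
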