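## Independent oracles and fixture builders shared across the test files.
## These deliberately avoid every code path of the implementation they check:
## character-map reverse complement, string-walking seam homology, exhaustive
## diagonal scans, choose()-based hypergeometric tails.

## reverse complement by character map, independent of Biostrings
revCompOracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

## brute-force realized seam homology: read = ...SL[..iL] + (ins) + SR[jR..]...
## walk outward from the seam; shared suffix + shared prefix (all 1-based)
bruteSeamOL <- function(SL, iL, SR, jR) {
  k <- 0L
  while (iL - k >= 1L && jR - 1L - k >= 1L &&
         substr(SL, iL - k, iL - k) == substr(SR, jR - 1L - k, jR - 1L - k))
    k <- k + 1L
  f <- 0L
  while (iL + 1L + f <= nchar(SL) && jR + f <= nchar(SR) &&
         substr(SL, iL + 1L + f, iL + 1L + f) == substr(SR, jR + f, jR + f))
    f <- f + 1L
  k + f
}

## oriented sequence of a truth fragment (forward 0-based half-open coords)
orientedTruthSeq <- function(refs, frag) {
  s <- regionSequence(refs, frag$region)
  if (frag$strand == "-") s <- revCompOracle(s)
  s
}

## truth fragment's oriented end/start positions (1-based) for bruteSeamOL
truthSeamAnchors <- function(refs, fragLeft, fragRight) {
  sL <- orientedTruthSeq(refs, fragLeft)
  sR <- orientedTruthSeq(refs, fragRight)
  lenL <- nchar(regionSequence(refs, fragLeft$region))
  lenR <- nchar(regionSequence(refs, fragRight$region))
  iL <- if (fragLeft$strand == "+") fragLeft$rend else lenL - fragLeft$rstart
  jR <- if (fragRight$strand == "+") fragRight$rstart + 1L else lenR - fragRight$rend + 1L
  list(SL = sL, iL = iL, SR = sR, jR = jR)
}

## realized OL at a simulated read's inter-switch seam, from truth only
truthRealizedOL <- function(refs, truthRead) {
  fr <- truthRead$fragments
  k <- which(truthRead$boundaries$interSwitch)[1]
  a <- truthSeamAnchors(refs, fr[k, ], fr[k + 1L, ])
  bruteSeamOL(a$SL, a$iL, a$SR, a$jR)
}

## exhaustive gap-free diagonal scan of a read against a small target:
## returns, per diagonal, mismatch count of the full-read window (read must
## fit inside the target for that diagonal)
exhaustiveScan <- function(read, target) {
  nq <- nchar(read); nr <- nchar(target)
  rc <- strsplit(read, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  out <- data.frame(rstart = integer(0), mismatches = integer(0))
  for (r0 in 0:(nr - nq)) {
    mm <- sum(rc != tc[(r0 + 1L):(r0 + nq)])
    out <- rbind(out, data.frame(rstart = r0, mismatches = mm))
  }
  out
}

## exact two-tailed Fisher p by full enumeration with choose() arithmetic
fisherEnumOracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(c1, r1)
  k <- lo:hi
  pk <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  pObs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(pk[pk <= pObs * (1 + 1e-7)]))
}

## hand-constructed JunctionCall fixture: fragments laid left to right on an
## implied read; reference intervals are forward-strand 0-based half-open
fixtureCall <- function(readId, regions, strands, rstarts, rends,
                        kinds = NULL, ols = NULL, inss = NULL) {
  nf <- length(regions)
  lens <- rends - rstarts
  qstart <- cumsum(c(0L, head(lens, -1L)))
  qend <- qstart + lens
  frs <- data.frame(qstart = as.integer(qstart), qend = as.integer(qend),
                    rstart = as.integer(rstarts), rend = as.integer(rends),
                    strand = strands, mismatches = 0L,
                    score = as.integer(lens), region = regions)
  nb <- nf - 1L
  if (is.null(kinds)) kinds <- rep("blunt", nb)
  if (is.null(ols)) ols <- rep(0L, nb)
  if (is.null(inss)) inss <- rep("", nb)
  bnds <- data.frame(kind = kinds, overlapLen = as.integer(ols),
                     insertionSeq = inss,
                     leftBreakRef = as.integer(rends[seq_len(nb)]),
                     rightBreakRef = as.integer(rstarts[-1] + 1L),
                     qWinStart = as.integer(qend[seq_len(nb)]),
                     qWinEnd = as.integer(qend[seq_len(nb)] + ols))
  methods::new("JunctionCall", readId = readId,
               read = strrep("A", sum(lens)), callable = TRUE,
               fragments = frs, boundaries = bnds,
               unassignedPrefix = 0L, unassignedSuffix = 0L,
               orientationFlipped = FALSE)
}

## tiny two-region reference set around explicit seam sequences
tinyRefs <- function(donor, acceptor, donorOffset = 1000L, acceptorOffset = 5000L) {
  switchRegionSet(c(Smu = donor, Sg1 = acceptor), "Smu", "Sg1",
                  genomicOffset = c(Smu = donorOffset, Sg1 = acceptorOffset))
}

## deterministic random DNA for fixture construction
randDNA <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
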