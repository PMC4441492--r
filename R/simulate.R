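## Synthetic references, junction reads and SHM clone sets with exact ground
## truth. The critical correctness trap: naive concatenation of reference
## fragments can create accidental seam homology longer than the planted
## overlap in repeat-rich sequence. Every seam is therefore realized by
## rejection sampling (bounded attempts) so that the REALIZED maximal perfect
## homology equals the planted value, and mutations are kept out of a
## protected window around each seam.

.randBases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Configuration for the junction simulator
#'
#' The defaults describe a wild-type-like cohort: mostly blunt and short-
#' microhomology inter-switch boundaries, a modest compound fraction, and
#' switch-region-like pentamer repeats in the references.
#'
#' @param seed integer RNG seed; a fixed seed makes all outputs byte-identical.
#' @param nReads number of reads to simulate.
#' @param refLength reference length per region (>= 200 nt).
#' @param repeatMotifs short motifs planted in tandem runs (switch-region-like
#'   pentamers by default); both regions draw from the same pool, which is
#'   what makes long seam microhomology realizable.
#' @param repeatDensity probability that the next reference block is a tandem
#'   motif run rather than random background (0 = plain random sequence).
#' @param boundaryMix probabilities over blunt / microhomology / insertion at
#'   the inter-switch boundary; must sum to 1.
#' @param mhLenGeomP,mhLenMax microhomology lengths are sampled from a
#'   geometric distribution (success probability `mhLenGeomP`) truncated to
#'   `1..mhLenMax`.
#' @param mhLenDist `"geometric"` (realistic decay) or `"uniform"` over
#'   `1..mhLenMax` (stress coverage of every overlap length).
#' @param insLenRange inclusive range of insertion lengths.
#' @param compoundFraction probability that a read carries an additional
#'   intra-switch event.
#' @param eventMix probabilities over intra_donor / intra_acceptor /
#'   inversion / microdeletion for compound reads; must sum to 1.
#' @param mutationRate per-base substitution probability applied outside a
#'   protected seam window of width max(5, OL + 2).
#' @param mutateSeams allow mutations inside the protected seam window
#'   (robustness testing only; default `FALSE`).
#' @param readLengthRange inclusive range of total read lengths.
#' @return validated config list (class `SimJunctionConfig`).
#' @export
simJunctionConfig <- function(seed = 1L, nReads = 100L, refLength = 1500L,
                              repeatMotifs = c("GAGCT", "GGGGT", "AGCTG"),
                              repeatDensity = 0.35,
                              boundaryMix = c(blunt = 0.45, microhomology = 0.40,
                                              insertion = 0.15),
                              mhLenGeomP = 0.45, mhLenMax = 30L,
                              mhLenDist = c("geometric", "uniform"),
                              insLenRange = c(1L, 12L),
                              compoundFraction = 0.15,
                              eventMix = c(intra_donor = 0.35, intra_acceptor = 0.25,
                                           inversion = 0.25, microdeletion = 0.15),
                              mutationRate = 0,
                              mutateSeams = FALSE,
                              readLengthRange = c(280L, 520L)) {
  stopifnot(refLength >= 200L, nReads >= 1L,
            abs(sum(boundaryMix) - 1) < 1e-9,
            all(names(boundaryMix) == c("blunt", "microhomology", "insertion")),
            abs(sum(eventMix) - 1) < 1e-9,
            mutationRate >= 0, mutationRate < 0.5,
            mhLenMax >= 1L, mhLenGeomP > 0, mhLenGeomP <= 1,
            repeatDensity >= 0, repeatDensity <= 1,
            compoundFraction >= 0, compoundFraction <= 1)
  mhLenDist <- match.arg(mhLenDist)
  structure(list(seed = as.integer(seed), nReads = as.integer(nReads),
                 refLength = as.integer(refLength), repeatMotifs = repeatMotifs,
                 repeatDensity = repeatDensity, boundaryMix = boundaryMix,
                 mhLenGeomP = mhLenGeomP, mhLenMax = as.integer(mhLenMax),
                 mhLenDist = mhLenDist,
                 insLenRange = as.integer(insLenRange),
                 compoundFraction = compoundFraction, eventMix = eventMix,
                 mutationRate = mutationRate, mutateSeams = isTRUE(mutateSeams),
                 readLengthRange = as.integer(readLengthRange)),
            class = "SimJunctionConfig")
}

## one synthetic switch-region-like sequence: random background interleaved
## with tandem motif runs
.makeRegionSeq <- function(len, motifs, density) {
  parts <- character(0); tot <- 0L
  while (tot < len) {
    if (length(motifs) && runif(1) < density) {
      m <- motifs[sample.int(length(motifs), 1L)]
      ## occasional long tandem runs are what make long (>= 25 nt) seam
      ## microhomology realizable at all
      copies <- 2L + stats::rpois(1, 2) + (if (runif(1) < 0.12) 6L else 0L)
      p <- strrep(m, min(12L, copies))
    } else {
      p <- .randBases(sample(12:30, 1L))
    }
    parts <- c(parts, p); tot <- tot + nchar(p)
  }
  substr(paste(parts, collapse = ""), 1L, len)
}

#' Generate a synthetic donor/acceptor reference pair
#'
#' Both regions interleave random background with tandem runs of the
#' configured repeat motifs; the shared motif pool stresses overlap-length
#' ambiguity exactly the way real switch-region repeats do. Deterministic
#' under `cfg$seed`.
#'
#' @param cfg a [simJunctionConfig()].
#' @param donorName,acceptorName region names (defaults "Smu", "Sg1").
#' @param genomicOffset named offsets for the two regions.
#' @return a [SwitchRegionSet].
#' @export
makeReference <- function(cfg, donorName = "Smu", acceptorName = "Sg1",
                          genomicOffset = c(10000L, 50000L)) {
  stopifnot(inherits(cfg, "SimJunctionConfig"))
  set.seed(cfg$seed)
  donor <- .makeRegionSeq(cfg$refLength, cfg$repeatMotifs, cfg$repeatDensity)
  acceptor <- .makeRegionSeq(cfg$refLength, cfg$repeatMotifs, cfg$repeatDensity)
  seqs <- setNames(c(donor, acceptor), c(donorName, acceptorName))
  switchRegionSet(seqs, donorName, acceptorName,
                  genomicOffset = setNames(genomicOffset, c(donorName, acceptorName)),
                  accession = setNames(c("synthetic", "synthetic"),
                                       c(donorName, acceptorName)))
}

## ---- seam realization (all coordinates 1-based on oriented sequences) ------

.charAt <- function(s, i) substr(s, i, i)

## all (overlapping) occurrence start positions of word W in string S, 1-based
.allOcc <- function(W, S) {
  out <- integer(0)
  from <- 1L
  n <- nchar(S)
  repeat {
    hit <- regexpr(W, substr(S, from, n), fixed = TRUE)
    if (hit == -1L) break
    p <- from + as.integer(hit) - 1L
    out <- c(out, p)
    from <- p + 1L
  }
  out
}

## realized maximal perfect homology at a seam joining SL[..iL] to SR[jR..]:
## shared suffix before the seam + shared prefix after it
.realizedSeamOL <- function(SL, iL, SR, jR) {
  k <- 0L
  while (iL - k >= 1L && jR - 1L - k >= 1L &&
         .charAt(SL, iL - k) == .charAt(SR, jR - 1L - k)) k <- k + 1L
  f <- 0L
  while (iL + 1L + f <= nchar(SL) && jR + f <= nchar(SR) &&
         .charAt(SL, iL + 1L + f) == .charAt(SR, jR + f)) f <- f + 1L
  k + f
}

## find (iL, jR) with exactly L bases of seam homology
.realizeMH <- function(SL, SR, L, iLrange, jRrange, attempts = 300L) {
  for (t in seq_len(attempts)) {
    iL <- sample(iLrange[1]:iLrange[2], 1L)
    if (iL - L < 1L || iL + 1L > nchar(SL)) next
    word <- substr(SL, iL - L + 1L, iL)
    if (grepl("N", word, fixed = TRUE)) next
    occ <- .allOcc(word, SR)
    if (!length(occ)) next
    jRs <- occ + L     # right fragment starts just after the matched word
    jRs <- jRs[jRs >= max(jRrange[1], L + 2L) & jRs <= jRrange[2]]
    if (!length(jRs)) next
    jRs <- jRs[sample.int(length(jRs))]
    for (jR in jRs) {
      if (.charAt(SL, iL + 1L) == .charAt(SR, jR)) next           # would extend right
      if (iL - L >= 1L && jR - L - 1L >= 1L &&
          .charAt(SL, iL - L) == .charAt(SR, jR - L - 1L)) next   # would extend left
      if (.realizedSeamOL(SL, iL, SR, jR) != L) next
      return(c(iL = iL, jR = jR))
    }
  }
  NULL
}

.realizeBlunt <- function(SL, SR, iLrange, jRrange, attempts = 300L) {
  for (t in seq_len(attempts)) {
    iL <- sample(iLrange[1]:iLrange[2], 1L)
    jR <- sample(jRrange[1]:jRrange[2], 1L)
    if (iL + 1L > nchar(SL) || jR - 1L < 1L) next
    if (.charAt(SL, iL + 1L) == .charAt(SR, jR)) next
    if (.charAt(SL, iL) == .charAt(SR, jR - 1L)) next
    return(c(iL = iL, jR = jR))
  }
  NULL
}

## blunt seam between same-region fragments separated by a fixed-gap jump
.realizeBluntGap <- function(S, iLrange, gapRange, jRmax = nchar(S), attempts = 300L) {
  for (t in seq_len(attempts)) {
    iL <- sample(iLrange[1]:iLrange[2], 1L)
    g <- sample(gapRange[1]:gapRange[2], 1L)
    jR <- iL + g + 1L
    if (jR > jRmax || iL + 1L > nchar(S)) next
    if (.charAt(S, iL + 1L) == .charAt(S, jR)) next
    if (.charAt(S, iL) == .charAt(S, jR - 1L)) next
    return(c(iL = iL, jR = jR, gap = g))
  }
  NULL
}

.realizeInsertionSeq <- function(SL, iL, SR, jR, insLen) {
  ins <- strsplit(.randBases(insLen), "")[[1]]
  forbidFirst <- .charAt(SL, iL + 1L)
  forbidLast <- .charAt(SR, jR - 1L)
  bases <- c("A", "C", "G", "T")
  if (ins[1] == forbidFirst)
    ins[1] <- sample(setdiff(bases, forbidFirst), 1L)
  if (ins[insLen] == forbidLast)
    ins[insLen] <- sample(setdiff(bases, c(forbidLast,
                                           if (insLen == 1L) forbidFirst)), 1L)
  paste(ins, collapse = "")
}

## Seam honesty: the planted boundary must be the unique maximal-parsimony
## explanation of the read. In repeat-rich references the flanking fragment
## can have exact copies elsewhere whose context absorbs planted insertion
## bases or lengthens the apparent homology. We therefore enumerate EVERY
## registration of the 25-nt seam-proximal flank words in their reference
## and take the adversarial maximum of the perfect extensions across the
## seam; the planted kind/OL must survive it.
.seamHonest <- function(readCh, sp, ins, SLch, SRch, kind, L) {
  il <- nchar(ins)
  n <- length(readCh)
  aStart <- sp + il                     # 1-based read pos of first acceptor-side base
  dEnd <- sp - 1L                       # 1-based read pos of last donor-side base
  if (dEnd < 45L || aStart + 45L > n) return(FALSE)
  Pa <- if (kind == "microhomology") aStart - L else aStart

  checkSide <- function(anchor, P, refCh, dir) {
    ## dir = -1: acceptor side, registrations align refCh[o] to read[anchor],
    ## body extends rightward, illegitimate extension goes leftward past P.
    ## dir = +1: donor side, mirrored.
    nr <- length(refCh)
    W <- paste(readCh[if (dir < 0) anchor:(anchor + 24L) else (anchor - 24L):anchor],
               collapse = "")
    occ <- .allOcc(W, paste(refCh, collapse = ""))
    if (!length(occ)) return(NA)
    occ <- if (dir < 0) occ else occ + 24L   # ref position aligned to read[anchor]
    regs <- unique(as.vector(outer(occ, -15L:15L, "+")))
    regs <- regs[regs >= 30L & regs <= nr - 30L]
    plantedBack <- if (dir < 0) anchor - P else P - anchor
    for (o in regs) {
      ## body agreement in the fragment direction
      bl <- if (dir < 0) min(150L, n - anchor + 1L, nr - o + 1L)
            else min(150L, anchor, o)
      ri <- if (dir < 0) anchor:(anchor + bl - 1L) else (anchor - bl + 1L):anchor
      oi <- if (dir < 0) o:(o + bl - 1L) else (o - bl + 1L):o
      deficit <- sum(readCh[ri] != refCh[oi])
      d40 <- sum(readCh[ri[seq_len(min(40L, bl))]] != refCh[oi[seq_len(min(40L, bl))]])
      if (deficit > 12L) next                 # never competitive for the chain
      ## perfect extension from the anchor toward/past the seam
      k <- 0L
      while (TRUE) {
        rp <- if (dir < 0) anchor - k - 1L else anchor + k + 1L
        op <- if (dir < 0) o - k - 1L else o + k + 1L
        if (rp < 1L || rp > n || op < 1L || op > nr) break
        if (readCh[rp] != refCh[op]) break
        k <- k + 1L
      }
      if (deficit <= 2L && k != plantedBack) return(FALSE)
      ## net-positive mismatch-tolerated extension past P (what the aligner
      ## could absorb), charged with the registration's body deficit
      oP <- if (dir < 0) o - (anchor - P) else o + (P - anchor)
      best <- 0L; s <- 0L
      tmax <- if (dir < 0) min(40L, P - 1L, oP - 1L) else min(40L, n - P, nr - oP)
      if (tmax >= 1L) for (t in seq_len(tmax)) {
        rp <- if (dir < 0) P - t else P + t
        op <- if (dir < 0) oP - t else oP + t
        s <- s + (if (readCh[rp] == refCh[op]) 1L else -2L)
        if (s > best) best <- s
      }
      if (best - 3L * d40 > 0L) return(FALSE)
    }
    TRUE
  }
  okA <- checkSide(aStart, Pa, SRch, -1L)
  if (!isTRUE(okA)) return(FALSE)
  okD <- checkSide(dEnd, dEnd, SLch, +1L)
  isTRUE(okD)
}

## oriented sequence for a region/strand
.orientedSeq <- function(refs, region, strand) {
  s <- regionSequence(refs, region)
  if (strand == "-") revComp(s) else s
}

## oriented interval [a, b] (1-based inclusive) -> forward 0-based half-open
.orientedToFwd <- function(len, strand, a, b) {
  if (strand == "+") c(a - 1L, b) else c(len - b, len - a + 1L)
}

#' Simulate junction reads with exact ground truth
#'
#' Each read is a concatenation of reference fragments. The inter-switch
#' boundary kind is drawn from `boundaryMix`; microhomology seams are placed
#' so that the realized maximal perfect homology equals the planted length
#' exactly (rejection-sampled, capped attempts); insertion seams carry novel
#' bases matching neither continuation; intra-switch seams of compound reads
#' are emitted blunt. Point mutations are then applied at `mutationRate`
#' outside a protected window of width max(5, OL + 2) around every seam.
#'
#' @param cfg a [simJunctionConfig()].
#' @param refs a [SwitchRegionSet] (e.g. from [makeReference()]).
#' @return list with `reads` (named character vector), `truth` (list per read:
#'   `fragments` data.frame, `boundaries` data.frame with the planted kind /
#'   OL / insertion per seam plus `interSwitch` flag, `events`, `nMutations`)
#'   and `truthTable` (one-row-per-read summary: `readId`, `architecture`,
#'   `kind`, `OL`, `insertionLen`, `events`, `nFragments`).
#' @export
simulateJunctions <- function(cfg, refs) {
  stopifnot(inherits(cfg, "SimJunctionConfig"))
  set.seed(cfg$seed + 1L)
  dn <- refs@donorName; an <- refs@acceptorName

  orientCh <- list()
  for (rg in c(dn, an)) for (st in c("+", "-"))
    orientCh[[paste0(rg, st)]] <- strsplit(.orientedSeq(refs, rg, st), "")[[1]]

  sampleMH <- function() {
    if (identical(cfg$mhLenDist, "uniform")) sample.int(cfg$mhLenMax, 1L)
    else min(cfg$mhLenMax, 1L + stats::rgeom(1, cfg$mhLenGeomP))
  }
  sampleIns <- function() sample(cfg$insLenRange[1]:cfg$insLenRange[2], 1L)
  kinds <- c("blunt", "microhomology", "insertion")

  buildRead <- function(readId) {
    for (attempt in seq_len(1000L)) {
      compound <- runif(1) < cfg$compoundFraction
      event <- if (compound) sample(names(cfg$eventMix), 1L, prob = cfg$eventMix) else "none"
      plan <- switch(event,
        none = list(c(dn, "+"), c(an, "+")),
        intra_donor = list(c(dn, "+"), c(dn, "+"), c(an, "+")),
        microdeletion = list(c(dn, "+"), c(dn, "+"), c(an, "+")),
        intra_acceptor = list(c(dn, "+"), c(an, "+"), c(an, "+")),
        inversion = list(c(dn, "+"), c(dn, "-"), c(an, "+")))
      nf <- length(plan)
      total <- sample(cfg$readLengthRange[1]:cfg$readLengthRange[2], 1L)
      fragLen <- pmax(90L, as.integer(round(total / nf)))

      interIdx <- which(vapply(seq_len(nf - 1L), function(i)
        plan[[i]][1] == dn && plan[[i + 1L]][1] == an, logical(1)))[1]
      interKind <- sample(kinds, 1L, prob = cfg$boundaryMix)
      L <- if (interKind == "microhomology") sampleMH() else 0L
      insLen <- if (interKind == "insertion") sampleIns() else 0L

      segs <- vector("list", nf)     # per fragment: S, start, end (oriented 1-based)
      bnds <- vector("list", nf - 1L)
      ok <- TRUE
      gapUsed <- NA_integer_
      for (i in seq_len(nf)) {
        S <- .orientedSeq(refs, plan[[i]][1], plan[[i]][2])
        segs[[i]] <- list(region = plan[[i]][1], strand = plan[[i]][2],
                          S = S, start = NA_integer_, end = NA_integer_)
      }
      margin <- 60L
      ## first fragment start
      segs[[1]]$start <- sample(1L:max(1L, nchar(segs[[1]]$S) - nf * fragLen - margin), 1L)
      for (i in seq_len(nf - 1L)) {
        SL <- segs[[i]]$S; SR <- segs[[i + 1L]]$S
        iLrange <- c(segs[[i]]$start + fragLen - 30L, segs[[i]]$start + fragLen + 30L)
        iLrange[2] <- min(iLrange[2], nchar(SL) - 1L)
        if (iLrange[1] >= iLrange[2]) { ok <- FALSE; break }
        lastFrag <- i + 1L == nf
        jRrange <- c(margin, nchar(SR) - fragLen - (if (lastFrag) 0L else margin))
        if (jRrange[1] >= jRrange[2]) { ok <- FALSE; break }
        kind <- if (i == interIdx) interKind else "blunt"
        sameRegionJump <- segs[[i]]$region == segs[[i + 1L]]$region &&
          segs[[i]]$strand == segs[[i + 1L]]$strand
        if (sameRegionJump) {
          gapRange <- if (event == "microdeletion") c(5L, 50L) else c(60L, 400L)
          r <- .realizeBluntGap(SL, iLrange, gapRange, jRmax = jRrange[2])
          if (is.null(r)) { ok <- FALSE; break }
          segs[[i]]$end <- r[["iL"]]
          segs[[i + 1L]]$start <- r[["jR"]]
          gapUsed <- r[["gap"]]
          bnds[[i]] <- list(kind = "blunt", OL = 0L, ins = "")
        } else if (kind == "microhomology") {
          r <- .realizeMH(SL, SR, L, iLrange, jRrange)
          if (is.null(r)) { ok <- FALSE; break }
          segs[[i]]$end <- r[["iL"]]
          segs[[i + 1L]]$start <- r[["jR"]]
          bnds[[i]] <- list(kind = "microhomology", OL = L, ins = "")
        } else if (kind == "insertion") {
          r <- .realizeBlunt(SL, SR, iLrange, jRrange)
          if (is.null(r)) { ok <- FALSE; break }
          ins <- .realizeInsertionSeq(SL, r[["iL"]], SR, r[["jR"]], insLen)
          segs[[i]]$end <- r[["iL"]]
          segs[[i + 1L]]$start <- r[["jR"]]
          bnds[[i]] <- list(kind = "insertion", OL = 0L, ins = ins)
        } else {
          r <- .realizeBlunt(SL, SR, iLrange, jRrange)
          if (is.null(r)) { ok <- FALSE; break }
          segs[[i]]$end <- r[["iL"]]
          segs[[i + 1L]]$start <- r[["jR"]]
          bnds[[i]] <- list(kind = "blunt", OL = 0L, ins = "")
        }
      }
      if (!ok) next
      segs[[nf]]$end <- min(nchar(segs[[nf]]$S), segs[[nf]]$start + fragLen)

      ## assemble read and per-seam read positions
      pieces <- character(0)
      seamPos <- integer(0)   # 1-based read position of first base right of seam k
      cur <- 0L
      for (i in seq_len(nf)) {
        frag <- substr(segs[[i]]$S, segs[[i]]$start, segs[[i]]$end)
        pieces <- c(pieces, frag)
        cur <- cur + nchar(frag)
        if (i < nf) {
          insSeq <- bnds[[i]]$ins
          if (nzchar(insSeq)) { pieces <- c(pieces, insSeq); }
          seamPos <- c(seamPos, cur + 1L)
          cur <- cur + nchar(insSeq)
        }
      }
      read <- paste(pieces, collapse = "")

      ## reject reads whose planted boundary is not the unique explanation
      honest <- TRUE
      readCh <- strsplit(read, "")[[1]]
      for (k in seq_len(nf - 1L)) {
        SLch <- orientCh[[paste0(segs[[k]]$region, segs[[k]]$strand)]]
        SRch <- orientCh[[paste0(segs[[k + 1L]]$region, segs[[k + 1L]]$strand)]]
        if (!.seamHonest(readCh, seamPos[k], bnds[[k]]$ins, SLch, SRch,
                         bnds[[k]]$kind, bnds[[k]]$OL)) { honest <- FALSE; break }
      }
      if (!honest) next

      ## planted mutations outside protected seam windows
      nMut <- 0L
      if (cfg$mutationRate > 0) {
        n <- nchar(read)
        prot <- logical(n)
        if (!cfg$mutateSeams) {
          for (k in seq_len(nf - 1L)) {
            W <- max(5L, bnds[[k]]$OL + 2L, nchar(bnds[[k]]$ins) + 2L)
            lo <- max(1L, seamPos[k] - W)
            hi <- min(n, seamPos[k] + nchar(bnds[[k]]$ins) + W - 1L)
            prot[lo:hi] <- TRUE
          }
        }
        hitPos <- which(runif(n) < cfg$mutationRate & !prot)
        if (length(hitPos)) {
          ch <- strsplit(read, "")[[1]]
          for (p in hitPos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          read <- paste(ch, collapse = "")
          nMut <- length(hitPos)
        }
      }

      ## truth fragments in forward 0-based half-open reference coordinates
      frTruth <- do.call(rbind, lapply(seq_len(nf), function(i) {
        fwd <- .orientedToFwd(nchar(segs[[i]]$S), segs[[i]]$strand,
                              segs[[i]]$start, segs[[i]]$end)
        data.frame(region = segs[[i]]$region, strand = segs[[i]]$strand,
                   rstart = fwd[1], rend = fwd[2])
      }))
      bTruth <- do.call(rbind, lapply(seq_len(nf - 1L), function(k)
        data.frame(kind = bnds[[k]]$kind, OL = bnds[[k]]$OL,
                   insertionSeq = bnds[[k]]$ins,
                   interSwitch = k == interIdx, seamPos = seamPos[k])))
      events <- switch(event,
        none = character(0),
        intra_donor = "intra",
        intra_acceptor = "intra",
        microdeletion = c("intra", "microdeletion"),
        inversion = c("intra", "inversion"))
      return(list(readId = readId, read = read, fragments = frTruth,
                  boundaries = bTruth, events = events, event = event,
                  gap = gapUsed, nMutations = nMut))
    }
    stop("could not realize the requested junction after 1000 attempts ",
         "(is the planted overlap longer than any shared substring?)")
  }

  ids <- sprintf("sim%05d", seq_len(cfg$nReads))
  sims <- lapply(ids, buildRead)
  reads <- setNames(vapply(sims, `[[`, character(1), "read"), ids)
  tt <- do.call(rbind, lapply(sims, function(s) {
    ib <- s$boundaries[s$boundaries$interSwitch, , drop = FALSE][1, ]
    data.frame(readId = s$readId,
               architecture = paste0(s$fragments$region, s$fragments$strand,
                                     collapse = ","),
               kind = ib$kind, OL = ib$OL, insertionLen = nchar(ib$insertionSeq),
               events = paste(s$events, collapse = ","),
               nFragments = nrow(s$fragments),
               nMutations = s$nMutations)
  }))
  truth <- setNames(sims, ids)
  list(reads = reads, truth = truth, truthTable = tt)
}

#' Configuration for the SHM clone simulator
#'
#' @param seed RNG seed.
#' @param nClones number of clones.
#' @param refLength reference length (used when the reference is generated).
#' @param targetFrequency per-bp mutation frequency F0 (<= 0.05). Per-position
#'   rates are F0 scaled by the hotspot multiplier and normalized to mean F0
#'   across the reference, so the realized genome-wide expectation is F0
#'   regardless of the bias.
#' @param hotspotBias rate multiplier at RGYW/WRCY hotspot positions (>= 0).
#' @param transitionBias odds of the transition base relative to each
#'   transversion base when drawing the mutated identity.
#' @param indelRate per-bp indel probability (default 0).
#' @param indelLenRange inclusive indel length range.
#' @return validated config list (class `SimSHMConfig`).
#' @export
simSHMConfig <- function(seed = 1L, nClones = 50L, refLength = 500L,
                         targetFrequency = 5e-3, hotspotBias = 3,
                         transitionBias = 2, indelRate = 0,
                         indelLenRange = c(1L, 3L)) {
  stopifnot(targetFrequency >= 0, targetFrequency <= 0.05, hotspotBias >= 0,
            transitionBias >= 0, indelRate >= 0, indelRate < 0.01,
            nClones >= 1L, refLength >= 50L)
  structure(list(seed = as.integer(seed), nClones = as.integer(nClones),
                 refLength = as.integer(refLength),
                 targetFrequency = targetFrequency, hotspotBias = hotspotBias,
                 transitionBias = transitionBias, indelRate = indelRate,
                 indelLenRange = as.integer(indelLenRange)),
            class = "SimSHMConfig")
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate an SHM clone set with known ground truth
#'
#' Every position mutates independently with probability F0 x (normalized
#' hotspot multiplier); mutated identities are drawn with the configured
#' transition bias; indels (when enabled) are applied after substitutions.
#'
#' @param cfg a [simSHMConfig()].
#' @param reference germline reference (character string); generated at
#'   `cfg$refLength` when `NULL`.
#' @return list: `clones` (named character vector), `reference`, `truth`
#'   (data.frame `clone`, `position`, `refBase`, `altBase`, `motifClass`),
#'   `indelTruth` (data.frame `clone`, `type`, `position`, `length`).
#' @export
simulateSHMClones <- function(cfg, reference = NULL) {
  stopifnot(inherits(cfg, "SimSHMConfig"))
  set.seed(cfg$seed)
  if (is.null(reference)) reference <- .randBases(cfg$refLength)
  reference <- toupper(reference)
  n <- nchar(reference)
  refCh <- strsplit(reference, "")[[1]]
  mclass <- vapply(seq_len(n), function(p) motifClass(reference, p), character(1))
  mult <- ifelse(mclass %in% c("hotspot_RGYW", "hotspot_WRCY"), cfg$hotspotBias, 1)
  rate <- pmin(0.5, cfg$targetFrequency * mult / mean(mult))

  bases <- c("A", "C", "G", "T")
  drawAlt <- function(ref) {
    opts <- setdiff(bases, ref)
    w <- ifelse(opts == .TRANSITION[[ref]], cfg$transitionBias, 1)
    sample(opts, 1L, prob = w)
  }

  truth <- list(); indelTruth <- list()
  clones <- character(cfg$nClones)
  ids <- sprintf("clone%04d", seq_len(cfg$nClones))
  for (ci in seq_len(cfg$nClones)) {
    ch <- refCh
    hit <- which(runif(n) < rate)
    for (p in hit) ch[p] <- drawAlt(refCh[p])
    if (length(hit))
      truth[[length(truth) + 1L]] <- data.frame(
        clone = ids[ci], position = hit, refBase = refCh[hit], altBase = ch[hit],
        motifClass = mclass[hit])
    if (cfg$indelRate > 0) {
      nIndel <- rbinom(1, n, cfg$indelRate)
      if (nIndel > 0L) {
        for (k in seq_len(nIndel)) {
          ln <- sample(cfg$indelLenRange[1]:cfg$indelLenRange[2], 1L)
          type <- sample(c("insertion", "deletion"), 1L)
          pos <- sample(20L:(length(ch) - 20L - ln), 1L)
          if (type == "deletion") ch <- ch[-(pos:(pos + ln - 1L))]
          else ch <- append(ch, strsplit(.randBases(ln), "")[[1]], after = pos)
          indelTruth[[length(indelTruth) + 1L]] <- data.frame(
            clone = ids[ci], type = type, position = pos, length = ln)
        }
      }
    }
    clones[ci] <- paste(ch, collapse = "")
  }
  list(clones = setNames(clones, ids), reference = reference,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(clone = character(0), position = integer(0),
                    refBase = character(0), altBase = character(0),
                    motifClass = character(0)),
       indelTruth = if (length(indelTruth)) do.call(rbind, indelTruth) else
         data.frame(clone = character(0), type = character(0),
                    position = integer(0), length = integer(0)))
}
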