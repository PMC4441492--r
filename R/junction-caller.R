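## Junction reconstruction: chain seed-and-extend segments from donor and
## acceptor (both strands) across the read, then resolve every fragment
## boundary as blunt / microhomology / insertion.
##
## The overlap (OL) at a boundary is the longest read window spanning the
## breakpoint that matches BOTH the left reference continuation and the right
## reference continuation perfectly. Within that window the breakpoint is
## inherently ambiguous, so the window itself is reported (leftBreakRef = end
## of the maximal donor-side extension, rightBreakRef = start of the maximal
## acceptor-side extension) rather than an arbitrary single point.

#' Caller parameters
#'
#' @param minSegLen minimum fragment length in nt (default 20, sized to the
#'   switch-repeat unit length).
#' @param maxMismatchRate maximum per-fragment mismatch fraction (default 0.1).
#' @param seedK exact seed length for the scanner (default 12).
#' @param maxBoundaryOverlap maximum read overlap allowed between adjacent
#'   chained fragments (bounds the microhomology plus alignment over-extension
#'   the chain can absorb; default 80).
#' @param fragmentPenalty chain score penalty per extra fragment; together
#'   with the overlap deduction this makes spurious repeat matches that do
#'   not explain new read bases strictly unprofitable (default 25).
#' @return a named list of parameters.
#' @export
junctionParams <- function(minSegLen = 20L, maxMismatchRate = 0.1, seedK = 12L,
                           maxBoundaryOverlap = 80L, fragmentPenalty = 25) {
  stopifnot(minSegLen >= seedK, maxMismatchRate >= 0, maxMismatchRate < 0.5)
  list(minSegLen = as.integer(minSegLen), maxMismatchRate = maxMismatchRate,
       seedK = as.integer(seedK), maxBoundaryOverlap = as.integer(maxBoundaryOverlap),
       fragmentPenalty = fragmentPenalty)
}

## oriented (strand-adjusted) integer sequences of both regions, computed once
.orientCache <- function(refs) {
  e <- new.env(parent = emptyenv())
  for (rg in c(refs@donorName, refs@acceptorName)) {
    s <- regionSequence(refs, rg)
    assign(paste0(rg, "+"), .s2i(s), envir = e)
    assign(paste0(rg, "-"), .s2i(revComp(s)), envir = e)
  }
  e
}

## strand-oriented continuation of a fragment's alignment:
## expected target base at read position i (0-based) is tInt[off + i + 1]
.continuation <- function(frag, refs, cache = NULL) {
  key <- paste0(frag$region, frag$strand)
  tInt <- if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE))
    get(key, envir = cache) else {
      s <- regionSequence(refs, frag$region)
      .s2i(if (frag$strand == "-") revComp(s) else s)
    }
  L <- length(tInt)
  ts <- if (frag$strand == "+") frag$rstart else L - frag$rend
  list(tInt = tInt, off = ts - frag$qstart, len = L,
       strand = frag$strand, region = frag$region)
}

## perfect-match indicator of read vs a continuation over 0-based positions pos
.contMatch <- function(readInt, cont, pos) {
  tp <- cont$off + pos
  ok <- tp >= 0L & tp < cont$len
  m <- logical(length(pos))
  if (any(ok)) {
    a <- readInt[pos[ok] + 1L]
    b <- cont$tInt[tp[ok] + 1L]
    m[ok] <- a == b & a != .NCODE & b != .NCODE
  }
  m
}

## genomic (1-based) coordinate of the reference base a read position maps to
.readPosToGenomic <- function(frag, cont, refs, pos) {
  tp <- cont$off + pos
  fwd0 <- if (frag$strand == "+") tp else cont$len - 1L - tp
  unname(refs@genomicOffset[[frag$region]] + fwd0)
}

#' Resolve one fragment boundary as blunt, microhomology or insertion
#'
#' Places a canonical breakpoint at the split point maximizing local donor
#' agreement to the left plus acceptor agreement to the right (leftmost on
#' ties), then computes OL = length of the longest read window spanning that
#' breakpoint which matches both reference continuations perfectly
#' (case-insensitive after uppercasing; N never matches). Read bases between
#' the maximal perfect left-extension and right-extension that match neither
#' reference become an insertion (which forces OL = 0: a boundary is
#' insertion XOR microhomology); zero shared and zero novel bases is a blunt
#' join. OL is a function of the read and the two continuations only:
#' shifting the nominal breakpoint inside the homology window cannot change
#' the result.
#'
#' @param read the read sequence (character, orientation of the call).
#' @param left,right one-row data.frames (or lists) with fields `qstart`,
#'   `qend`, `region`, `rstart`, `rend`, `strand` as produced by
#'   [scanReference()].
#' @param refs a [SwitchRegionSet].
#' @param cache internal: precomputed oriented sequences.
#' @return one-row data.frame: `kind`, `overlapLen`, `insertionSeq`,
#'   `leftBreakRef`, `rightBreakRef` (1-based genomic), `qWinStart`,
#'   `qWinEnd` (0-based half-open window on the read).
#' @export
resolveBoundary <- function(read, left, right, refs, cache = NULL) {
  left <- as.list(left); right <- as.list(right)
  if (identical(left[c("region", "strand", "rstart", "rend", "qstart", "qend")],
                right[c("region", "strand", "rstart", "rend", "qstart", "qend")]))
    stop("degenerate boundary: left and right are the same match")
  if (left$qend > right$qend)
    stop("left fragment must end at or before the right fragment's end")
  read <- toupper(read)
  readInt <- .s2i(read)
  nq <- length(readInt)
  contL <- .continuation(left, refs, cache)
  contR <- .continuation(right, refs, cache)

  aEnd <- left$qend        # 0-based exclusive end of left fragment
  b0 <- right$qstart       # 0-based start of right fragment
  wlo <- max(0L, min(aEnd, b0) - 90L)
  whi <- min(nq, max(aEnd, b0) + 90L)
  pos <- wlo:(whi - 1L)
  cmpL <- .contMatch(readInt, contL, pos)
  cmpR <- .contMatch(readInt, contR, pos)
  at <- function(v, p) p > wlo && p <= whi && v[p - wlo]     # value at position p-1
  atp <- function(v, p) p >= wlo && p < whi && v[p - wlo + 1L]  # value at position p

  ## canonical breakpoint: split m maximizing donor agreement in [m-40, m)
  ## plus acceptor agreement in [m, m+40), scored +1 per match / -2 per
  ## mismatch so that repeat-driven partial matches beyond the junction do
  ## not attract the split; leftmost on ties
  w <- 40L
  cumL <- c(0L, cumsum(cmpL)); cumR <- c(0L, cumsum(cmpR))
  ms <- max(wlo, min(aEnd, b0) - 60L):min(whi, max(aEnd, b0) + 60L)
  loL <- pmax(ms - w, wlo); hiR <- pmin(ms + w, whi)
  mL <- cumL[ms - wlo + 1L] - cumL[loL - wlo + 1L]
  mR <- cumR[hiR - wlo + 1L] - cumR[ms - wlo + 1L]
  sc <- (3L * mL - 2L * (ms - loL)) + (3L * mR - 2L * (hiR - ms))
  mstar <- ms[which.max(sc)]

  ## maximal perfect donor extension [xL, eL): the match run connected to the
  ## donor fragment body (stray islands of chance matches inside an inserted
  ## stretch are skipped, they are not extensions of the donor)
  e <- mstar; xL <- eL <- wlo
  repeat {
    while (e > wlo && !at(cmpL, e)) e <- e - 1L
    if (e == wlo) break
    x <- e
    while (x > wlo && at(cmpL, x)) x <- x - 1L
    if (x <= aEnd - 1L) {          # run contains the fragment's last match
      xL <- x
      eL <- e
      while (eL < whi && atp(cmpL, eL)) eL <- eL + 1L
      break
    }
    e <- x                          # island: continue searching leftward
  }
  ## maximal perfect acceptor extension [sR, yR), mirrored
  s <- mstar; sR <- yR <- whi
  repeat {
    while (s < whi && !atp(cmpR, s)) s <- s + 1L
    if (s == whi) break
    y <- s
    while (y < whi && atp(cmpR, y)) y <- y + 1L
    if (y >= b0 + 1L) {            # run contains the fragment's first match
      yR <- y
      sR <- s
      while (sR > wlo && at(cmpR, sR)) sR <- sR - 1L
      break
    }
    s <- y                          # island: continue searching rightward
  }
  if (eL == wlo || sR == whi)
    stop("could not anchor boundary continuations (invalid fragments?)")

  ovS <- max(xL, sR); ovE <- min(eL, yR)
  if (ovE > ovS) {
    kind <- "microhomology"; ol <- ovE - ovS; ins <- ""
    winS <- ovS; winE <- ovE
  } else if (sR > eL) {
    kind <- "insertion"; ol <- 0L
    ins <- substr(read, eL + 1L, sR)
    winS <- eL; winE <- sR
  } else {
    kind <- "blunt"; ol <- 0L; ins <- ""
    winS <- eL; winE <- eL
  }
  data.frame(kind = kind, overlapLen = as.integer(ol), insertionSeq = ins,
             leftBreakRef = .readPosToGenomic(left, contL, refs, eL - 1L),
             rightBreakRef = .readPosToGenomic(right, contR, refs, sR),
             qWinStart = as.integer(winS), qWinEnd = as.integer(winE),
             stringsAsFactors = FALSE)
}

## chain DP over candidate segments, maximizing total score minus the overlap
## double-count and a per-extra-fragment penalty; ties broken by fewer
## fragments, then fewer mismatches, then leftmost
.chainSegments <- function(cands, params) {
  n <- nrow(cands)
  if (n == 0L) return(integer(0))
  ord <- order(cands$qstart, cands$qend, -cands$score, cands$mismatches)
  qstart <- cands$qstart[ord]; qend <- cands$qend[ord]
  score <- cands$score[ord]; mism <- cands$mismatches[ord]
  len <- qend - qstart
  dp <- as.numeric(score)
  nf <- rep(1L, n)
  mm <- mism
  prev <- rep(0L, n)
  maxOv <- params$maxBoundaryOverlap
  pen <- params$fragmentPenalty
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (qstart[j] >= qstart[i] || qend[j] >= qend[i]) next
      ovl <- qend[j] - qstart[i]
      if (ovl > maxOv || ovl > min(len[i], len[j]) - 1L) next
      val <- dp[j] + score[i] - max(0L, ovl) - pen
      better <- val > dp[i] + 1e-9 ||
        (abs(val - dp[i]) <= 1e-9 &&
           (nf[j] + 1L < nf[i] ||
              (nf[j] + 1L == nf[i] && mm[j] + mism[i] < mm[i])))
      if (better) {
        dp[i] <- val
        nf[i] <- nf[j] + 1L
        mm[i] <- mm[j] + mism[i]
        prev[i] <- j
      }
    }
  }
  best <- which.max(dp)
  alt <- which(abs(dp - dp[best]) <= 1e-9)
  if (length(alt) > 1L) {  # tie: fewer fragments, fewer mismatches, leftmost
    alt <- alt[order(nf[alt], mm[alt], qstart[alt])]
    best <- alt[1]
  }
  chain <- integer(0)
  i <- best
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  ord[chain]
}

.emptyCands <- function() {
  data.frame(qstart = integer(0), qend = integer(0), rstart = integer(0),
             rend = integer(0), strand = character(0),
             mismatches = integer(0), score = integer(0), region = character(0))
}

.candidateSegments <- function(read, refs, params, indices) {
  out <- list()
  for (rg in c(refs@donorName, refs@acceptorName)) {
    seqChr <- regionSequence(refs, rg)
    for (st in c("+", "-")) {
      m <- scanReference(read, seqChr, strand = st,
                         minSegLen = params$minSegLen,
                         maxMismatchRate = params$maxMismatchRate,
                         seedK = params$seedK,
                         index = indices[[paste0(rg, st)]])
      if (nrow(m)) {
        m$region <- rg
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out)) return(.emptyCands())
  do.call(rbind, out)
}

.seedIndices <- function(refs, seedK) {
  idx <- list()
  for (rg in c(refs@donorName, refs@acceptorName)) {
    seqChr <- regionSequence(refs, rg)
    idx[[paste0(rg, "+")]] <- .seedIndex(seqChr, seedK)
    idx[[paste0(rg, "-")]] <- .seedIndex(revComp(seqChr), seedK)
  }
  idx
}

.uncallable <- function(readId, read, partial) {
  methods::new("JunctionCall", readId = readId, read = read, callable = FALSE,
               fragments = partial,
               boundaries = data.frame(kind = character(0), overlapLen = integer(0),
                                       insertionSeq = character(0),
                                       leftBreakRef = integer(0), rightBreakRef = integer(0),
                                       qWinStart = integer(0), qWinEnd = integer(0)),
               unassignedPrefix = NA_integer_, unassignedSuffix = NA_integer_,
               orientationFlipped = FALSE)
}

#' Reconstruct the fragment architecture of one junction read
#'
#' Selects the highest-total-score chain of gap-free segments (donor and
#' acceptor, both strands) tiling the read left to right, then resolves each
#' boundary with [resolveBoundary()]. Both the given orientation and the
#' reverse complement are tried; the orientation placing a forward-strand
#' donor fragment first wins. Reads without at least one donor and one
#' acceptor fragment are reported uncallable (carrying their partial matches),
#' not as an error.
#'
#' @param read DNA character string (length >= 2 x `minSegLen`).
#' @param refs a [SwitchRegionSet].
#' @param params see [junctionParams()].
#' @param readId identifier recorded in the call.
#' @param indices,cache internal: precomputed seed indices / oriented
#'   sequences (built when `NULL`).
#' @return a [JunctionCall].
#' @export
segmentJunction <- function(read, refs, params = junctionParams(),
                            readId = "read", indices = NULL, cache = NULL) {
  read <- toupper(read)
  if (nchar(read) < 2L * params$minSegLen)
    stop("read shorter than 2 x minSegLen")
  if (is.null(indices)) indices <- .seedIndices(refs, params$seedK)
  if (is.null(cache)) cache <- .orientCache(refs)

  tryOrientation <- function(seq) {
    cands <- .candidateSegments(seq, refs, params, indices)
    if (!nrow(cands)) return(NULL)
    chain <- .chainSegments(cands, params)
    frs <- cands[chain, , drop = FALSE]
    rownames(frs) <- NULL
    score <- sum(frs$score) - params$fragmentPenalty * (nrow(frs) - 1L)
    list(fragments = frs, score = score,
         hasDonor = any(frs$region == refs@donorName),
         hasAcceptor = any(frs$region == refs@acceptorName),
         donorFwdFirst = nrow(frs) > 0L && frs$region[1] == refs@donorName &&
           frs$strand[1] == "+")
  }
  pick <- function(o) !is.null(o) && o$hasDonor && o$hasAcceptor

  fwd <- tryOrientation(read)
  sel <- NULL; flipped <- FALSE; seq <- read
  if (pick(fwd) && fwd$donorFwdFirst) {
    sel <- fwd   # the preferred orientation; no need to try the complement
  } else {
    rcRead <- revComp(read)
    rev <- tryOrientation(rcRead)
    if (pick(fwd) && pick(rev)) {
      if (rev$donorFwdFirst || rev$score > fwd$score) { sel <- rev; flipped <- TRUE }
      else sel <- fwd
    } else if (pick(fwd)) sel <- fwd
    else if (pick(rev)) { sel <- rev; flipped <- TRUE }
    if (flipped) seq <- rcRead
  }

  if (is.null(sel)) {
    partial <- if (!is.null(fwd)) fwd$fragments else .emptyCands()
    return(.uncallable(readId, read, partial))
  }
  frs <- sel$fragments
  if (nrow(frs) < 2L) return(.uncallable(readId, seq, frs))
  bnds <- do.call(rbind, lapply(seq_len(nrow(frs) - 1L), function(i)
    resolveBoundary(seq, frs[i, ], frs[i + 1L, ], refs, cache = cache)))
  methods::new("JunctionCall",
    readId = readId, read = seq, callable = TRUE,
    fragments = frs, boundaries = bnds,
    unassignedPrefix = as.integer(frs$qstart[1]),
    unassignedSuffix = as.integer(nchar(seq) - frs$qend[nrow(frs)]),
    orientationFlipped = flipped)
}

#' Call junction architectures for a set of reads
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param refs a [SwitchRegionSet].
#' @param params see [junctionParams()].
#' @return list of [JunctionCall], one per read, named by read id.
#' @export
callJunctions <- function(reads, refs, params = junctionParams()) {
  if (methods::is(reads, "DNAStringSet")) reads <- setNames(as.character(reads), names(reads))
  if (is.null(names(reads))) names(reads) <- sprintf("read%04d", seq_along(reads))
  indices <- .seedIndices(refs, params$seedK)
  cache <- .orientCache(refs)
  out <- lapply(names(reads), function(id)
    segmentJunction(reads[[id]], refs, params, readId = id,
                    indices = indices, cache = cache))
  names(out) <- names(reads)
  out
}

#' Discard exact duplicate reads
#'
#' Removes exact full-sequence duplicates, keeping the first occurrence.
#' Reads identical only around the junction but differing elsewhere are
#' distinct sequences and are retained.
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @return same type as the input, duplicates removed.
#' @export
dedupReads <- function(reads) {
  if (methods::is(reads, "DNAStringSet"))
    return(reads[!duplicated(as.character(reads))])
  reads[!duplicated(reads)]
}

#' Extract the inter-switch (donor-to-acceptor) boundary of a call
#'
#' For compound junctions only the donor-to-acceptor transition boundary is
#' scored in overlap summaries (one OL per junction); intra-switch boundaries
#' are reported separately. Returns the first boundary whose left fragment is
#' the donor region and right fragment is the acceptor region.
#'
#' @param call a [JunctionCall].
#' @param refs a [SwitchRegionSet].
#' @return one-row boundary data.frame, or `NULL` for uncallable calls or
#'   architectures without a donor-to-acceptor adjacency.
#' @export
interSwitchBoundary <- function(call, refs) {
  if (!call@callable) return(NULL)
  fr <- call@fragments
  for (i in seq_len(nrow(fr) - 1L)) {
    if (fr$region[i] == refs@donorName && fr$region[i + 1L] == refs@acceptorName)
      return(call@boundaries[i, , drop = FALSE])
  }
  NULL
}

#' Tabulate a list of junction calls
#'
#' @param calls list of [JunctionCall].
#' @param refs a [SwitchRegionSet] (used to locate the inter-switch boundary).
#' @return data.frame with one row per read: `readId`, `callable`,
#'   `nFragments`, `kind`, `OL`, `insertionLen`, `leftBreakRef`,
#'   `rightBreakRef` (inter-switch boundary), `architecture`.
#' @export
junctionTable <- function(calls, refs) {
  rows <- lapply(calls, function(cl) {
    if (!cl@callable)
      return(data.frame(readId = cl@readId, callable = FALSE, nFragments = nrow(cl@fragments),
                        kind = NA_character_, OL = NA_integer_, insertionLen = NA_integer_,
                        leftBreakRef = NA_integer_, rightBreakRef = NA_integer_,
                        architecture = NA_character_))
    b <- interSwitchBoundary(cl, refs)
    arch <- paste0(cl@fragments$region, cl@fragments$strand, collapse = ",")
    if (is.null(b))
      return(data.frame(readId = cl@readId, callable = TRUE, nFragments = nrow(cl@fragments),
                        kind = NA_character_, OL = NA_integer_, insertionLen = NA_integer_,
                        leftBreakRef = NA_integer_, rightBreakRef = NA_integer_,
                        architecture = arch))
    data.frame(readId = cl@readId, callable = TRUE, nFragments = nrow(cl@fragments),
               kind = b$kind, OL = b$overlapLen, insertionLen = nchar(b$insertionSeq),
               leftBreakRef = b$leftBreakRef, rightBreakRef = b$rightBreakRef,
               architecture = arch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "JunctionCall", function(object) {
  if (!object@callable) {
    cat(sprintf("JunctionCall '%s': uncallable (%d partial match(es))\n",
                object@readId, nrow(object@fragments)))
    return(invisible(NULL))
  }
  arch <- paste0(object@fragments$region, object@fragments$strand, collapse = ",")
  cat(sprintf("JunctionCall '%s': %d fragment(s) [%s]%s\n", object@readId,
              nrow(object@fragments), arch,
              if (object@orientationFlipped) " (read reverse-complemented)" else ""))
  b <- object@boundaries
  for (i in seq_len(nrow(b))) {
    extra <- switch(b$kind[i],
      microhomology = sprintf(" OL=%d", b$overlapLen[i]),
      insertion = sprintf(" +%dnt '%s'", nchar(b$insertionSeq[i]), b$insertionSeq[i]),
      "")
    cat(sprintf("  boundary %d: %s%s  [%d | %d]\n", i, b$kind[i], extra,
                b$leftBreakRef[i], b$rightBreakRef[i]))
  }
})
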