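## Gap-free seed-and-extend local scanner.
##
## Switch junction amplicons at Sanger scale are substitution-dominated, so
## the engine is deliberately gap-free: exact k-mer seeds grouped by diagonal,
## then a maximal-scoring-run extension (+1 match / -2 mismatch) per diagonal.
## Segments with internal indels simply split into two diagonals. This keeps
## every call auditable against a brute-force oracle.

.NCODE <- 78L  # utf8 'N'

.s2i <- function(s) utf8ToInt(s)

## k-mer index of a target string: environment kmer -> 0-based start positions
.seedIndex <- function(seqChr, k) {
  n <- nchar(seqChr)
  if (n < k) return(list2env(list(), hash = TRUE))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seqChr, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  idx <- split(starts[keep] - 1L, kmers[keep])
  list2env(idx, hash = TRUE, size = max(16L, length(idx)))
}

## maximal-scoring subarray (Kadane), returns c(value, i, j) 1-based or NULL
.bestRun <- function(w) {
  n <- length(w)
  cs <- cumsum(w)
  prev <- c(0, cs[-n])
  minPrev <- cummin(prev)
  val <- cs - minPrev
  j <- which.max(val)
  if (val[j] <= 0) return(NULL)
  i <- max(which(prev[seq_len(j)] == minPrev[j]))
  c(val[j], i, j)
}

## all acceptable runs along one diagonal's match vector
.diagonalRuns <- function(match, minSegLen, maxMismatchRate, maxRuns = 4L) {
  w <- ifelse(match, 1, -2)
  out <- list()
  add <- function(i, j, mm) out[[length(out) + 1L]] <<- c(i, j, mm)
  for (iter in seq_len(maxRuns)) {
    r <- .bestRun(w)
    if (is.null(r) || r[1] < minSegLen * (1 - 3 * maxMismatchRate)) break
    i <- r[2]; j <- r[3]
    len <- j - i + 1L
    mmPos <- which(!match[i:j])
    mm <- length(mmPos)
    if (len >= minSegLen && mm <= maxMismatchRate * len) {
      add(i, j, mm)
      ## a mismatch-tolerant run can fuse a perfect segment with a
      ## net-positive noisy extension reaching across a junction seam; the
      ## maximal perfect prefix/suffix are therefore emitted as independent
      ## chaining candidates so the seam-respecting segmentation stays
      ## available to the chainer
      if (mm > 0L) {
        pj <- i + mmPos[1] - 2L
        if (pj - i + 1L >= minSegLen) add(i, pj, 0L)
        si <- i + mmPos[mm]
        if (j - si + 1L >= minSegLen) add(si, j, 0L)
      }
    }
    w[i:j] <- -1e9
  }
  out
}

#' Scan a read against one switch region (gap-free seed-and-extend)
#'
#' Finds all locally optimal gap-free alignments of read substrings to the
#' region on the given strand: exact k-mer seeds are grouped by diagonal and
#' extended with mismatch tolerance (+1 match / -2 mismatch scoring, runs
#' trimmed to match at both ends). N bases never count as matches. Matches on
#' the reverse strand are reported in forward-region coordinates with
#' `strand = "-"`.
#'
#' @param read DNA character string.
#' @param regionSeq region sequence (character) on its forward strand.
#' @param strand `"+"` or `"-"`.
#' @param minSegLen minimum reported segment length (default 20).
#' @param maxMismatchRate maximum mismatch fraction per segment (default 0.1,
#'   must be < 0.5).
#' @param seedK exact seed length (default 12).
#' @param index optional precomputed seed index of the strand-oriented target
#'   (see internals); built on the fly when `NULL`.
#' @param maxKmerHits seeds occurring more often than this in the target are
#'   ignored (repeat masking; default 64).
#' @return data.frame with columns `qstart`, `qend`, `rstart`, `rend` (0-based
#'   half-open; reference interval always on the forward strand), `strand`,
#'   `mismatches`, `score`, sorted by `qstart` then descending score.
#' @export
scanReference <- function(read, regionSeq, strand = "+", minSegLen = 20L,
                          maxMismatchRate = 0.1, seedK = 12L, index = NULL,
                          maxKmerHits = 64L) {
  if (!nzchar(read)) stop("empty read")
  if (maxMismatchRate < 0 || maxMismatchRate >= 0.5)
    stop("maxMismatchRate must be in [0, 0.5)")
  read <- toupper(read)
  target <- if (strand == "-") revComp(regionSeq) else toupper(regionSeq)
  nq <- nchar(read); nr <- nchar(target)
  empty <- data.frame(qstart = integer(0), qend = integer(0), rstart = integer(0),
                      rend = integer(0), strand = character(0),
                      mismatches = integer(0), score = integer(0))
  if (nq < seedK || nr < seedK) return(empty)
  if (is.null(index)) index <- .seedIndex(target, seedK)
  qs <- seq_len(nq - seedK + 1L)
  kmers <- substring(read, qs, qs + seedK - 1L)
  hits <- mget(kmers, envir = index, ifnotfound = list(NULL))
  nhit <- lengths(hits)
  keep <- nhit > 0L & nhit <= maxKmerHits
  if (!any(keep)) return(empty)
  q0 <- rep(qs[keep] - 1L, nhit[keep])
  r0 <- unlist(hits[keep], use.names = FALSE)
  diag <- r0 - q0
  dtab <- sort(table(diag), decreasing = TRUE)
  ## a genuine >= minSegLen gap-free fragment yields several seeds; lone-seed
  ## diagonals are repeat noise unless nothing better exists
  if (any(dtab >= 2L)) dtab <- dtab[dtab >= 2L]
  diags <- as.integer(names(dtab))
  if (length(diags) > 48L) diags <- diags[seq_len(48L)]

  readInt <- .s2i(read)
  tgtInt <- .s2i(target)
  res <- vector("list", length(diags))
  for (ii in seq_along(diags)) {
    d <- diags[ii]
    qlo <- max(0L, -d)
    qhi <- min(nq, nr - d)
    if (qhi - qlo < minSegLen) next
    a <- readInt[(qlo + 1L):qhi]
    b <- tgtInt[(qlo + d + 1L):(qhi + d)]
    match <- a == b & a != .NCODE & b != .NCODE
    runs <- .diagonalRuns(match, minSegLen, maxMismatchRate)
    if (!length(runs)) next
    res[[ii]] <- do.call(rbind, lapply(runs, function(r) {
      qstart <- qlo + r[1] - 1L
      qend <- qlo + r[2]
      len <- qend - qstart
      c(qstart = qstart, qend = qend, tstart = qstart + d, tend = qend + d,
        mm = r[3], score = (len - r[3]) - 2L * r[3])
    }))
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  m <- as.data.frame(do.call(rbind, res))
  if (strand == "-") {
    rstart <- nr - m$tend
    rend <- nr - m$tstart
  } else {
    rstart <- m$tstart
    rend <- m$tend
  }
  out <- data.frame(qstart = as.integer(m$qstart), qend = as.integer(m$qend),
                    rstart = as.integer(rstart), rend = as.integer(rend),
                    strand = strand, mismatches = as.integer(m$mm),
                    score = as.integer(m$score))
  out <- out[order(out$qstart, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
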