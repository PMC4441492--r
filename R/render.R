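## Three-wise alignment rendering: donor germline above, read in the middle,
## acceptor germline below, pipes at identities, lower-case read bases at
## mismatches, homology window delimited by brackets, 1-based genomic
## coordinates at line starts. Byte-for-byte deterministic for a fixed call.

.renderBoundary <- function(call, i, refs, flank) {
  read <- call@read
  readInt <- .s2i(read)
  nq <- length(readInt)
  left <- as.list(call@fragments[i, ])
  right <- as.list(call@fragments[i + 1L, ])
  b <- call@boundaries[i, ]
  contL <- .continuation(left, refs)
  contR <- .continuation(right, refs)

  wlo <- max(0L, b$qWinStart - flank)
  whi <- min(nq, b$qWinEnd + flank)
  pos <- wlo:(whi - 1L)
  readCh <- strsplit(substr(read, wlo + 1L, whi), "")[[1]]

  expect <- function(cont) {
    tp <- cont$off + pos
    ok <- tp >= 0L & tp < cont$len
    ch <- rep(" ", length(pos))
    ch[ok] <- strsplit(intToUtf8(cont$tInt[tp[ok] + 1L]), "")[[1]]
    ch
  }
  dCh <- expect(contL)
  aCh <- expect(contR)
  pipeD <- ifelse(dCh == readCh & dCh != " " & dCh != "N", "|", " ")
  pipeA <- ifelse(aCh == readCh & aCh != " " & aCh != "N", "|", " ")

  ## read base case: donor territory left of the window, acceptor territory
  ## right of it; in-window bases belong to both. Mismatches (and inserted
  ## bases) are lower-case.
  assignedMatch <- logical(length(pos))
  inWin <- pos >= b$qWinStart & pos < b$qWinEnd
  leftOf <- pos < b$qWinStart
  rightOf <- pos >= b$qWinEnd
  assignedMatch[leftOf] <- pipeD[leftOf] == "|"
  assignedMatch[rightOf] <- pipeA[rightOf] == "|"
  assignedMatch[inWin] <- if (b$kind == "insertion") FALSE else
    pipeD[inWin] == "|" & pipeA[inWin] == "|"
  rCh <- ifelse(assignedMatch, readCh, tolower(readCh))

  ## bracket columns delimiting the homology window (or the inserted bases)
  insertAt <- function(ch, openCol, closeCol, open, close) {
    out <- character(0)
    for (k in seq_along(ch)) {
      if (pos[k] == openCol) out <- c(out, open)
      out <- c(out, ch[k])
      if (pos[k] == closeCol) out <- c(out, close)
    }
    paste(out, collapse = "")
  }
  ## zero-width windows (blunt seams) still get adjacent "[]" marking the seam
  insertZero <- function(ch, col, open, close) {
    out <- character(0)
    for (k in seq_along(ch)) {
      if (pos[k] == col) out <- c(out, open, close)
      out <- c(out, ch[k])
    }
    paste(out, collapse = "")
  }
  openCol <- b$qWinStart
  closeCol <- b$qWinEnd - 1L
  mk <- function(ch, bl, br) {
    if (b$qWinEnd > b$qWinStart) insertAt(ch, openCol, closeCol, bl, br)
    else insertZero(ch, openCol, bl, br)
  }
  dCoord <- .readPosToGenomic(left, contL, refs, pos[which(dCh != " ")[1]])
  aCoord <- .readPosToGenomic(right, contR, refs, pos[which(aCh != " ")[1]])
  pre <- function(lbl, coord) sprintf("%-4s %9s ", lbl, format(coord))
  lines <- c(
    paste0(pre(left$region, dCoord), mk(dCh, "[", "]")),
    paste0(pre("", ""), mk(pipeD, " ", " ")),
    paste0(pre("read", wlo + 1L), mk(rCh, "[", "]")),
    paste0(pre("", ""), mk(pipeA, " ", " ")),
    paste0(pre(right$region, aCoord), mk(aCh, "[", "]"))
  )
  note <- sprintf("boundary %d: %s%s", i, b$kind,
                  switch(b$kind,
                         microhomology = sprintf(" OL=%d", b$overlapLen),
                         insertion = sprintf(" insertion=%s (%d nt)",
                                             b$insertionSeq, nchar(b$insertionSeq)),
                         ""))
  paste(c(note, lines), collapse = "\n")
}

#' Render a junction call as a three-wise alignment text block
#'
#' For every boundary of the call, prints the donor germline line, the read
#' line and the acceptor germline line around the breakpoint (plus/minus
#' `flank` bases), with `|` at nucleotide identities, lower-case read letters
#' at mismatched (mutated or inserted) bases, the homology window delimited by
#' brackets, insertions annotated, and 1-based genomic coordinates at line
#' starts. Output is byte-for-byte deterministic for a fixed call.
#'
#' @param call a callable [JunctionCall].
#' @param refs a [SwitchRegionSet].
#' @param flank bases shown on each side of the boundary window (default 40).
#' @return a single character string (the text block).
#' @export
renderThreewise <- function(call, refs, flank = 40L) {
  if (!call@callable) return(sprintf("# read %s: uncallable", call@readId))
  blocks <- vapply(seq_len(nrow(call@boundaries)), function(i)
    .renderBoundary(call, i, refs, flank), character(1))
  paste0("# read ", call@readId, "\n", paste(blocks, collapse = "\n\n"), "\n")
}
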