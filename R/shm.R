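## Somatic hypermutation profiling: point-mutation calling of clone sets
## against a germline reference (global affine-gap alignment), 12-class
## substitution spectrum, per-bp frequency, spatial distribution, and
## AID / polymerase-eta hotspot motif classification.
##
## Hotspot motifs (germline strand, IUPAC W = A/T, R = A/G, Y = C/T, S = G/C):
##   hotspot_WRCY  mutated C, context WRC.Y  (AID deamination hotspot)
##   hotspot_RGYW  mutated G, context R.G.YW (WRCY on the sister strand)
##   hotspot_WA    mutated A preceded by W   (polymerase-eta A:T hotspot)
##   hotspot_TW    mutated T followed by W   (WA on the sister strand)
##   coldspot      mutated C in SYC, or mutated G in GRS (its complement)

.IUPAC <- list(W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"))

#' Classify the motif context of a mutated reference position
#'
#' @param reference germline reference as a character string.
#' @param position 1-based mutated position.
#' @return one of `"hotspot_RGYW"`, `"hotspot_WRCY"`, `"hotspot_WA"`,
#'   `"hotspot_TW"`, `"coldspot"`, `"none"`.
#' @export
motifClass <- function(reference, position) {
  n <- nchar(reference)
  at <- function(p) if (p >= 1L && p <= n) substr(reference, p, p) else "N"
  refBase <- at(position)
  isW <- function(b) b %in% .IUPAC$W
  isR <- function(b) b %in% .IUPAC$R
  isY <- function(b) b %in% .IUPAC$Y
  isS <- function(b) b %in% .IUPAC$S
  if (refBase == "C" &&
      isW(at(position - 2L)) && isR(at(position - 1L)) && isY(at(position + 1L)))
    return("hotspot_WRCY")
  if (refBase == "G" &&
      isR(at(position - 1L)) && isY(at(position + 1L)) && isW(at(position + 2L)))
    return("hotspot_RGYW")
  if (refBase == "A" && isW(at(position - 1L))) return("hotspot_WA")
  if (refBase == "T" && isW(at(position + 1L))) return("hotspot_TW")
  if (refBase == "C" && isS(at(position - 2L)) && isY(at(position - 1L)))
    return("coldspot")
  if (refBase == "G" && isR(at(position + 1L)) && isS(at(position + 2L)))
    return("coldspot")
  "none"
}

.motifContext <- function(reference, position) {
  n <- nchar(reference)
  ch <- vapply((position - 2L):(position + 2L), function(p)
    if (p >= 1L && p <= n) substr(reference, p, p) else "N", character(1))
  paste(ch, collapse = "")
}

.emptyCalls <- function() data.frame(cloneId = character(0), position = integer(0),
                                     refBase = character(0), altBase = character(0),
                                     context = character(0), motifClass = character(0),
                                     gapAdjacent = logical(0))
.emptyIndels <- function() data.frame(cloneId = character(0), type = character(0),
                                      position = integer(0), length = integer(0))

.shmSubstMatrix <- function()
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2, baseOnly = FALSE)

## equal-length clones whose direct column comparison already clears the
## identity threshold are treated as gapless alignments (an indel would shift
## the register and push identity far below the threshold, forcing the full
## affine-gap alignment path)
.gaplessOK <- function(clone, reference, minIdentity) {
  nchar(clone) == nchar(reference) &&
    sum(utf8ToInt(clone) != utf8ToInt(reference)) <=
      (1 - minIdentity) * nchar(reference)
}

## shared extraction core working on one aligned clone/reference string pair
.callsFromAlignedPair <- function(paStr, saStr, cloneId, reference, minIdentity) {
  pa <- strsplit(paStr, "")[[1]]
  sa <- strsplit(saStr, "")[[1]]
  nonGap <- pa != "-" & sa != "-"
  ident <- sum(pa == sa & nonGap) / max(1L, sum(nonGap))
  if (ident < minIdentity)
    return(list(calls = .emptyCalls(), indels = .emptyIndels(),
                alignable = FALSE, identity = ident))

  refPos <- cumsum(sa != "-")        # 1-based reference coordinate per column
  gapCol <- pa == "-" | sa == "-"
  nearGap <- gapCol
  if (length(gapCol) > 1L)
    nearGap <- gapCol | c(gapCol[-1], FALSE) | c(FALSE, gapCol[-length(gapCol)])

  isSub <- nonGap & pa != sa & pa %in% c("A", "C", "G", "T") &
    sa %in% c("A", "C", "G", "T")
  calls <- .emptyCalls()
  if (any(isSub)) {
    posv <- refPos[isSub]
    calls <- data.frame(
      cloneId = cloneId, position = posv,
      refBase = sa[isSub], altBase = pa[isSub],
      context = vapply(posv, function(p) .motifContext(reference, p), character(1)),
      motifClass = vapply(posv, function(p) motifClass(reference, p), character(1)),
      gapAdjacent = nearGap[isSub])
  }
  indels <- .emptyIndels()
  r <- rle(ifelse(sa == "-", "ins", ifelse(pa == "-", "del", "m")))
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "m") next
    indels <- rbind(indels, data.frame(
      cloneId = cloneId, type = if (r$values[k] == "ins") "insertion" else "deletion",
      position = max(1L, refPos[startIdx[k]]), length = r$lengths[k]))
  }
  list(calls = calls, indels = indels, alignable = TRUE, identity = ident)
}

#' Call point mutations in one clone against a germline reference
#'
#' Globally aligns the clone to the reference with affine gap penalties.
#' Substitutions are emitted as mutation calls with their 5-mer germline
#' context and hotspot/coldspot motif class; gaps are emitted as indel
#' records (excluded from the substitution spectrum). Mutations within 1 nt
#' of an indel column are kept but flagged `gapAdjacent`. Clones below the
#' identity threshold are flagged unalignable and excluded, not fatal.
#'
#' @param clone clone sequence (character string).
#' @param reference germline reference (character string).
#' @param cloneId identifier recorded on each call.
#' @param minIdentity minimum global identity to accept the alignment
#'   (default 0.9).
#' @return a list: `calls` (data.frame `cloneId`, `position`, `refBase`,
#'   `altBase`, `context`, `motifClass`, `gapAdjacent`), `indels` (data.frame
#'   `cloneId`, `type`, `position`, `length`), `alignable` (logical),
#'   `identity`.
#' @export
callCloneMutations <- function(clone, reference, cloneId = "clone",
                               minIdentity = 0.9) {
  clone <- toupper(clone); reference <- toupper(reference)
  if (identical(clone, reference))
    return(list(calls = .emptyCalls(), indels = .emptyIndels(),
                alignable = TRUE, identity = 1))
  if (.gaplessOK(clone, reference, minIdentity))
    return(.callsFromAlignedPair(clone, reference, cloneId, reference, minIdentity))
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(clone),
                                       Biostrings::DNAString(reference),
                                       type = "global",
                                       substitutionMatrix = .shmSubstMatrix(),
                                       gapOpening = 8, gapExtension = 2)
  .callsFromAlignedPair(as.character(Biostrings::alignedPattern(aln)),
                        as.character(Biostrings::alignedSubject(aln)),
                        cloneId, reference, minIdentity)
}

#' Profile a clone set against a germline reference
#'
#' Runs [callCloneMutations()] on every clone, pools the calls and indel
#' records, and reports which clones were unalignable. Clonally related
#' sequences (identical mutation sets) are optionally collapsed to one
#' representative.
#'
#' @param clones named character vector or [Biostrings::DNAStringSet].
#' @param reference germline reference (character string or single-record
#'   `DNAStringSet`).
#' @param collapseClones collapse clones with identical mutation sets
#'   (default `FALSE`).
#' @param minIdentity see [callCloneMutations()].
#' @return list: `calls`, `indels`, `nClones` (alignable, after collapsing),
#'   `excluded` (ids of unalignable clones).
#' @export
profileClones <- function(clones, reference, collapseClones = FALSE,
                          minIdentity = 0.9) {
  if (methods::is(reference, "DNAStringSet")) reference <- as.character(reference[[1]])
  if (methods::is(clones, "DNAStringSet")) clones <- setNames(as.character(clones), names(clones))
  if (is.null(names(clones))) names(clones) <- sprintf("clone%04d", seq_along(clones))
  clones <- toupper(clones); reference <- toupper(reference)
  res <- setNames(vector("list", length(clones)), names(clones))
  same <- clones == reference
  for (id in names(clones)[same])
    res[[id]] <- list(calls = .emptyCalls(), indels = .emptyIndels(),
                      alignable = TRUE, identity = 1)
  todo <- names(clones)[!same]
  fast <- todo[vapply(todo, function(id)
    .gaplessOK(clones[[id]], reference, minIdentity), logical(1))]
  for (id in fast)
    res[[id]] <- .callsFromAlignedPair(clones[[id]], reference, id,
                                       reference, minIdentity)
  todo <- setdiff(todo, fast)
  if (length(todo)) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(clones[todo]),
                                         Biostrings::DNAString(reference),
                                         type = "global",
                                         substitutionMatrix = .shmSubstMatrix(),
                                         gapOpening = 8, gapExtension = 2)
    paS <- as.character(Biostrings::alignedPattern(aln))
    saS <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(todo))
      res[[todo[k]]] <- .callsFromAlignedPair(paS[k], saS[k], todo[k],
                                              reference, minIdentity)
  }
  ok <- vapply(res, function(x) x$alignable, logical(1))
  calls <- do.call(rbind, lapply(res[ok], function(x) x$calls))
  indels <- do.call(rbind, lapply(res[ok], function(x) x$indels))
  keptIds <- names(clones)[ok]
  if (collapseClones && length(keptIds) > 1L) {
    sig <- vapply(keptIds, function(id) {
      cc <- res[[id]]$calls
      paste(sprintf("%d%s>%s", cc$position, cc$refBase, cc$altBase), collapse = ";")
    }, character(1))
    keep <- !duplicated(sig)
    keptIds <- keptIds[keep]
    calls <- calls[calls$cloneId %in% keptIds, , drop = FALSE]
    indels <- indels[indels$cloneId %in% keptIds, , drop = FALSE]
  }
  rownames(calls) <- NULL
  list(calls = calls, indels = indels, nClones = length(keptIds),
       excluded = names(clones)[!ok])
}

.BASES <- c("A", "C", "G", "T")

#' Build a mutation spectrum from pooled mutation calls
#'
#' Frequency per bp is total substitutions / (`nSequences` x `analyzedLen`).
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @param calls mutation-call data.frame (see [callCloneMutations()]); may
#'   have zero rows.
#' @param nSequences number of clones analyzed (>= 1).
#' @param analyzedLen analyzed reference length per clone (>= 1); columns
#'   where the reference base is N should already be excluded from it.
#' @param indels optional indel data.frame; counted into the spectrum's indel
#'   slots.
#' @return a [MutationSpectrum].
#' @export
buildSpectrum <- function(calls, nSequences, analyzedLen, indels = NULL) {
  stopifnot(nSequences >= 1L, analyzedLen >= 1L)
  m <- matrix(0L, 4, 4, dimnames = list(.BASES, .BASES))
  if (nrow(calls)) {
    tab <- table(factor(calls$refBase, .BASES), factor(calls$altBase, .BASES))
    m <- m + unclass(tab)
    storage.mode(m) <- "integer"
  }
  tr <- m["A", "G"] + m["G", "A"] + m["C", "T"] + m["T", "C"]
  tot <- sum(m)
  at <- if (tot > 0L) sum(m[c("A", "T"), ]) / tot else 0
  nIns <- nDel <- 0L
  if (!is.null(indels) && nrow(indels)) {
    nIns <- sum(indels$type == "insertion")
    nDel <- sum(indels$type == "deletion")
  }
  methods::new("MutationSpectrum",
    subCounts = m, nSequences = as.integer(nSequences),
    nBases = as.numeric(nSequences) * analyzedLen,
    transitions = as.integer(tr), transversions = as.integer(tot - tr),
    atFraction = at, gcFraction = if (tot > 0L) 1 - at else 0,
    insertionCount = as.integer(nIns), deletionCount = as.integer(nDel))
}

#' Per-bp mutation frequency F of a spectrum
#' @param x a [MutationSpectrum].
#' @export
frequencyPerBp <- function(x) sum(x@subCounts) / x@nBases

setMethod("show", "MutationSpectrum", function(object) {
  tot <- sum(object@subCounts)
  cat(sprintf("MutationSpectrum: %d substitutions in %d clone(s), %.0f bases\n",
              tot, object@nSequences, object@nBases))
  cat(sprintf("  F = %.3g /bp   Tr = %d  Tv = %d   A:T %.1f%%  G:C %.1f%%   ins %d  del %d\n",
              frequencyPerBp(object), object@transitions, object@transversions,
              100 * object@atFraction, 100 * object@gcFraction,
              object@insertionCount, object@deletionCount))
  print(object@subCounts)
})

#' Spatial distribution of mutations along the reference
#'
#' @param calls mutation-call data.frame with a `position` column; must be
#'   non-empty.
#' @param referenceLen reference length.
#' @param bin bin width in nt (default 1).
#' @return numeric vector of percentages of total mutations per bin; sums
#'   to 100.
#' @export
positionalDistribution <- function(calls, referenceLen, bin = 1L) {
  if (!nrow(calls)) stop("no mutation calls")
  nbins <- ceiling(referenceLen / bin)
  idx <- pmin(ceiling(calls$position / bin), nbins)
  counts <- tabulate(idx, nbins = nbins)
  100 * counts / sum(counts)
}

#' Compare two mutation spectra
#'
#' Pearson chi-squared over the 12 substitution classes (classes whose
#' expected count falls below 1 are pooled into a rest category) and a
#' two-tailed Fisher exact test on the indel 2x2 table (indel events vs
#' non-indel bases).
#'
#' @param a,b [MutationSpectrum] objects.
#' @return list with elements `chisq` (statistic, df, p) and `fisher`
#'   (p, oddsRatio) — the latter `NULL` when either spectrum has zero
#'   analyzed bases for indels.
#' @export
compareSpectra <- function(a, b) {
  va <- .spectrumVector(a); vb <- .spectrumVector(b)
  if (sum(va) == 0L || sum(vb) == 0L) stop("cannot compare an all-zero spectrum")
  chi <- chi2Test(rbind(a = va, b = vb), poolExpectedBelow = 1)
  indelA <- a@insertionCount + a@deletionCount
  indelB <- b@insertionCount + b@deletionCount
  fish <- fisherExact2x2(matrix(c(indelA, a@nBases - indelA,
                                  indelB, b@nBases - indelB),
                                nrow = 2, byrow = TRUE))
  list(chisq = chi, fisher = fish)
}

.spectrumVector <- function(x) {
  m <- x@subCounts
  v <- integer(0); nm <- character(0)
  for (i in .BASES) for (j in .BASES) if (i != j) {
    v <- c(v, m[i, j]); nm <- c(nm, paste0(i, ">", j))
  }
  setNames(v, nm)
}
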