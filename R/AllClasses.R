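#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet reverseComplement
#' @importFrom stats pchisq rbinom runif setNames dhyper
#' @importFrom utils write.table head tail
NULL

#' Germline switch-region reference set
#'
#' Holds the germline donor and acceptor switch-region sequences a junction
#' amplicon is segmented against, together with their provenance (accession)
#' and the 1-based genomic offset of each sequence's first base in that
#' accession's coordinate frame. Internal arithmetic is 0-based half-open;
#' every reported coordinate is 1-based inclusive in the accession frame.
#'
#' @slot sequences named [Biostrings::DNAStringSet] of uppercase sequences
#'   over A/C/G/T/N.
#' @slot accession named character vector, free-text provenance per region.
#' @slot genomicOffset named integer vector, 1-based position of each
#'   sequence's first base in its accession.
#' @slot donorName,acceptorName names of the donor (e.g. Smu) and acceptor
#'   (e.g. Sg1, Sg3) regions; must resolve to distinct records.
#'
#' @seealso [loadReferences()], [donorRegion()], [acceptorRegion()]
#' @export
setClass("SwitchRegionSet",
  slots = c(
    sequences     = "DNAStringSet",
    accession     = "character",
    genomicOffset = "integer",
    donorName     = "character",
    acceptorName  = "character"
  )
)

setValidity("SwitchRegionSet", function(object) {
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    return("region names must be present and unique")
  if (length(object@sequences) < 1L || any(Biostrings::width(object@sequences) == 0L))
    return("every region sequence must be non-empty")
  bad <- grepl("[^ACGTN]", as.character(object@sequences))
  if (any(bad))
    return(sprintf("non-DNA characters in region(s): %s", paste(nm[bad], collapse = ", ")))
  if (!identical(sort(names(object@accession)), sort(nm)) ||
      !identical(sort(names(object@genomicOffset)), sort(nm)))
    return("accession and genomicOffset must be named parallel to sequences")
  if (any(object@genomicOffset < 1L))
    return("genomicOffset must be >= 1")
  for (who in c(object@donorName, object@acceptorName))
    if (!who %in% nm)
      return(sprintf("region '%s' not present in the reference set", who))
  if (identical(object@donorName, object@acceptorName))
    return("donor and acceptor must be distinct regions")
  TRUE
})

#' Reconstructed architecture of one junction read
#'
#' The result of segmenting a read against a [SwitchRegionSet]: an ordered
#' set of reference fragments tiling the read left to right, and one resolved
#' boundary (blunt / microhomology / insertion) between each adjacent pair.
#' Uncallable reads (no donor or no acceptor fragment) carry their partial
#' matches with `callable = FALSE`.
#'
#' @slot readId read identifier.
#' @slot read the read sequence in the orientation that was called (reads are
#'   tried in both orientations; the one placing a forward-strand donor
#'   fragment first wins).
#' @slot callable logical; `FALSE` when no donor or no acceptor fragment was
#'   found.
#' @slot fragments data.frame, one row per fragment: `qstart`/`qend` (0-based
#'   half-open on the read), `region`, `rstart`/`rend` (0-based half-open on
#'   the region forward strand), `strand` ("+"/"-"), `mismatches`, `score`.
#' @slot boundaries data.frame, one row per adjacent fragment pair: `kind`
#'   ("blunt"/"microhomology"/"insertion"), `overlapLen`, `insertionSeq`,
#'   `leftBreakRef`/`rightBreakRef` (1-based genomic), `qWinStart`/`qWinEnd`
#'   (0-based half-open homology window on the read).
#' @slot unassignedPrefix,unassignedSuffix read end lengths not covered by
#'   any fragment.
#' @slot orientationFlipped `TRUE` when the reverse complement of the input
#'   read was called.
#' @export
setClass("JunctionCall",
  slots = c(
    readId            = "character",
    read              = "character",
    callable          = "logical",
    fragments         = "data.frame",
    boundaries        = "data.frame",
    unassignedPrefix  = "integer",
    unassignedSuffix  = "integer",
    orientationFlipped = "logical"
  )
)

setValidity("JunctionCall", function(object) {
  if (length(object@callable) != 1L) return("callable must be length 1")
  fr <- object@fragments
  if (object@callable) {
    if (nrow(fr) < 2L) return("a callable junction needs >= 2 fragments")
    if (nrow(object@boundaries) != nrow(fr) - 1L)
      return("boundaries must have exactly fragments - 1 rows")
    if (is.unsorted(fr$qstart, strictly = TRUE))
      return("fragments must be ordered left-to-right on the read")
    bad <- !object@boundaries$kind %in% c("blunt", "microhomology", "insertion")
    if (any(bad)) return("unknown boundary kind")
    b <- object@boundaries
    if (any(b$kind == "blunt" & (b$overlapLen != 0L | nzchar(b$insertionSeq))))
      return("blunt boundaries must have overlapLen 0 and empty insertionSeq")
    if (any(b$kind == "microhomology" & b$overlapLen < 1L))
      return("microhomology boundaries must have overlapLen >= 1")
    if (any(b$kind == "insertion" & (!nzchar(b$insertionSeq) | b$overlapLen != 0L)))
      return("insertion boundaries must carry the inserted sequence and overlapLen 0")
  }
  TRUE
})

#' Taxonomy assignment for one junction call
#'
#' Category (`simple` / `compound` / `uncallable`), atypical flags
#' (`microdeletion`, `long_microhomology`, `inversion`), the region/strand
#' architecture signature (e.g. `"Smu+,Smu+,Sg1+"`), the count of intra-region
#' recombination events and the per-sequence complexity score
#' (intra events + insertions + inversions + microdeletions).
#'
#' @seealso [classifyJunction()], [summarizeClasses()]
#' @export
setClass("JunctionClass",
  slots = c(
    readId        = "character",
    category      = "character",
    atypicalFlags = "character",
    architecture  = "character",
    intraEvents   = "integer",
    complexity    = "integer"
  )
)

setValidity("JunctionClass", function(object) {
  if (!object@category %in% c("simple", "compound", "uncallable"))
    return("category must be simple, compound or uncallable")
  if (!all(object@atypicalFlags %in% c("microdeletion", "long_microhomology", "inversion")))
    return("unknown atypical flag")
  if (object@complexity < 0L || object@intraEvents < 0L)
    return("complexity and intraEvents must be non-negative")
  TRUE
})

#' Somatic hypermutation spectrum for a clone set
#'
#' Twelve-class substitution counts (germline base x mutated base,
#' off-diagonal 4x4), indel counts, totals and the per-bp mutation frequency
#' F = total substitutions / (sequences x analyzed length).
#'
#' @slot subCounts 4x4 integer matrix (rows = germline base, cols = mutated
#'   base, A/C/G/T; diagonal zero).
#' @slot nSequences number of clones analyzed.
#' @slot nBases total analyzed bases (sequences x analyzed length, minus
#'   excluded columns).
#' @slot transitions,transversions substitution counts by class (transitions
#'   are A<->G and C<->T).
#' @slot atFraction,gcFraction fraction of substitutions at A:T / G:C pairs.
#' @slot insertionCount,deletionCount indel event counts.
#' @seealso [buildSpectrum()], [frequencyPerBp()]
#' @export
setClass("MutationSpectrum",
  slots = c(
    subCounts      = "matrix",
    nSequences     = "integer",
    nBases         = "numeric",
    transitions    = "integer",
    transversions  = "integer",
    atFraction     = "numeric",
    gcFraction     = "numeric",
    insertionCount = "integer",
    deletionCount  = "integer"
  )
)

setValidity("MutationSpectrum", function(object) {
  m <- object@subCounts
  if (!all(dim(m) == c(4L, 4L))) return("subCounts must be 4x4")
  if (any(diag(m) != 0L)) return("subCounts diagonal must be zero")
  if (any(m < 0L)) return("negative substitution counts")
  if (sum(m) != object@transitions + object@transversions)
    return("sum(subCounts) must equal transitions + transversions")
  if (object@nSequences < 1L || object@nBases < 1)
    return("nSequences and nBases must be positive")
  tot <- sum(m)
  if (tot > 0L && abs(object@atFraction + object@gcFraction - 1) > 1e-9)
    return("atFraction + gcFraction must be 1 when mutations are present")
  TRUE
})
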