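#' Load germline switch-region references from FASTA
#'
#' Reads a multi-record FASTA of germline switch-region sequences and builds a
#' validated [SwitchRegionSet]. Sequences are uppercased; the genomic offset
#' of each record is parsed from an optional `offset=<int>` key in the
#' description line (space-separated `key=value` pairs), defaulting to 1; an
#' optional `accession=<text>` key records provenance.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param donorName,acceptorName identifiers of the donor (e.g. `"Smu"`) and
#'   acceptor (e.g. `"Sg1"`) records; both must be present and distinct.
#' @return a [SwitchRegionSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">Smu offset=136645 accession=NC_000078.6", "ACGTACGTACGT",
#'              ">Sg1", "TTTTGGGGCCCC"), fa)
#' refs <- loadReferences(fa, donorName = "Smu", acceptorName = "Sg1")
#' genomicOffset(refs)[["Smu"]]
#' @export
loadReferences <- function(path, donorName, acceptorName) {
  if (!file.exists(path))
    stop("reference FASTA not found: ", path)
  ## parsed as text (not via a sequence importer) so that invalid characters
  ## are reported with their position instead of being silently dropped
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr))
    stop("no records in reference FASTA: ", path)
  desc <- sub("^>", "", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  rawSeq <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("[ \t\r]", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, character(1))
  ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L)
  kv <- lapply(strsplit(desc, "\\s+"), function(tok) {
    tok <- tok[-1]
    tok <- tok[grepl("=", tok, fixed = TRUE)]
    if (!length(tok)) return(character(0))
    sp <- regmatches(tok, regexpr("=", tok), invert = TRUE)
    setNames(vapply(sp, `[`, character(1), 2L), vapply(sp, `[`, character(1), 1L))
  })
  off <- vapply(kv, function(x) {
    if ("offset" %in% names(x)) {
      v <- suppressWarnings(as.integer(x[["offset"]]))
      if (is.na(v)) stop("non-integer offset= value in FASTA description")
      v
    } else 1L
  }, integer(1))
  acc <- vapply(kv, function(x) if ("accession" %in% names(x)) x[["accession"]] else "", character(1))
  for (who in c(donorName, acceptorName))
    if (!who %in% ids)
      stop("requested region '", who, "' is absent from ", path,
           " (records: ", paste(ids, collapse = ", "), ")")
  chr <- toupper(rawSeq)
  badAt <- regexpr("[^ACGTN]", chr)
  if (any(badAt > 0L)) {
    i <- which(badAt > 0L)[1]
    stop(sprintf("non-DNA character in record '%s' at position %d", ids[i], badAt[i]))
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  methods::new("SwitchRegionSet",
    sequences = out,
    accession = setNames(acc, ids),
    genomicOffset = setNames(off, ids),
    donorName = donorName, acceptorName = acceptorName)
}

#' Build a SwitchRegionSet from in-memory sequences
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param donorName,acceptorName donor / acceptor record names.
#' @param genomicOffset named integer vector of 1-based offsets (default 1).
#' @param accession named character vector of provenance strings (default "").
#' @return a [SwitchRegionSet].
#' @export
switchRegionSet <- function(sequences, donorName, acceptorName,
                            genomicOffset = NULL, accession = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(toupper(sequences))
  nm <- names(sequences)
  if (is.null(genomicOffset)) genomicOffset <- setNames(rep(1L, length(nm)), nm)
  if (is.null(accession)) accession <- setNames(rep("", length(nm)), nm)
  methods::new("SwitchRegionSet",
    sequences = sequences,
    accession = accession[nm],
    genomicOffset = as.integer(genomicOffset[nm]) |> setNames(nm),
    donorName = donorName, acceptorName = acceptorName)
}

#' Write a SwitchRegionSet to FASTA (round-trips offset/accession keys)
#'
#' @param refs a [SwitchRegionSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReferences <- function(refs, path) {
  seqs <- refs@sequences
  desc <- sprintf("%s offset=%d%s", names(seqs), refs@genomicOffset[names(seqs)],
                  ifelse(nzchar(refs@accession[names(seqs)]),
                         paste0(" accession=", refs@accession[names(seqs)]), ""))
  out <- seqs
  names(out) <- desc
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' @rdname SwitchRegionSet-accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname SwitchRegionSet-accessors
#' @export
setGeneric("regionSequence", function(x, name) standardGeneric("regionSequence"))
#' @rdname SwitchRegionSet-accessors
#' @export
setGeneric("genomicOffset", function(x) standardGeneric("genomicOffset"))
#' @rdname SwitchRegionSet-accessors
#' @export
setGeneric("donorName", function(x) standardGeneric("donorName"))
#' @rdname SwitchRegionSet-accessors
#' @export
setGeneric("acceptorName", function(x) standardGeneric("acceptorName"))

#' Accessors for SwitchRegionSet
#'
#' @param x a [SwitchRegionSet].
#' @param name region identifier.
#' @name SwitchRegionSet-accessors
NULL

#' @rdname SwitchRegionSet-accessors
setMethod("regionNames", "SwitchRegionSet", function(x) names(x@sequences))
#' @rdname SwitchRegionSet-accessors
setMethod("regionSequence", "SwitchRegionSet", function(x, name) {
  if (!name %in% names(x@sequences)) stop("no region named '", name, "'")
  as.character(x@sequences[[name]])
})
#' @rdname SwitchRegionSet-accessors
setMethod("genomicOffset", "SwitchRegionSet", function(x) x@genomicOffset)
#' @rdname SwitchRegionSet-accessors
setMethod("donorName", "SwitchRegionSet", function(x) x@donorName)
#' @rdname SwitchRegionSet-accessors
setMethod("acceptorName", "SwitchRegionSet", function(x) x@acceptorName)

#' @describeIn SwitchRegionSet-accessors donor record sequence as a character
#'   string.
#' @export
donorRegion <- function(x) regionSequence(x, x@donorName)

#' @describeIn SwitchRegionSet-accessors acceptor record sequence as a
#'   character string.
#' @export
acceptorRegion <- function(x) regionSequence(x, x@acceptorName)

setMethod("show", "SwitchRegionSet", function(object) {
  cat("SwitchRegionSet with", length(object@sequences), "region(s)\n")
  for (nm in names(object@sequences)) {
    role <- if (nm == object@donorName) "donor"
            else if (nm == object@acceptorName) "acceptor" else "other"
    cat(sprintf("  %-8s %6d nt  offset %-9d %-8s %s\n", nm,
                Biostrings::width(object@sequences[nm]),
                object@genomicOffset[[nm]], role, object@accession[[nm]]))
  }
})

#' Reverse complement of a DNA string
#'
#' Standard reverse complement over the A/C/G/T/N alphabet (N maps to N);
#' an involution. Needed to detect inverted fragments inside compound
#' junctions.
#'
#' @param seq a DNA character string.
#' @return the reverse complement, same length.
#' @examples
#' revComp("AAAC")  # "GTTT"
#' @export
revComp <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("seq must be a single string")
  if (grepl("[^ACGTNacgtn]", seq)) stop("revComp: sequence contains non-DNA characters")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

## ---- coordinate conventions -------------------------------------------------
## Internal: 0-based half-open on the region's forward strand.
## Reported: 1-based inclusive in the accession frame via genomicOffset.

#' Convert a local 0-based half-open interval to genomic 1-based inclusive
#'
#' @param refs a [SwitchRegionSet].
#' @param region region name.
#' @param start0,end0 0-based half-open local interval.
#' @return integer vector `c(start, end)`, 1-based inclusive genomic.
#' @export
localToGenomic <- function(refs, region, start0, end0) {
  if (end0 <= start0) stop("empty interval")
  off <- refs@genomicOffset[[region]]
  c(off + start0, off + end0 - 1L)
}

#' Convert a genomic 1-based inclusive interval back to local 0-based half-open
#'
#' @param refs a [SwitchRegionSet].
#' @param region region name.
#' @param start1,end1 1-based inclusive genomic interval.
#' @return integer vector `c(start0, end0)`, 0-based half-open local.
#' @export
genomicToLocal <- function(refs, region, start1, end1) {
  off <- refs@genomicOffset[[region]]
  c(start1 - off, end1 - off + 1L)
}
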