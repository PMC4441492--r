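## End-to-end orchestration: dedup -> call -> classify -> stats, with
## plain-text TSV/JSON outputs so externally transcribed sequence data can be
## diffed against reports, and a wild-type-vs-knockout style group comparison.

#' Run the junction analysis pipeline
#'
#' Executes dedup -> call -> classify -> overlap statistics on a read set and
#' (optionally) writes the junctions TSV, class TSV, overlap-summary JSON,
#' class-summary JSON, three-wise text renders and a run log of effective
#' parameter values into `outDir`. Rerunning with the same inputs and
#' parameters reproduces the outputs byte for byte.
#'
#' @param reads FASTA path, named character vector or
#'   [Biostrings::DNAStringSet] of junction amplicon reads.
#' @param refs FASTA path (then `donorName`/`acceptorName` are required) or a
#'   [SwitchRegionSet].
#' @param outDir output directory (created); `NULL` writes nothing.
#' @param params caller parameters, see [junctionParams()].
#' @param longMhThreshold,microdelMin,microdelMax classifier thresholds, see
#'   [classifyJunction()].
#' @param mhBinMax overlap histogram top bin, see [meanOverlap()].
#' @param donorName,acceptorName used only when `refs` is a FASTA path.
#' @return a report bundle (list): `calls`, `classes`, `junctions`
#'   (data.frame), `classTable` (data.frame), `overlap` (`OverlapSummary`),
#'   `classSummary`, `params`, `nInput`, `nAfterDedup`.
#' @export
runPipeline <- function(reads, refs, outDir = NULL, params = junctionParams(),
                        longMhThreshold = 15L, microdelMin = 1L, microdelMax = 50L,
                        mhBinMax = 15L, donorName = NULL, acceptorName = NULL) {
  if (is.character(refs) && length(refs) == 1L) {
    if (is.null(donorName) || is.null(acceptorName))
      stop("donorName and acceptorName are required when refs is a FASTA path")
    refs <- loadReferences(refs, donorName, acceptorName)
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (methods::is(reads, "DNAStringSet")) {
    nms <- vapply(strsplit(names(reads), "\\s+"), `[`, character(1), 1L)
    reads <- setNames(as.character(reads), nms)
  }
  if (!length(reads)) stop("no reads supplied")
  if (is.null(names(reads))) names(reads) <- sprintf("read%04d", seq_along(reads))

  nInput <- length(reads)
  reads <- dedupReads(reads)
  calls <- callJunctions(reads, refs, params)
  classes <- lapply(calls, classifyJunction, refs = refs,
                    longMhThreshold = longMhThreshold,
                    microdelMin = microdelMin, microdelMax = microdelMax)
  jt <- junctionTable(calls, refs)
  ct <- classTable(classes)
  scored <- jt[!is.na(jt$kind), , drop = FALSE]
  overlap <- if (nrow(scored))
    meanOverlap(data.frame(kind = scored$kind, overlapLen = scored$OL), mhBinMax)
  else NULL
  classSummary <- summarizeClasses(classes)

  bundle <- list(calls = calls, classes = classes, junctions = jt,
                 classTable = ct, overlap = overlap, classSummary = classSummary,
                 params = c(params, longMhThreshold = longMhThreshold,
                            microdelMin = microdelMin, microdelMax = microdelMax,
                            mhBinMax = mhBinMax),
                 nInput = nInput, nAfterDedup = length(reads))
  if (!is.null(outDir)) .writeBundle(bundle, refs, outDir)
  bundle
}

.writeBundle <- function(bundle, refs, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f) write.table(df, file.path(outDir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  tsv(bundle$junctions, "junctions.tsv")
  tsv(bundle$classTable, "classes.tsv")
  ov <- bundle$overlap
  if (!is.null(ov))
    jsonlite::write_json(
      list(nJunctions = ov$nJunctions, nWithInsertion = ov$nWithInsertion,
           meanOverlap = ov$meanOverlap, histogram = as.list(ov$histogram)),
      file.path(outDir, "overlap_summary.json"), auto_unbox = TRUE, digits = NA)
  cs <- bundle$classSummary
  cs$flagCounts <- as.list(cs$flagCounts)
  jsonlite::write_json(cs, file.path(outDir, "class_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  renders <- vapply(bundle$calls, function(cl)
    renderThreewise(cl, refs), character(1))
  writeLines(paste(renders, collapse = "\n"), file.path(outDir, "threewise.txt"))
  writeLines(c("switchjunction run log",
               sprintf("package version: %s",
                       as.character(utils::packageVersion("switchjunction"))),
               sprintf("reads in / after dedup: %d / %d", bundle$nInput,
                       bundle$nAfterDedup),
               "effective parameters:",
               sprintf("  %s = %s", names(bundle$params),
                       vapply(bundle$params, function(x) paste(x, collapse = ","),
                              character(1)))),
             file.path(outDir, "run.log"))
  invisible(outDir)
}

#' Compare two pipeline report bundles (wild-type vs knockout style)
#'
#' Emits the group comparison: difference of mean overlaps, chi-squared on
#' the binned OL histograms, Fisher exact tests on the compound fraction and
#' on atypical-among-compound counts, and the fold change of mean compound
#' complexity.
#'
#' @param runA,runB report bundles from [runPipeline()] (same `mhBinMax`).
#' @return list: `deltaMeanOverlap` (B - A), `overlapChisq`,
#'   `compoundFisher`, `atypicalFisher`, `complexityFold` (B / A), and the
#'   per-group summaries.
#' @export
compareGroups <- function(runA, runB) {
  if (is.null(runA$overlap) || is.null(runB$overlap))
    stop("both runs need scored junctions")
  ov <- compareOverlapDistributions(runA$overlap, runB$overlap)
  a <- runA$classSummary; b <- runB$classSummary
  compound <- fisherExact2x2(matrix(c(a$nCompound, a$nSimple,
                                      b$nCompound, b$nSimple), 2, byrow = TRUE))
  ## the atypical contrast is conditional on compound junctions existing
  atyp <- if (a$nCompound + b$nCompound > 0L)
    fisherExact2x2(matrix(c(a$nAtypicalCompound, a$nCompound - a$nAtypicalCompound,
                            b$nAtypicalCompound, b$nCompound - b$nAtypicalCompound),
                          2, byrow = TRUE))
  else list(p = NA_real_, pOneTailed = NA_real_, oddsRatio = NaN,
            method = "not testable: no compound junctions in either group")
  list(deltaMeanOverlap = ov$meanDifference,
       overlapChisq = ov$chisq,
       compoundFisher = compound,
       atypicalFisher = atyp,
       complexityFold = b$meanComplexityCompound / a$meanComplexityCompound,
       summaryA = a, summaryB = b)
}
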