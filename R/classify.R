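## Junction taxonomy: simple (the single expected donor-to-acceptor event,
## both fragments forward) vs compound (additional intra-switch recombination
## events: donor-donor-acceptor, donor-acceptor-acceptor, ...), with atypical
## flags for microdeletions, long microhomologies and inversions, and the
## per-sequence complexity score.

#' Classify one junction call
#'
#' A call is `simple` iff it has exactly two fragments, donor then acceptor,
#' both on the forward strand; anything else callable is `compound`.
#' Atypical flags: `inversion` iff any fragment is on the reverse strand;
#' `microdeletion` iff two adjacent fragments map to the same region and
#' strand with a reference-coordinate gap in `[microdelMin, microdelMax]`
#' (larger same-region gaps count as intra-switch recombination events, not
#' microdeletions); `long_microhomology` iff any boundary overlap is at least
#' `longMhThreshold`. `intraEvents` counts adjacent same-region fragment
#' pairs (same-region pairs with overlapping reference intervals, i.e.
#' duplications, count here too). Complexity = intraEvents + insertions +
#' inversions + microdeletions.
#'
#' @param call a [JunctionCall].
#' @param refs a [SwitchRegionSet].
#' @param longMhThreshold minimum overlap called a long microhomology
#'   (default 15 nt).
#' @param microdelMin,microdelMax same-region reference gap range called a
#'   microdeletion (defaults 1 and 50 nt).
#' @return a [JunctionClass].
#' @export
classifyJunction <- function(call, refs, longMhThreshold = 15L,
                             microdelMin = 1L, microdelMax = 50L) {
  if (!call@callable)
    return(methods::new("JunctionClass", readId = call@readId,
                        category = "uncallable", atypicalFlags = character(0),
                        architecture = "", intraEvents = 0L, complexity = 0L))
  fr <- call@fragments
  b <- call@boundaries
  arch <- paste0(fr$region, fr$strand, collapse = ",")
  simple <- nrow(fr) == 2L &&
    fr$region[1] == refs@donorName && fr$region[2] == refs@acceptorName &&
    all(fr$strand == "+")

  nInv <- sum(fr$strand == "-")
  nIns <- sum(b$kind == "insertion")
  intra <- 0L
  nMicrodel <- 0L
  for (i in seq_len(nrow(fr) - 1L)) {
    if (fr$region[i] != fr$region[i + 1L]) next
    intra <- intra + 1L
    if (fr$strand[i] == fr$strand[i + 1L]) {
      gap <- if (fr$strand[i] == "+") fr$rstart[i + 1L] - fr$rend[i]
             else fr$rstart[i] - fr$rend[i + 1L]
      if (gap >= microdelMin && gap <= microdelMax) nMicrodel <- nMicrodel + 1L
    }
  }
  flags <- character(0)
  if (nMicrodel > 0L) flags <- c(flags, "microdeletion")
  if (any(b$overlapLen >= longMhThreshold)) flags <- c(flags, "long_microhomology")
  if (nInv > 0L) flags <- c(flags, "inversion")

  ## an insertion at the single inter-switch seam does not make a junction
  ## compound; simple junctions carry complexity 0 by definition
  methods::new("JunctionClass",
    readId = call@readId,
    category = if (simple) "simple" else "compound",
    atypicalFlags = flags,
    architecture = arch,
    intraEvents = intra,
    complexity = if (simple) 0L else intra + nIns + nInv + nMicrodel)
}

#' Summarize a set of junction classifications
#'
#' @param classes list of [JunctionClass].
#' @return a list: `n` (callable junctions), `nUncallable`, `nSimple`,
#'   `nCompound`, `compoundFraction` (compound / callable),
#'   `nAtypicalCompound`, `atypicalAmongCompound`, `meanComplexityCompound`,
#'   `flagCounts` (named vector over the three atypical flags).
#' @export
summarizeClasses <- function(classes) {
  if (!length(classes)) stop("empty class list")
  cat_ <- vapply(classes, function(x) x@category, character(1))
  callable <- cat_ != "uncallable"
  nSimple <- sum(cat_ == "simple")
  nCompound <- sum(cat_ == "compound")
  n <- nSimple + nCompound
  if (n == 0L) stop("no callable junctions to summarize")
  isAty <- vapply(classes, function(x)
    x@category == "compound" && length(x@atypicalFlags) > 0L, logical(1))
  cx <- vapply(classes, function(x)
    if (x@category == "compound") as.numeric(x@complexity) else NA_real_, numeric(1))
  flagCounts <- c(microdeletion = 0L, long_microhomology = 0L, inversion = 0L)
  for (x in classes) for (f in x@atypicalFlags) flagCounts[[f]] <- flagCounts[[f]] + 1L
  list(n = n,
       nUncallable = sum(!callable),
       nSimple = nSimple,
       nCompound = nCompound,
       compoundFraction = nCompound / n,
       nAtypicalCompound = sum(isAty),
       atypicalAmongCompound = if (nCompound > 0L) sum(isAty) / nCompound else NA_real_,
       meanComplexityCompound = if (nCompound > 0L) mean(cx, na.rm = TRUE) else NA_real_,
       flagCounts = flagCounts)
}

#' Tabulate junction classifications
#'
#' @param classes list of [JunctionClass].
#' @return data.frame: `readId`, `category`, `flags` (comma-joined),
#'   `intraEvents`, `complexity`, `architecture`.
#' @export
classTable <- function(classes) {
  out <- do.call(rbind, lapply(classes, function(x)
    data.frame(readId = x@readId, category = x@category,
               flags = paste(x@atypicalFlags, collapse = ","),
               intraEvents = x@intraEvents, complexity = x@complexity,
               architecture = x@architecture)))
  rownames(out) <- NULL
  out
}

setMethod("show", "JunctionClass", function(object) {
  cat(sprintf("JunctionClass '%s': %s [%s]%s  intraEvents=%d complexity=%d\n",
              object@readId, object@category, object@architecture,
              if (length(object@atypicalFlags))
                paste0(" {", paste(object@atypicalFlags, collapse = ", "), "}")
              else "",
              object@intraEvents, object@complexity))
})
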