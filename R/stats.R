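## The study's statistical toolbox: exact two-tailed Fisher test
## (point-probability tail definition), Pearson chi-squared with
## small-expected-count pooling, overlap summaries excluding insertions, and
## ratio normalization with error propagation in quadrature.

#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Two-tailed p = sum of hypergeometric probabilities of all tables with the
#' same margins whose probability is at most that of the observed table (the
#' point-probability / minimum-likelihood tail definition, the convention of
#' mainstream statistical software). The odds ratio reported is the sample
#' cross-product ratio ad/bc.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return list: `p` (two-tailed), `pOneTailed` (smaller tail), `oddsRatio`,
#'   `method`.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p  # 1
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("fisherExact2x2 needs a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 + r2 == 0) stop("empty table")
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  k <- lo:hi
  pk <- dhyper(k, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  p <- sum(pk[pk <= pObs * (1 + 1e-7)])
  pLow <- sum(pk[k <= a]); pHigh <- sum(pk[k >= a])
  orr <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NaN
  list(p = min(1, p), pOneTailed = min(1, min(pLow, pHigh)), oddsRatio = orr,
       method = "Fisher exact, two-tailed (point-probability)")
}

#' Pearson chi-squared test with small-expected-count pooling
#'
#' Computes the plain Pearson statistic sum((O-E)^2/E) on an r x c table
#' (no continuity correction). Zero-margin rows/columns are dropped with a
#' warning. Columns whose expected count falls below `poolExpectedBelow` in
#' any row are pooled: into the adjacent higher column for ordered histograms
#' (`ordered = TRUE`, the overlap-length binning case) or into a single rest
#' column otherwise. Degrees of freedom are (r-1)(c-1) after pooling.
#'
#' @param table r x c non-negative matrix (rows = groups).
#' @param poolExpectedBelow pooling threshold on expected counts (default 1;
#'   set to 0 to disable).
#' @param ordered treat columns as ordered bins and pool into the adjacent
#'   higher bin (default `FALSE`).
#' @return list: `statistic`, `df`, `p`, `table` (the table actually tested).
#' @export
chi2Test <- function(table, poolExpectedBelow = 1, ordered = FALSE) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("negative counts")
  keepR <- rowSums(m) > 0; keepC <- colSums(m) > 0
  if (!all(keepR) || !all(keepC)) {
    warning("dropping zero-margin row(s)/column(s)")
    m <- m[keepR, keepC, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) stop("degenerate table after dropping zero margins")

  expected <- function(x) outer(rowSums(x), colSums(x)) / sum(x)
  if (poolExpectedBelow > 0) {
    repeat {
      E <- expected(m)
      bad <- which(apply(E, 2, min) < poolExpectedBelow)
      if (!length(bad) || ncol(m) <= 2L) break
      j <- bad[length(bad)]            # pool the highest offending column
      into <- if (ordered) (if (j < ncol(m)) j + 1L else j - 1L)
              else (if (j < ncol(m)) ncol(m) else ncol(m) - 1L)
      m[, into] <- m[, into] + m[, j]
      m <- m[, -j, drop = FALSE]
    }
  }
  E <- expected(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE), table = m)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson statistic of observed counts against expected proportions, with
#' cells whose expected count falls below `poolExpectedBelow` pooled into the
#' adjacent higher cell. df = cells - 1 after pooling.
#'
#' @param observed non-negative count vector.
#' @param expectedProbs expected proportions (default uniform); recycled /
#'   normalized to sum 1.
#' @param poolExpectedBelow pooling threshold (default 1).
#' @return list: `statistic`, `df`, `p`.
#' @export
chi2GoF <- function(observed, expectedProbs = NULL, poolExpectedBelow = 1) {
  o <- as.numeric(observed)
  if (any(o < 0)) stop("negative counts")
  n <- sum(o)
  if (n == 0) stop("empty observed vector")
  p <- if (is.null(expectedProbs)) rep(1 / length(o), length(o))
       else expectedProbs / sum(expectedProbs)
  if (length(p) != length(o)) stop("observed and expectedProbs lengths differ")
  e <- n * p
  while (any(e < poolExpectedBelow) && length(o) > 2L) {
    j <- max(which(e < poolExpectedBelow))
    into <- if (j < length(o)) j + 1L else j - 1L
    o[into] <- o[into] + o[j]; e[into] <- e[into] + e[j]
    o <- o[-j]; e <- e[-j]
  }
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Ratio of two measured quantities with propagated standard deviation
#'
#' value = num/den; relative errors add in quadrature:
#' sd = |value| * sqrt((sd_num/num)^2 + (sd_den/den)^2). A zero numerator is
#' handled as sd = sd_num/|den|. Used to normalize qPCR / ChIP quantities to
#' a control (e.g. expression relative to a housekeeping gene, fold-change to
#' input) while carrying measurement error through the division.
#'
#' @param num,den lists with elements `value` and `sd` (see [ratioSD()]).
#' @return list with `value` and `sd`.
#' @examples
#' ratioWithPropagatedSD(ratioSD(2, 0.2), ratioSD(1, 0.1))
#' @export
ratioWithPropagatedSD <- function(num, den) {
  stopifnot(is.finite(num$value), is.finite(den$value), num$sd >= 0, den$sd >= 0)
  if (den$value == 0) stop("zero denominator")
  v <- num$value / den$value
  s <- if (num$value == 0) num$sd / abs(den$value)
       else abs(v) * sqrt((num$sd / num$value)^2 + (den$sd / den$value)^2)
  ratioSD(v, s)
}

#' Construct a value-with-sd pair
#' @param value measured value.
#' @param sd its standard deviation (>= 0).
#' @export
ratioSD <- function(value, sd = 0) {
  stopifnot(sd >= 0)
  structure(list(value = value, sd = sd), class = "ratioSD")
}

#' @export
print.ratioSD <- function(x, ...) {
  cat(sprintf("%g +/- %g\n", x$value, x$sd))
  invisible(x)
}

#' Summarize junction overlaps, excluding insertions
#'
#' Mean overlap is computed over blunt (OL = 0) and microhomology boundaries;
#' junctions with an insertion at the boundary are excluded from the mean and
#' from the histogram (counted in `nWithInsertion` only). The histogram bins
#' OL as 0, 1, ..., `mhBinMax - 1`, `>= mhBinMax`; the default top bin
#' (>= 15 nt) corresponds to the long-microhomology emphasis.
#'
#' @param boundaries data.frame of boundary calls with columns `kind` and
#'   `overlapLen` — one scored (inter-switch) boundary per junction.
#' @param mhBinMax lower edge of the open top histogram bin (default 15).
#' @return an `OverlapSummary` list: `nJunctions`, `nWithInsertion`,
#'   `meanOverlap` (NA and flagged when every boundary is an insertion),
#'   `histogram` (named counts), `mhBinMax`.
#' @export
meanOverlap <- function(boundaries, mhBinMax = 15L) {
  if (!nrow(boundaries)) stop("no boundaries")
  ins <- boundaries$kind == "insertion"
  ol <- boundaries$overlapLen[!ins]
  binned <- pmin(ol, mhBinMax)
  h <- tabulate(binned + 1L, nbins = mhBinMax + 1L)
  names(h) <- c(as.character(0:(mhBinMax - 1L)), paste0(">=", mhBinMax))
  structure(list(
    nJunctions = nrow(boundaries),
    nWithInsertion = sum(ins),
    meanOverlap = if (length(ol)) mean(ol) else NA_real_,
    allInsertions = !length(ol),
    histogram = h,
    mhBinMax = as.integer(mhBinMax)), class = "OverlapSummary")
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf("OverlapSummary: n = %d junctions (%d with insertion excluded)\n",
              x$nJunctions, x$nWithInsertion))
  if (x$allInsertions) cat("  mean overlap undefined (all boundaries are insertions)\n")
  else cat(sprintf("  mean overlap = %.2f bp\n", x$meanOverlap))
  print(x$histogram)
  invisible(x)
}

#' Compare two overlap distributions
#'
#' Chi-squared on the two OL histograms stacked as a 2 x k table (empty /
#' small-expected bins pooled into the adjacent higher bin), plus the
#' difference of mean overlaps.
#'
#' @param a,b `OverlapSummary` objects with identical binning.
#' @return list: `chisq` (see [chi2Test()]), `meanDifference` (b - a).
#' @export
compareOverlapDistributions <- function(a, b) {
  if (a$mhBinMax != b$mhBinMax) stop("incompatible overlap binnings")
  tab <- rbind(a = a$histogram, b = b$histogram)
  if (all(colSums(tab) == 0)) stop("degenerate histograms")
  list(chisq = chi2Test(tab, poolExpectedBelow = 1, ordered = TRUE),
       meanDifference = b$meanOverlap - a$meanOverlap)
}
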