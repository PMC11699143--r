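#' Fragment-length histogram within regions
#'
#' Histogram of the lengths of fragments whose midpoint lies in one of the
#' regions (overlapping regions are merged with a warning), plus the
#' region-restricted NRS at `breakpoint` computed from those same
#' midpoint-assigned fragments: `a` = fragments of length >= breakpoint,
#' `b` = shorter ones. Peak regions are typically sub-bin scale, so the
#' region NRS works from fragments directly, not from bin tracks.
#'
#' @param frags a [FragmentSet-class].
#' @param regions a [GenomicRanges::GRanges] of regions (e.g. ChIP peaks;
#'   only chrom/start/end are used).
#' @param breakpoint break point (bp) for the region NRS; default 140.
#' @param binWidth histogram bin width in bp; default 1.
#' @param regionLabel free-text label carried on the result.
#' @return a [LengthHistogram-class].
#' @export
regionLengthHistogram <- function(frags, regions, breakpoint = 140,
                                  binWidth = 1, regionLabel = "") {
  if (length(regions) == 0L) stop("empty region set")
  red <- reduce(regions, ignore.strand = TRUE)
  if (length(red) < length(regions))
    warning("overlapping regions merged: ", length(regions), " -> ",
            length(red))
  gr <- fragRanges(frags)
  mid0 <- (start(gr) - 1 + end(gr)) %/% 2
  pts <- GRanges(as.character(seqnames(gr)),
                 IRanges(start = mid0 + 1, width = 1L))
  inReg <- IRanges::overlapsAny(pts, red, ignore.strand = TRUE)
  len <- width(gr)[inReg]
  if (length(len)) {
    lo <- floor(min(len) / binWidth) * binWidth
    hi <- ceiling((max(len) + 1) / binWidth) * binWidth
    breaks <- seq(lo, hi, by = binWidth)
    counts <- as.numeric(table(cut(len, breaks = breaks, right = FALSE)))
    a <- sum(len >= breakpoint); b <- sum(len < breakpoint)
    nrsVal <- (a - b) / (a + b)
  } else {
    breaks <- numeric(0); counts <- numeric(0); nrsVal <- NA_real_
  }
  new("LengthHistogram", breaks = breaks, counts = counts,
      region = regionLabel, nrs = nrsVal, breakpoint = breakpoint)
}

setMethod("show", "LengthHistogram", function(object) {
  cat("LengthHistogram:", sum(object@counts), "fragments",
      if (nzchar(object@region)) paste0("in '", object@region, "'") else "",
      sprintf("; NRS(%g) = %.4f\n", object@breakpoint, object@nrs))
})

#' Normalized length density
#'
#' @param x a [LengthHistogram-class].
#' @return numeric density per histogram bin (sums to 1).
#' @export
lengthDensity <- function(x) {
  tot <- sum(x@counts)
  if (tot == 0) stop("empty histogram")
  x@counts / tot
}

#' Per-domain parental-vs-nascent NRS difference
#'
#' For each domain, `delta = mean(nascent NRS) - mean(parental NRS)` over
#' the domain's bins, with bin-level pairing: bins missing in either track
#' are excluded from both means. Within one digestion, parental and nascent
#' NRS are directly comparable, so the difference is taken on NRS rather
#' than NRI.
#'
#' @param parental,nascent NRS [SignalTrack-class] objects on one layout.
#' @param domains a [DomainSet-class].
#' @return data.frame: chrom, start (0-based), end, label, parentalMean,
#'   nascentMean, delta, nBins. Domains with zero paired bins get NA with a
#'   warning.
#' @export
nrsDifference <- function(parental, nascent, domains) {
  .stopIfLayoutMismatch(genomeLayout(parental), genomeLayout(nascent))
  layout <- genomeLayout(parental)
  bins <- binRanges(layout)
  vp <- trackValues(parental); vn <- trackValues(nascent)
  dgr <- domainRanges(domains)
  hits <- findOverlaps(bins, dgr, minoverlap = 1L)
  out <- data.frame(chrom = as.character(seqnames(dgr)),
                    start = start(dgr) - 1, end = end(dgr),
                    label = mcols(dgr)$label,
                    parentalMean = NA_real_, nascentMean = NA_real_,
                    delta = NA_real_, nBins = 0L)
  for (d in seq_along(dgr)) {
    bi <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == d]
    ok <- bi[!is.na(vp[bi]) & !is.na(vn[bi])]
    out$nBins[d] <- length(ok)
    if (length(ok)) {
      out$parentalMean[d] <- mean(vp[ok])
      out$nascentMean[d] <- mean(vn[ok])
      out$delta[d] <- out$nascentMean[d] - out$parentalMean[d]
    }
  }
  if (any(out$nBins == 0L))
    warning(sum(out$nBins == 0L), " domain(s) with zero paired bins: delta NA")
  out
}

#' Per-domain NRS difference from pooled counts
#'
#' Alternative to [nrsDifference()]: instead of averaging per-bin NRS, the
#' length-group counts are pooled over each domain's bins and NRS is
#' recomputed from the pooled a/b sums, for each of the two conditions.
#'
#' @param parentalCounts,nascentCounts [BinCountMatrix-class] objects on one
#'   layout and scheme.
#' @param domains a [DomainSet-class].
#' @param breakpoint break point (bp).
#' @return data.frame as in [nrsDifference()].
#' @export
nrsDifferencePooled <- function(parentalCounts, nascentCounts, domains,
                                breakpoint = 140) {
  .stopIfLayoutMismatch(genomeLayout(parentalCounts),
                        genomeLayout(nascentCounts))
  layout <- genomeLayout(parentalCounts)
  scheme <- lengthScheme(parentalCounts)
  b <- boundaries(scheme)
  if (!breakpoint %in% b)
    stop("breakpoint must be a boundary of the counting scheme")
  lower <- b[-length(b)]
  aCols <- which(lower >= breakpoint)
  bins <- binRanges(layout)
  dgr <- domainRanges(domains)
  hits <- findOverlaps(bins, dgr, minoverlap = 1L)
  mp <- assay(parentalCounts, "counts")
  mn <- assay(nascentCounts, "counts")
  poolNrs <- function(m, bi) {
    a <- sum(m[bi, aCols, drop = FALSE])
    tot <- sum(m[bi, , drop = FALSE])
    if (tot == 0) NA_real_ else (2 * a - tot) / tot
  }
  out <- data.frame(chrom = as.character(seqnames(dgr)),
                    start = start(dgr) - 1, end = end(dgr),
                    label = mcols(dgr)$label,
                    parentalMean = NA_real_, nascentMean = NA_real_,
                    delta = NA_real_, nBins = 0L)
  for (d in seq_along(dgr)) {
    bi <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == d]
    out$nBins[d] <- length(bi)
    out$parentalMean[d] <- poolNrs(mp, bi)
    out$nascentMean[d] <- poolNrs(mn, bi)
    out$delta[d] <- out$nascentMean[d] - out$parentalMean[d]
  }
  out
}
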