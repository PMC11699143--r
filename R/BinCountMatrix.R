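#' Construct a BinCountMatrix
#'
#' @param counts integer matrix, bins x length groups, in layout/bin order.
#' @param layout a [GenomeLayout-class].
#' @param scheme a [LengthGroupScheme-class].
#' @return a [BinCountMatrix-class] (a RangedSummarizedExperiment whose rows
#'   are the layout bins and whose columns are the length groups).
#' @export
BinCountMatrix <- function(counts, layout, scheme) {
  stopifnot(nrow(counts) == nBins(layout),
            ncol(counts) == .nGroups(scheme))
  colnames(counts) <- .groupLabels(scheme)
  b <- boundaries(scheme)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = binRanges(layout),
    colData = DataFrame(lower = b[-length(b)], upper = b[-1L],
                        row.names = .groupLabels(scheme)))
  metadata(se) <- list(layout = layout, scheme = scheme)
  new("BinCountMatrix", se)
}

#' @rdname BinCountMatrix-class
#' @export
setMethod("genomeLayout", "BinCountMatrix", function(x) metadata(x)$layout)

#' @rdname BinCountMatrix-class
#' @export
setMethod("lengthScheme", "BinCountMatrix", function(x) metadata(x)$scheme)

#' Count fragments per bin per length group
#'
#' In the default `"overlap"` mode a fragment increments every bin it
#' overlaps by at least 1 bp (the behaviour of bedtools-style annotation);
#' `"midpoint"` mode assigns each fragment to the single bin containing its
#' midpoint. Ungrouped fragments (length outside the scheme) are not
#' counted.
#'
#' @param frags a [FragmentSet-class].
#' @param layout a [GenomeLayout-class]; fragment chromosomes must all be
#'   present in it.
#' @param scheme a [LengthGroupScheme-class].
#' @param mode `"overlap"` (default) or `"midpoint"`.
#' @return a [BinCountMatrix-class].
#' @export
countFragments <- function(frags, layout, scheme,
                           mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  gr <- fragRanges(frags)
  bad <- setdiff(unique(as.character(seqnames(gr))), layout@chromNames)
  if (length(bad))
    stop("fragments on chromosomes absent from layout: ",
         paste(bad, collapse = ", "))
  grp <- classifyLengths(frags, scheme)
  nb <- nBins(layout)
  K <- .nGroups(scheme)
  if (mode == "overlap") {
    bins <- binRanges(layout)
    gr2 <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)))
    hits <- findOverlaps(gr2, bins, minoverlap = 1L)
    binIdx <- S4Vectors::subjectHits(hits)
    grpIdx <- grp[S4Vectors::queryHits(hits)]
  } else {
    mid0 <- (start(gr) - 1 + end(gr)) %/% 2    # 0-based midpoint position
    off <- .chromBinOffsets(layout)[as.character(seqnames(gr))]
    binIdx <- as.integer(off + mid0 %/% layout@binSize + 1L)
    grpIdx <- grp
  }
  ok <- !is.na(grpIdx)
  counts <- matrix(tabulate((grpIdx[ok] - 1L) * nb + binIdx[ok],
                            nbins = nb * K),
                   nrow = nb, ncol = K)
  storage.mode(counts) <- "integer"
  BinCountMatrix(counts, layout, scheme)
}

#' Write a BinCountMatrix as TSV
#'
#' Columns: chrom, start (0-based), end, then one column per length group.
#'
#' @param counts a [BinCountMatrix-class].
#' @param path output path.
#' @export
writeCountsTsv <- function(counts, path) {
  br <- rowRanges(counts)
  df <- data.frame(chrom = as.character(seqnames(br)),
                   start = start(br) - 1, end = end(br),
                   as.data.frame(assay(counts, "counts")),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
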