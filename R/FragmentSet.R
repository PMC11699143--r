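#' Construct a FragmentSet from a GRanges
#'
#' @param ranges a [GenomicRanges::GRanges] of fragments (1-based).
#' @param provenance free-text sample/condition label.
#' @param qc optional named list of QC counters.
#' @return a [FragmentSet-class].
#' @export
FragmentSet <- function(ranges, provenance = "", qc = list()) {
  new("FragmentSet", ranges = ranges, provenance = provenance, qc = qc)
}

#' @rdname FragmentSet-class
#' @export
setMethod("fragRanges", "FragmentSet", function(x) x@ranges)

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentLengths", "FragmentSet", function(x) width(x@ranges))

#' @rdname FragmentSet-class
#' @export
setMethod("provenance", "FragmentSet", function(x) x@provenance)

#' @rdname FragmentSet-class
#' @export
setMethod("qcReport", "FragmentSet", function(x) x@qc)

#' @rdname FragmentSet-class
#' @export
setMethod("length", "FragmentSet", function(x) length(x@ranges))

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet:", length(object@ranges), "fragments",
      if (nzchar(object@provenance)) paste0("(", object@provenance, ")") else "",
      "\n")
  if (length(object@ranges))
    cat("  length range:", min(width(object@ranges)), "-",
        max(width(object@ranges)), "bp\n")
})

#' Load paired-end fragments from BED or BAM
#'
#' Reads aligned fragments and applies the closed length filter
#' `minLen <= length <= maxLen` (the conventional retention window is
#' 50-250 bp, both endpoints kept). For BAM the fragment is the template
#' (insert) interval of a properly paired read pair, taken once per pair from
#' the first-in-pair record; secondary, supplementary and duplicate-flagged
#' records are skipped. Strand is ignored. Fragments on chromosomes absent
#' from `layout` are dropped and counted in the QC report.
#'
#' @param path a BED3+ file (tab-separated, 0-based half-open, no header
#'   required) or a coordinate-sorted, indexed BAM file.
#' @param layout the active [GenomeLayout-class].
#' @param minLen,maxLen closed fragment-length retention bounds (bp).
#' @param provenance sample label; defaults to the file name.
#' @return a [FragmentSet-class]; `qcReport()` lists fragments read, kept and
#'   dropped by reason.
#' @export
loadFragments <- function(path, layout, minLen = 50, maxLen = 250,
                          provenance = basename(path)) {
  if (!file.exists(path)) stop("cannot read fragment file: ", path)
  if (minLen >= maxLen) stop("minLen must be < maxLen")
  isBam <- grepl("\\.bam$", path, ignore.case = TRUE)
  if (isBam) raw <- .readBamFragments(path) else raw <- .readBedFragments(path)
  nRead <- length(raw$chrom)
  onLayout <- raw$chrom %in% layout@chromNames
  nOffChrom <- sum(!onLayout)
  len <- raw$end0 - raw$start0
  inLen <- len >= minLen & len <= maxLen
  keep <- onLayout & inLen
  nShortLong <- sum(onLayout & !inLen)
  # bounds check against chromosome lengths
  if (any(keep)) {
    clen <- chromLengths(layout)[raw$chrom[keep]]
    oob <- raw$end0[keep] > clen | raw$start0[keep] < 0
    if (any(oob)) {
      idx <- which(keep)[oob]
      keep[idx] <- FALSE
    }
    nOob <- sum(oob)
  } else nOob <- 0L
  gr <- GRanges(raw$chrom[keep],
                IRanges(start = raw$start0[keep] + 1, end = raw$end0[keep]),
                seqinfo = Seqinfo(layout@chromNames, layout@chromLengths))
  qc <- list(read = nRead, kept = sum(keep),
             dropped_off_layout = nOffChrom,
             dropped_length = nShortLong,
             dropped_out_of_bounds = nOob)
  if (sum(keep) == 0L)
    warning("no fragments retained after filtering (", nRead, " read)")
  FragmentSet(gr, provenance = provenance, qc = qc)
}

.readBedFragments <- function(path) {
  n <- tryCatch(length(readLines(path, n = 1L)), error = function(e)
    stop("I/O error reading BED: ", path))
  if (n == 0L)
    return(list(chrom = character(0), start0 = numeric(0), end0 = numeric(0)))
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  list(chrom = as.character(tab[[1L]]), start0 = as.numeric(tab[[2L]]),
       end0 = as.numeric(tab[[3L]]))
}

.readBamFragments <- function(path) {
  bai <- paste0(path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", path, ignore.case = TRUE)
  if (!file.exists(bai) && !file.exists(bai2))
    stop("BAM index not found (expected ", bai, "); index the BAM first")
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isFirstMateRead = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "mpos", "isize"))
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  ok <- !is.na(res$isize) & res$isize != 0L
  rn <- as.character(res$rname[ok])
  pos <- res$pos[ok]; mpos <- res$mpos[ok]; isz <- res$isize[ok]
  # leftmost 1-based template start; template spans |isize| bp
  left1 <- ifelse(isz > 0L, pos, mpos)
  list(chrom = rn, start0 = as.numeric(left1 - 1L),
       end0 = as.numeric(left1 - 1L + abs(isz)))
}

#' Assign fragments to length groups
#'
#' Fragment of length L goes to group k iff `b_k <= L < b_{k+1}` (half-open);
#' lengths outside `[b_1, b_{K+1})` get NA ("ungrouped").
#'
#' @param frags a [FragmentSet-class], or a numeric vector of lengths.
#' @param scheme a [LengthGroupScheme-class].
#' @return integer group indices (1-based), NA for ungrouped.
#' @export
classifyLengths <- function(frags, scheme) {
  len <- if (is(frags, "FragmentSet")) fragmentLengths(frags) else
    as.numeric(frags)
  b <- boundaries(scheme)
  g <- findInterval(len, b)          # 0 below b1; K+1 at/after b_{K+1}
  g[g == 0L | g == length(b)] <- NA_integer_
  g
}

#' Write fragments as BED3
#'
#' Exact (chrom, start, end) round-trip with [loadFragments()] for BED input.
#'
#' @param frags a [FragmentSet-class].
#' @param path output path.
#' @export
writeFragmentsBed <- function(frags, path) {
  gr <- fragRanges(frags)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a per-sample fragment QC report
#'
#' @param frags a [FragmentSet-class] produced by [loadFragments()].
#' @param path output text path.
#' @export
writeFragmentQC <- function(frags, path) {
  qc <- qcReport(frags)
  lines <- c(paste0("sample\t", provenance(frags)),
             paste0(names(qc), "\t", unlist(qc)))
  writeLines(lines, path)
  invisible(path)
}
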