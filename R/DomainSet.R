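#' Construct a DomainSet
#'
#' @param ranges GRanges with mcols `label` (in `labelSet`) and optionally
#'   `score`; sorted, non-overlapping.
#' @param labelSet the two permitted labels, e.g. `c("Ti", "Lo")`.
#' @param provenance free-text label.
#' @return a [DomainSet-class].
#' @export
DomainSet <- function(ranges, labelSet, provenance = "") {
  if (!"score" %in% names(mcols(ranges)))
    mcols(ranges)$score <- rep(NA_real_, length(ranges))
  if (!"label" %in% names(mcols(ranges)))
    mcols(ranges)$label <- character(length(ranges))
  ranges <- GenomicRanges::sort(ranges)
  new("DomainSet", ranges = ranges, labelSet = labelSet,
      provenance = provenance)
}

#' @rdname DomainSet-class
#' @export
setMethod("domainRanges", "DomainSet", function(x) x@ranges)

#' @rdname DomainSet-class
#' @export
setMethod("labelSet", "DomainSet", function(x) x@labelSet)

#' @rdname DomainSet-class
#' @export
setMethod("length", "DomainSet", function(x) length(x@ranges))

setMethod("show", "DomainSet", function(object) {
  lab <- mcols(object@ranges)$label
  cat("DomainSet:", length(object@ranges), "domains (",
      paste(vapply(object@labelSet,
                   function(l) paste0(l, "=", sum(lab == l)), ""),
            collapse = ", "), ")\n")
  if (length(object@ranges))
    cat("  median length:",
        format(stats::median(width(object@ranges)), big.mark = ","), "bp\n")
})

#' Write a DomainSet as BED4
#'
#' Columns: chrom, start (0-based), end, label.
#'
#' @param ds a [DomainSet-class].
#' @param path output path.
#' @export
writeDomainsBed <- function(ds, path) {
  gr <- domainRanges(ds)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE),
                   name = mcols(gr)$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a DomainSet from BED4
#'
#' @param path BED file whose 4th column holds the domain label.
#' @param labelSet the two permitted labels; inferred from the file when NULL.
#' @param provenance free-text label.
#' @return a [DomainSet-class].
#' @export
readDomainsBed <- function(path, labelSet = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("cannot read BED: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 4L) stop("domain BED needs 4 columns (chrom,start,end,label)")
  if (is.null(labelSet)) labelSet <- sort(unique(as.character(tab[[4L]])))
  gr <- GRanges(tab[[1L]], IRanges(start = tab[[2L]] + 1, end = tab[[3L]]))
  mcols(gr)$label <- as.character(tab[[4L]])
  DomainSet(gr, labelSet = labelSet, provenance = provenance)
}
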