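#' Construct a GenomeLayout
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp), in
#'   the desired order.
#' @param binSize bin width in bp.
#' @return a [GenomeLayout-class] object.
#' @examples
#' GenomeLayout(c(chr1 = 1e6, chr2 = 5e5), binSize = 1e5)
#' @export
GenomeLayout <- function(chromLengths, binSize) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
    stop("chromLengths must be a named vector")
  new("GenomeLayout", chromNames = names(chromLengths),
      chromLengths = unname(as.numeric(chromLengths)),
      binSize = as.numeric(binSize))
}

#' Read a chromosome-sizes file into a GenomeLayout
#'
#' @param path two-column text file (name, length), tab- or space-separated.
#' @param binSize bin width in bp.
#' @return a [GenomeLayout-class].
#' @export
readChromSizes <- function(path, binSize) {
  if (!file.exists(path)) stop("cannot read chrom-sizes file: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chrom-sizes file needs two columns (name, length)")
  GenomeLayout(stats::setNames(as.numeric(tab[[2L]]), tab[[1L]]), binSize)
}

#' @rdname GenomeLayout-class
#' @export
setMethod("binSize", "GenomeLayout", function(x) x@binSize)

#' @rdname GenomeLayout-class
#' @export
setMethod("chromLengths", "GenomeLayout",
          function(x) stats::setNames(x@chromLengths, x@chromNames))

.nBinsPerChrom <- function(layout)
  stats::setNames(as.integer(ceiling(layout@chromLengths / layout@binSize)),
                  layout@chromNames)

# 0-based row offset of each chromosome's first bin in layout order
.chromBinOffsets <- function(layout) {
  nb <- .nBinsPerChrom(layout)
  stats::setNames(c(0L, cumsum(nb)[-length(nb)]), names(nb))
}

#' @rdname GenomeLayout-class
#' @export
setMethod("nBins", "GenomeLayout", function(x) sum(.nBinsPerChrom(x)))

#' @rdname GenomeLayout-class
#' @export
setMethod("binRanges", "GenomeLayout", function(x) {
  nb <- .nBinsPerChrom(x)
  chrom <- rep(x@chromNames, nb)
  i <- unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
  start0 <- i * x@binSize
  end0 <- pmin(start0 + x@binSize, rep(x@chromLengths, nb))
  GRanges(chrom, IRanges(start = start0 + 1, end = end0),
          seqinfo = Seqinfo(x@chromNames, x@chromLengths))
})

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", length(object@chromNames), "chromosome(s),",
      format(sum(object@chromLengths), big.mark = ","), "bp,",
      format(object@binSize, big.mark = ","), "bp bins ->",
      nBins(object), "bins\n")
})

# TRUE iff two layouts define the same bin grid
.sameLayout <- function(a, b) {
  identical(a@chromNames, b@chromNames) &&
    identical(a@chromLengths, b@chromLengths) &&
    identical(a@binSize, b@binSize)
}

.stopIfLayoutMismatch <- function(a, b) {
  if (!.sameLayout(a, b))
    stop("tracks/objects are defined on different genome layouts")
}

#' Write a chromosome-sizes file
#'
#' @param layout a [GenomeLayout-class].
#' @param path output path (two-column, tab-separated).
#' @export
writeChromSizes <- function(layout, path) {
  write.table(data.frame(layout@chromNames, format(layout@chromLengths,
                                                   scientific = FALSE,
                                                   trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
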