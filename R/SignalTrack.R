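#' Construct a SignalTrack
#'
#' @param values numeric vector, one value per bin of `layout` (NA = missing).
#' @param layout a [GenomeLayout-class].
#' @return a [SignalTrack-class].
#' @export
SignalTrack <- function(values, layout)
  new("SignalTrack", layout = layout, values = as.numeric(values))

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname SignalTrack-class
#' @export
setMethod("genomeLayout", "SignalTrack", function(x) x@layout)

#' @rdname SignalTrack-class
#' @export
setMethod("nBins", "SignalTrack", function(x) length(x@values))

setMethod("show", "SignalTrack", function(object) {
  v <- object@values
  nm <- sum(is.na(v))
  cat("SignalTrack:", length(v), "bins (", nm, "missing );",
      if (all(is.na(v))) "all missing\n" else
        sprintf("range [%.4g, %.4g]\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
})

# values of one chromosome as a plain vector
.chromSlice <- function(track, chrom) {
  off <- .chromBinOffsets(track@layout)[[chrom]]
  nb <- .nBinsPerChrom(track@layout)[[chrom]]
  track@values[(off + 1L):(off + nb)]
}

#' Write a SignalTrack as bedGraph
#'
#' Missing bins are omitted; coordinates are 0-based half-open per the
#' bedGraph convention.
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  br <- binRanges(track@layout)
  keep <- !is.na(track@values)
  df <- data.frame(chrom = as.character(seqnames(br))[keep],
                   start = format(start(br)[keep] - 1, scientific = FALSE,
                                  trim = TRUE),
                   end = format(end(br)[keep], scientific = FALSE, trim = TRUE),
                   value = track@values[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a bin grid
#'
#' Each bedGraph interval must coincide with one bin of `layout`; bins absent
#' from the file are missing.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param layout the target [GenomeLayout-class].
#' @return a [SignalTrack-class].
#' @export
readBedGraphTrack <- function(path, layout) {
  if (!file.exists(path)) stop("cannot read bedGraph: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  vals <- rep(NA_real_, nBins(layout))
  bad <- !(tab[[1L]] %in% layout@chromNames)
  if (any(bad))
    warning(sum(bad), " bedGraph rows on chromosomes absent from layout; dropped")
  tab <- tab[!bad, , drop = FALSE]
  if (nrow(tab)) {
    if (any(tab[[2L]] %% layout@binSize != 0))
      stop("bedGraph intervals do not align with the ", layout@binSize,
           " bp bin grid")
    off <- .chromBinOffsets(layout)[tab[[1L]]]
    vals[off + tab[[2L]] %/% layout@binSize + 1L] <- tab[[4L]]
  }
  SignalTrack(vals, layout)
}
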