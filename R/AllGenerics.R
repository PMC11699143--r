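#' @rdname GenomeLayout-class
#' @param x an object with a genome layout.
#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname LengthGroupScheme-class
#' @param x a LengthGroupScheme (or object carrying one).
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname SignalTrack-class
#' @param x a SignalTrack.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname FragmentSet-class
#' @param x a FragmentSet.
#' @export
setGeneric("fragRanges", function(x) standardGeneric("fragRanges"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentLengths", function(x) standardGeneric("fragmentLengths"))

#' @rdname FragmentSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname FragmentSet-class
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname BinCountMatrix-class
#' @param x a BinCountMatrix.
#' @export
setGeneric("lengthScheme", function(x) standardGeneric("lengthScheme"))

#' @rdname DomainSet-class
#' @param x a DomainSet.
#' @export
setGeneric("domainRanges", function(x) standardGeneric("domainRanges"))

#' @rdname DomainSet-class
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))

#' @rdname BorderProfile-class
#' @param x a BorderProfile.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname BorderProfile-class
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))
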