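#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom IRanges IRanges Views
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width
#'   strand reduce
#' @importFrom GenomeInfoDb seqlevels Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#' @importFrom stats cor loess loess.control predict runif rpois
#'   quantile median qnorm pnorm
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeLayout: an ordered, binned genome
#'
#' Ordered chromosomes with lengths plus a fixed bin size. Bins are
#' consecutive, non-overlapping `[i*binSize, min((i+1)*binSize, chromLength))`
#' intervals; the last bin on each chromosome may be partial.
#'
#' @slot chromNames character vector of unique chromosome names, in order.
#' @slot chromLengths numeric vector of chromosome lengths (bp).
#' @slot binSize bin width in bp.
#' @export
setClass("GenomeLayout",
  slots = c(chromNames = "character", chromLengths = "numeric",
            binSize = "numeric"))

setValidity("GenomeLayout", function(object) {
  msg <- NULL
  if (length(object@chromNames) != length(object@chromLengths))
    msg <- c(msg, "chromNames and chromLengths differ in length")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "chromosome names must be unique")
  if (length(object@binSize) != 1L || object@binSize < 1)
    msg <- c(msg, "binSize must be a single value >= 1")
  if (any(object@chromLengths < 1))
    msg <- c(msg, "chromosome lengths must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' LengthGroupScheme: fragment-length groups
#'
#' Strictly increasing boundaries `b_1 < ... < b_{K+1}` defining K half-open
#' length groups `[b_k, b_{k+1})`. The default scheme mirrors the standard
#' ten groups 50-80, 80-90, ..., 150-160, 160-250 bp.
#'
#' @slot boundaries strictly increasing bp values; at least two, first >= 1.
#' @export
setClass("LengthGroupScheme", slots = c(boundaries = "numeric"))

setValidity("LengthGroupScheme", function(object) {
  b <- object@boundaries
  msg <- NULL
  if (length(b) < 2L) msg <- c(msg, "need at least 2 boundaries")
  if (length(b) >= 2L && any(diff(b) <= 0))
    msg <- c(msg, "boundaries must be strictly increasing")
  if (length(b) >= 1L && b[1L] < 1) msg <- c(msg, "first boundary must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' FragmentSet: paired-end derived genomic intervals
#'
#' A collection of MNase protection footprints (template intervals of proper
#' pairs), stored as a [GenomicRanges::GRanges] (1-based internally; BED I/O
#' converts). Strand is ignored: fragments are double-stranded footprints.
#'
#' @slot ranges GRanges of fragments.
#' @slot provenance free-text sample/condition label.
#' @slot qc named list: fragments read / kept / dropped, by reason.
#' @export
setClass("FragmentSet",
  slots = c(ranges = "GRanges", provenance = "character", qc = "list"))

setValidity("FragmentSet", function(object) {
  if (length(object@ranges) && any(width(object@ranges) < 1))
    return("all fragments must have length >= 1")
  TRUE
})

#' SignalTrack: one value per genomic bin
#'
#' A per-bin float track over a [GenomeLayout]; `NA` marks missing bins and is
#' propagated, never silently zero-filled. Houses NRS, NRI, replication
#' timing, A/T content and imported tracks.
#'
#' @slot layout the GenomeLayout defining the bin grid.
#' @slot values numeric, one value per bin (NA = missing).
#' @export
setClass("SignalTrack",
  slots = c(layout = "GenomeLayout", values = "numeric"))

setValidity("SignalTrack", function(object) {
  nb <- sum(ceiling(object@layout@chromLengths / object@layout@binSize))
  if (length(object@values) != nb)
    return(sprintf("values length (%d) != bin count of layout (%d)",
                   length(object@values), nb))
  TRUE
})

#' BinCountMatrix: bins x length-group fragment counts
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' bins of a [GenomeLayout] (in layout order) and whose columns are the
#' length groups of a [LengthGroupScheme]; the `"counts"` assay holds
#' non-negative integer counts. The layout and scheme travel in
#' `metadata()`.
#'
#' @export
setClass("BinCountMatrix", contains = "RangedSummarizedExperiment")

setValidity("BinCountMatrix", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must contain a 'counts' assay")
  else if (any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be >= 0")
  if (!all(c("layout", "scheme") %in% names(metadata(object))))
    msg <- c(msg, "metadata must carry 'layout' and 'scheme'")
  if (is.null(msg)) TRUE else msg
})

#' DomainSet: labeled, non-overlapping genomic domains
#'
#' Sorted, non-overlapping intervals carrying one of two labels (e.g. Ti/Lo
#' nucleosome wrapping domains, A/B compartments, early/late replication) and
#' a score (mean track value within the domain).
#'
#' @slot ranges GRanges with mcols `label` and `score`.
#' @slot labelSet the two permitted labels.
#' @slot provenance free-text label.
#' @export
setClass("DomainSet",
  slots = c(ranges = "GRanges", labelSet = "character",
            provenance = "character"))

setValidity("DomainSet", function(object) {
  gr <- object@ranges
  msg <- NULL
  if (!"label" %in% names(mcols(gr)))
    msg <- c(msg, "ranges must carry a 'label' mcol")
  else if (!all(mcols(gr)$label %in% object@labelSet))
    msg <- c(msg, "all labels must be in labelSet")
  if (length(object@labelSet) != 2L)
    msg <- c(msg, "labelSet must have exactly two labels")
  if (length(gr) > 1L) {
    if (!identical(order(gr), seq_along(gr)))
      msg <- c(msg, "domains must be sorted")
    if (sum(width(reduce(gr))) != sum(width(gr)))
      msg <- c(msg, "domains must be non-overlapping")
  }
  if (is.null(msg)) TRUE else msg
})

#' BorderProfile: track values around domain borders
#'
#' One row per border; columns are flank bins ordered upstream to downstream
#' across the border, oriented so they always read first-label to
#' second-label. Windows running off a chromosome are NA-padded.
#'
#' @slot matrix borders x flank-bins numeric matrix (may contain NA).
#' @slot flankBp flank width in bp on each side of the border.
#' @slot binBp track bin size in bp.
#' @slot borderType e.g. "Lo->Ti".
#' @export
setClass("BorderProfile",
  slots = c(matrix = "matrix", flankBp = "numeric", binBp = "numeric",
            borderType = "character"))

setValidity("BorderProfile", function(object) {
  if (ncol(object@matrix) != 2 * object@flankBp / object@binBp)
    return("column count must equal 2*flankBp/binBp")
  TRUE
})

#' BaseFrequencyMatrix: per-position base frequencies around cut sites
#'
#' Fractions of A/C/G/T per relative position (N excluded from the
#' denominator; the N fraction is reported separately).
#'
#' @slot positions relative offsets (bp) w.r.t. the cut site.
#' @slot freq positions x 4 matrix of A, C, G, T fractions.
#' @slot nFraction per-position fraction of N among all bases.
#' @slot nSites number of cut sites tallied.
#' @slot nSkipped cut sites skipped for falling within `flank` of a contig edge.
#' @slot side `"5prime"` or `"3prime"`.
#' @export
setClass("BaseFrequencyMatrix",
  slots = c(positions = "numeric", freq = "matrix", nFraction = "numeric",
            nSites = "integer", nSkipped = "integer", side = "character"))

setValidity("BaseFrequencyMatrix", function(object) {
  f <- object@freq
  if (ncol(f) != 4L) return("freq must have 4 columns (A, C, G, T)")
  s <- rowSums(f)
  ok <- is.na(s) | abs(s - 1) < 1e-9
  if (!all(ok)) return("each position's A+C+G+T fractions must sum to 1")
  TRUE
})

#' LengthHistogram: fragment-length distribution within regions
#'
#' @slot breaks histogram bin edges in bp (half-open bins).
#' @slot counts fragment counts per length bin.
#' @slot region free-text region-set label.
#' @slot nrs region-restricted NRS at `breakpoint` (midpoint-assigned
#'   fragments), NA when no fragments fall in the regions.
#' @slot breakpoint the break point (bp) used for `nrs`.
#' @export
setClass("LengthHistogram",
  slots = c(breaks = "numeric", counts = "numeric", region = "character",
            nrs = "numeric", breakpoint = "numeric"))

#' RTFractionCounts: per-bin counts for four S-phase fractions
#'
#' Per-bin fragment counts for FACS-sorted S-phase fractions S1-S4 on a
#' common bin grid, plus the total library size of each fraction.
#'
#' @slot layout the common GenomeLayout (50 Kb bins by default upstream).
#' @slot counts bins x 4 matrix, columns S1..S4.
#' @slot libraryTotals total fragments per fraction (length 4).
#' @export
setClass("RTFractionCounts",
  slots = c(layout = "GenomeLayout", counts = "matrix",
            libraryTotals = "numeric"))

setValidity("RTFractionCounts", function(object) {
  msg <- NULL
  if (ncol(object@counts) != 4L) msg <- c(msg, "counts must have 4 columns")
  if (length(object@libraryTotals) != 4L)
    msg <- c(msg, "libraryTotals must have length 4")
  nb <- sum(ceiling(object@layout@chromLengths / object@layout@binSize))
  if (nrow(object@counts) != nb)
    msg <- c(msg, "counts rows must equal layout bin count")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' SimulationSpec: ground-truth specification for synthetic data
#'
#' Defines a binned genome carrying alternating domains with a latent
#' per-domain tightness theta in \[0,1\]; fragment lengths are drawn from a
#' two-component truncated-normal mixture whose "long" (nucleosomal-scale)
#' component is sampled with probability theta. `digestionShift` uniformly
#' reduces theta to emulate longer MNase digestion.
#'
#' @slot layout the GenomeLayout.
#' @slot domainPlan data.frame(chrom, length, theta): consecutive domain
#'   lengths (bp) tiling each chromosome exactly, with per-domain theta.
#' @slot depth expected fragments per bin (Poisson mean).
#' @slot digestionShift delta in \[0,1\] subtracted from theta.
#' @slot seed integer master seed; all samplers derive per-(chromosome, bin,
#'   condition) sub-seeds from it.
#' @slot lengthModel list(longMean, longSd, shortMean, shortSd, minLen,
#'   maxLen) of the truncated-normal mixture.
#' @export
setClass("SimulationSpec",
  slots = c(layout = "GenomeLayout", domainPlan = "data.frame",
            depth = "numeric", digestionShift = "numeric", seed = "integer",
            lengthModel = "list"))

setValidity("SimulationSpec", function(object) {
  msg <- NULL
  dp <- object@domainPlan
  if (!all(c("chrom", "length", "theta") %in% names(dp)))
    msg <- c(msg, "domainPlan needs columns chrom, length, theta")
  else {
    if (any(dp$theta < 0 | dp$theta > 1))
      msg <- c(msg, "theta must lie in [0, 1]")
    tot <- tapply(dp$length, factor(dp$chrom, levels = object@layout@chromNames),
                  sum)
    tot[is.na(tot)] <- 0
    if (any(tot != object@layout@chromLengths))
      msg <- c(msg, "domain lengths must tile each chromosome exactly")
  }
  if (object@digestionShift < 0 || object@digestionShift > 1)
    msg <- c(msg, "digestionShift must lie in [0, 1]")
  if (object@depth < 0) msg <- c(msg, "depth must be >= 0")
  if (is.null(msg)) TRUE else msg
})
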