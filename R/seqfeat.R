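# sequence source: accept a DNAStringSet or a FASTA path
.asGenomeSeq <- function(x) {
  if (is(x, "DNAStringSet")) {
    names(x) <- sub("\\s.*$", "", names(x))
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("cannot read FASTA: ", x)
    seqs <- Biostrings::readDNAStringSet(x)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  stop("sequence source must be a DNAStringSet or a FASTA path")
}

.checkContigs <- function(seqs, chroms) {
  bad <- setdiff(unique(chroms), names(seqs))
  if (length(bad))
    stop("contig(s) absent from FASTA: ", paste(bad, collapse = ", "))
}

# DNAStringSet of interval sequences (1-based GRanges), bounds-checked
.extractSeqs <- function(seqs, gr) {
  .checkContigs(seqs, as.character(seqnames(gr)))
  clen <- Biostrings::width(seqs)[match(as.character(seqnames(gr)),
                                        names(seqs))]
  if (any(start(gr) < 1 | end(gr) > clen))
    stop("interval(s) outside contig bounds")
  out <- Biostrings::DNAStringSet(rep("", length(gr)))
  for (ch in unique(as.character(seqnames(gr)))) {
    sel <- which(as.character(seqnames(gr)) == ch)
    out[sel] <- Biostrings::DNAStringSet(
      Views(seqs[[ch]], start = start(gr)[sel], end = end(gr)[sel]))
  }
  out
}

#' A/T content of bins or fragments
#'
#' Fraction of A or T among non-N bases per interval (top strand; the value
#' equals its reverse complement's, so it is strand-safe). All-N intervals
#' are missing.
#'
#' @param seqs genome sequence: a [Biostrings::DNAStringSet] or FASTA path.
#' @param intervals a [GenomeLayout-class] (per-bin track), a
#'   [FragmentSet-class], or a [GenomicRanges::GRanges].
#' @return a [SignalTrack-class] when `intervals` is a layout, else a
#'   numeric vector (one value per interval).
#' @export
atContent <- function(seqs, intervals) {
  seqs <- .asGenomeSeq(seqs)
  asTrack <- is(intervals, "GenomeLayout")
  gr <- if (asTrack) binRanges(intervals) else
    if (is(intervals, "FragmentSet")) fragRanges(intervals) else intervals
  ss <- .extractSeqs(seqs, gr)
  at <- Biostrings::letterFrequency(ss, "AT")[, 1L]
  acgt <- Biostrings::letterFrequency(ss, "ACGT")[, 1L]
  vals <- ifelse(acgt > 0, at / acgt, NA_real_)
  if (asTrack) SignalTrack(vals, intervals) else vals
}

#' Per-fragment dinucleotide frequency
#'
#' For each fragment, the count of the requested dinucleotides among its
#' overlapping top-strand 2-mers, divided by the number of N-free 2-mers
#' (2-mers containing N are excluded from numerator and denominator).
#' Fragments shorter than 2 bp are missing.
#'
#' @param seqs genome sequence (DNAStringSet or FASTA path).
#' @param frags a [FragmentSet-class].
#' @param dinucs character vector of 2-mers, e.g. `c("CA", "CT")` or
#'   `c("AG", "TG")`.
#' @return numeric vector, one frequency per fragment.
#' @export
dinucleotideFreq <- function(seqs, frags, dinucs = c("CA", "CT")) {
  stopifnot(all(nchar(dinucs) == 2L))
  seqs <- .asGenomeSeq(seqs)
  gr <- fragRanges(frags)
  ss <- .extractSeqs(seqs, gr)
  dn <- Biostrings::dinucleotideFrequency(ss)
  num <- rowSums(dn[, toupper(dinucs), drop = FALSE])
  den <- rowSums(dn)
  ifelse(width(gr) >= 2 & den > 0, num / den, NA_real_)
}

#' MNase cut-site base-frequency profiles
#'
#' For every fragment end (5' = fragment start, 3' = fragment end), tallies
#' top-strand base frequencies at each relative position in
#' `[cut - flank, cut + flank)`. Cut sites closer than `flank` to a contig
#' edge are skipped and counted. N bases are excluded from the A/C/G/T
#' denominator; the N fraction is reported separately.
#'
#' @param seqs genome sequence (DNAStringSet or FASTA path).
#' @param frags a [FragmentSet-class].
#' @param flank bp on either side of the cut site (>= 1); default 20.
#' @return list with elements `fivePrime` and `threePrime`, each a
#'   [BaseFrequencyMatrix-class].
#' @export
cutSiteProfile <- function(seqs, frags, flank = 20) {
  if (flank < 1) stop("flank must be >= 1")
  seqs <- .asGenomeSeq(seqs)
  gr <- fragRanges(frags)
  if (!length(gr)) stop("zero usable cut sites")
  chrom <- as.character(seqnames(gr))
  .checkContigs(seqs, chrom)
  clen <- Biostrings::width(seqs)[match(chrom, names(seqs))]
  cut5 <- start(gr) - 1           # 0-based cut coordinate at fragment start
  cut3 <- end(gr)                 # 0-based cut coordinate at fragment end
  mk <- function(cut0, side) {
    s1 <- cut0 - flank + 1        # 1-based window start
    e1 <- cut0 + flank
    ok <- s1 >= 1 & e1 <= clen
    if (!any(ok)) stop("zero usable cut sites (all within flank of an edge)")
    win <- GRanges(chrom[ok], IRanges(start = s1[ok], end = e1[ok]))
    ss <- .extractSeqs(seqs, win)
    cm <- Biostrings::consensusMatrix(ss, baseOnly = TRUE)
    acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
    tot <- colSums(acgt)
    freq <- t(sweep(acgt, 2L, ifelse(tot > 0, tot, NA), `/`))
    all <- colSums(cm)
    new("BaseFrequencyMatrix", positions = (-flank):(flank - 1),
        freq = freq, nFraction = cm["other", ] / all,
        nSites = sum(ok), nSkipped = sum(!ok), side = side)
  }
  list(fivePrime = mk(cut5, "5prime"), threePrime = mk(cut3, "3prime"))
}

setMethod("show", "BaseFrequencyMatrix", function(object) {
  cat("BaseFrequencyMatrix (", object@side, "):", object@nSites,
      "cut sites (", object@nSkipped, "skipped ), positions",
      min(object@positions), "..", max(object@positions), "\n")
})

#' Write a BaseFrequencyMatrix as TSV
#'
#' Columns: position, A, C, G, T, N_fraction.
#'
#' @param bfm a [BaseFrequencyMatrix-class].
#' @param path output path.
#' @export
writeBaseFrequencyTsv <- function(bfm, path) {
  df <- data.frame(position = bfm@positions, bfm@freq,
                   N_fraction = bfm@nFraction)
  colnames(df) <- c("position", "A", "C", "G", "T", "N_fraction")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation between fragment length and a per-fragment statistic
#'
#' Pearson r between fragment length and `values` (e.g. A/T content or
#' dinucleotide frequency), optionally restricted to fragments whose
#' midpoint falls within domains of one label (half-open midpoint
#' convention: a fragment whose 0-based midpoint equals a domain's end
#' coordinate lies outside that domain).
#'
#' @param frags a [FragmentSet-class] (>= 3 fragments after filtering).
#' @param values numeric, one value per fragment.
#' @param domains optional [DomainSet-class] filter.
#' @param label domain label to restrict to (required with `domains`).
#' @return list with `r` and `n`.
#' @export
lengthCompositionCorrelation <- function(frags, values, domains = NULL,
                                         label = NULL) {
  gr <- fragRanges(frags)
  stopifnot(length(values) == length(gr))
  keep <- rep(TRUE, length(gr))
  if (!is.null(domains)) {
    if (is.null(label)) stop("supply the domain label to restrict to")
    mid0 <- (start(gr) - 1 + end(gr)) %/% 2
    pts <- GRanges(as.character(seqnames(gr)),
                   IRanges(start = mid0 + 1, width = 1L))
    dgr <- domainRanges(domains)
    dgr <- dgr[mcols(dgr)$label == label]
    keep <- IRanges::overlapsAny(pts, dgr, ignore.strand = TRUE)
  }
  keep <- keep & !is.na(values)
  len <- width(gr)[keep]
  val <- values[keep]
  if (length(len) < 3L) stop("need >= 3 fragments")
  if (stats::var(len) == 0 || stats::var(val) == 0)
    stop("zero variance; correlation undefined")
  list(r = stats::cor(len, val), n = length(len))
}
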