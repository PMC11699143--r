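# shared fixtures: toy layouts, tracks, and a programmatic BAM fixture

toyLayout <- function(chromLengths = c(chrA = 1e4, chrB = 5e3),
                      binSize = 1e3) {
  GenomeLayout(chromLengths, binSize)
}

trackOn <- function(values, layout) SignalTrack(values, layout)

# single-chromosome layout with one bin per value, bin size 100 bp
signTrack <- function(values, binSize = 100) {
  layout <- GenomeLayout(c(chrS = length(values) * binSize), binSize)
  SignalTrack(values, layout)
}

writeBedFixture <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# write a SAM of proper pairs and convert to a sorted, indexed BAM;
# pairs: data.frame(chrom, start0, tlen)
writeBamFixture <- function(pairs, chromLengths,
                            readLen = 40) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chromLengths), "\tLN:",
                  format(chromLengths, scientific = FALSE, trim = TRUE)))
  recs <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p1 <- pairs$start0[i] + 1                       # 1-based leftmost
    p2 <- pairs$start0[i] + pairs$tlen[i] - readLen + 1
    ch <- pairs$chrom[i]
    qn <- paste0("frag", i)
    seq1 <- paste(rep("A", readLen), collapse = "")
    recs <- c(recs,
      paste(qn, 99, ch, p1, 60, paste0(readLen, "M"), "=", p2,
            pairs$tlen[i], seq1, "*", sep = "\t"),
      paste(qn, 147, ch, p2, 60, paste0(readLen, "M"), "=", p1,
            -pairs$tlen[i], seq1, "*", sep = "\t"))
  }
  writeLines(c(hdr, recs), sam)
  bam0 <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                           indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam0, tempfile())
  Rsamtools::indexBam(sorted)
  sorted
}

# deterministic random FragmentSet on a layout
randomFragments <- function(layout, n, seed = 1, minLen = 50, maxLen = 250) {
  set.seed(seed)
  cl <- chromLengths(layout)
  chrom <- sample(names(cl), n, replace = TRUE)
  len <- sample(minLen:maxLen, n, replace = TRUE)
  maxStart <- cl[chrom] - len
  s0 <- floor(runif(n, 0, pmax(maxStart, 1)))
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = s0 + 1, end = s0 + len))
  FragmentSet(gr, provenance = "random")
}
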