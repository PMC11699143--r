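# independent brute-force oracles; deliberately naive implementations

# O(N*B) fragment-by-bin counting oracle
oracleCountMatrix <- function(frags, layout, scheme) {
  bins <- binRanges(layout)
  gr <- fragRanges(frags)
  b <- boundaries(scheme)
  K <- length(b) - 1L
  m <- matrix(0L, length(bins), K)
  for (i in seq_along(gr)) {
    L <- GenomicRanges::width(gr)[i]
    g <- NA_integer_
    for (k in seq_len(K)) if (L >= b[k] && L < b[k + 1L]) g <- k
    if (is.na(g)) next
    for (j in seq_along(bins)) {
      sameChrom <- as.character(GenomicRanges::seqnames(gr))[i] ==
        as.character(GenomicRanges::seqnames(bins))[j]
      if (sameChrom &&
          GenomicRanges::start(gr)[i] <= GenomicRanges::end(bins)[j] &&
          GenomicRanges::end(gr)[i] >= GenomicRanges::start(bins)[j])
        m[j, g] <- m[j, g] + 1L
    }
  }
  m
}

# exhaustive-absorption segmentation oracle on a +1/-1 sign vector with
# uniform bin width; operates on per-bin labels, re-scanning each pass
oracleSegment <- function(signs, minBins) {
  lab <- signs
  repeat {
    r <- rle(lab)
    if (length(r$values) <= 1L) break
    short <- which(r$lengths < minBins)
    if (!length(short)) break
    # shortest short run, leftmost on ties
    j <- short[order(r$lengths[short], short)][1L]
    e <- cumsum(r$lengths); s <- c(1L, head(e, -1L) + 1L)
    newSign <- if (j > 1L) r$values[j - 1L] else r$values[j + 1L]
    lab[s[j]:e[j]] <- newSign
  }
  lab
}

# per-base bitmap overlap-fraction oracle
oracleOverlapFraction <- function(query, reference, chromLengths) {
  paint <- function(ds) {
    gr <- domainRanges(ds)
    maps <- lapply(chromLengths, function(L) rep(NA_character_, L))
    for (i in seq_along(gr)) {
      ch <- as.character(GenomicRanges::seqnames(gr))[i]
      maps[[ch]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
        S4Vectors::mcols(gr)$label[i]
    }
    maps
  }
  qm <- paint(query); rm_ <- paint(reference)
  m <- matrix(NA_real_, 2, 2,
              dimnames = list(labelSet(reference), labelSet(query)))
  for (r in labelSet(reference)) for (q in labelSet(query)) {
    inter <- 0; tot <- 0
    for (ch in names(chromLengths)) {
      tot <- tot + sum(rm_[[ch]] == r, na.rm = TRUE)
      inter <- inter + sum(rm_[[ch]] == r & qm[[ch]] == q, na.rm = TRUE)
    }
    m[r, q] <- inter / tot
  }
  m
}

# tricube-weighted degree-1 local regression with k-nearest-neighbour window
oracleLocalLinear <- function(x, y, k) {
  vapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    dmax <- sort(d)[k]
    w <- pmax(1 - (d / dmax)^3, 0)^3
    w[d > dmax] <- 0
    fit <- stats::lm.wfit(cbind(1, x - x[i]), y, w)
    fit$coefficients[1L]
  }, 0)
}

# naive string scans for sequence statistics
oracleAtContent <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  nn <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(nn)) return(NA_real_)
  sum(nn %in% c("A", "T")) / length(nn)
}

oracleDinucFreq <- function(s, dinucs) {
  ch <- strsplit(s, "")[[1L]]
  if (length(ch) < 2L) return(NA_real_)
  two <- paste0(ch[-length(ch)], ch[-1L])
  ok <- !grepl("[^ACGT]", two)
  if (!sum(ok)) return(NA_real_)
  sum(two[ok] %in% dinucs) / sum(ok)
}
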