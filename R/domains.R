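#' Segment an NRI track into nucleosome wrapping domains
#'
#' Sign-based segmentation of a smoothed NRI (or RT) track:
#' \enumerate{
#'   \item smooth by `smoothSpan` bins (loess, per chromosome); pass
#'     `smoothSpan = 0` for a pre-smoothed track;
#'   \item assign each non-missing bin a sign; zero-valued bins take the
#'     sign of the nearest non-zero neighbour (ties broken toward the left);
#'   \item maximal runs of constant sign become candidate domains;
#'   \item runs spanning fewer than `minSizeBp` are absorbed into their
#'     flanking domains, shortest run first, iterating until stable (an
#'     interior short run's two flanks share the opposite sign, so absorbing
#'     it merges all three runs);
#'   \item missing-bin gaps of one bin are bridged (the bin joins its left
#'     neighbour's domain); gaps of two or more bins split domains.
#' }
#' Positive runs are labelled `labels[1]` ("Ti", tight), negative runs
#' `labels[2]` ("Lo", loose). Domain scores are mean smoothed values over
#' the domain's non-missing bins.
#'
#' @param track an NRI [SignalTrack-class] (unsmoothed unless
#'   `smoothSpan = 0`).
#' @param minSizeBp minimum domain span in bp; default 3 bins.
#' @param smoothSpan loess window in bins (0 = already smoothed).
#' @param labels labels for positive / negative domains.
#' @param provenance free-text label for the result.
#' @return a [DomainSet-class].
#' @export
callDomains <- function(track, minSizeBp = 3 * binSize(genomeLayout(track)),
                        smoothSpan = 10, labels = c("Ti", "Lo"),
                        provenance = "") {
  layout <- genomeLayout(track)
  if (all(is.na(trackValues(track))))
    stop("all-missing track: no domains can be called")
  sm <- if (smoothSpan > 0) loessSmooth(track, smoothSpan) else track
  off <- .chromBinOffsets(layout)
  nb <- .nBinsPerChrom(layout)
  br <- binRanges(layout)
  res <- list()
  for (ch in layout@chromNames) {
    idx <- (off[[ch]] + 1L):(off[[ch]] + nb[[ch]])
    v <- trackValues(sm)[idx]
    w <- width(br)[idx]
    start0 <- start(br)[idx] - 1
    end0 <- end(br)[idx]
    for (seg in .splitSegments(v)) {
      lab <- .segmentSigns(v[seg], w[seg], minSizeBp)
      if (is.null(lab)) next
      r <- rle(lab)
      e <- cumsum(r$lengths); s <- c(1L, head(e, -1L) + 1L)
      for (k in seq_along(r$values)) {
        binsel <- seg[s[k]:e[k]]
        vv <- v[binsel]
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = start0[binsel[1L]],
          end = end0[binsel[length(binsel)]],
          sign = r$values[k],
          score = mean(vv[!is.na(vv)]))
      }
    }
  }
  if (!length(res)) stop("no signed bins found: no domains can be called")
  df <- do.call(rbind, res)
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end),
                seqinfo = Seqinfo(layout@chromNames, layout@chromLengths))
  mcols(gr)$label <- ifelse(df$sign > 0, labels[1L], labels[2L])
  mcols(gr)$score <- df$score
  DomainSet(gr, labelSet = labels, provenance = provenance)
}

# split a per-chromosome value vector into segments of bin indices,
# cutting at runs of >= 2 consecutive missing bins (single NAs are bridged)
.splitSegments <- function(v) {
  r <- rle(is.na(v))
  e <- cumsum(r$lengths); s <- c(1L, head(e, -1L) + 1L)
  cut <- r$values & r$lengths >= 2L
  segs <- list()
  cur <- integer(0)
  for (k in seq_along(r$values)) {
    if (cut[k]) {
      if (length(cur)) segs[[length(segs) + 1L]] <- cur
      cur <- integer(0)
    } else cur <- c(cur, s[k]:e[k])
  }
  if (length(cur)) segs[[length(segs) + 1L]] <- cur
  segs
}

# per-bin +1/-1 sign assignment within one segment, after absorption;
# returns NULL for segments with no non-zero signal
.segmentSigns <- function(v, w, minSizeBp) {
  s <- sign(v)                     # NA for bridged bins
  nz <- which(!is.na(s) & s != 0)
  if (!length(nz)) return(NULL)
  need <- which(is.na(s) | s == 0)
  if (length(need)) {
    # zeros -> nearest non-zero (ties toward the left); bridged NAs -> left
    # neighbour's eventual sign (equivalently nearest-left non-zero)
    for (i in need) {
      if (is.na(s[i])) {
        cand <- nz[nz < i]
        j <- if (length(cand)) max(cand) else min(nz[nz > i])
      } else {
        d <- abs(nz - i)
        j <- nz[which.min(d)]      # which.min: leftmost on ties
      }
      s[i] <- s[j]
    }
  }
  .absorbRuns(s, w, minSizeBp)
}

# iterative absorption of short runs (run span in bp < minSizeBp)
.absorbRuns <- function(s, w, minSizeBp) {
  r <- rle(s)
  rs <- r$values
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  cw <- c(0, cumsum(w))
  bp <- cw[ends + 1L] - cw[starts]
  repeat {
    if (length(rs) <= 1L) break
    short <- which(bp < minSizeBp)
    if (!length(short)) break
    j <- short[which.min(bp[short])]
    if (j > 1L && j < length(rs)) {
      ends[j - 1L] <- ends[j + 1L]
      bp[j - 1L] <- bp[j - 1L] + bp[j] + bp[j + 1L]
      drop <- c(j, j + 1L)
    } else if (j == 1L) {
      starts[2L] <- starts[1L]
      bp[2L] <- bp[1L] + bp[2L]
      drop <- 1L
    } else {
      ends[j - 1L] <- ends[j]
      bp[j - 1L] <- bp[j - 1L] + bp[j]
      drop <- j
    }
    rs <- rs[-drop]; starts <- starts[-drop]; ends <- ends[-drop]
    bp <- bp[-drop]
  }
  rep(rs, ends - starts + 1L)
}

#' Overlap-fraction matrix between two domain sets
#'
#' Entry (row = reference label r, column = query label q) is the fraction
#' of total r-domain bp overlapped by q-domains. Each row sums to at most 1
#' (strictly less where the reference extends into genome not covered by the
#' query).
#'
#' @param query,reference [DomainSet-class] objects on the same genome.
#' @return a 2x2 numeric matrix, rownames = reference labels, colnames =
#'   query labels.
#' @export
overlapFraction <- function(query, reference) {
  if (length(query) == 0L || length(reference) == 0L)
    stop("empty DomainSet")
  qgr <- domainRanges(query); rgr <- domainRanges(reference)
  lv <- union(seqlevels(qgr), seqlevels(rgr))
  GenomeInfoDb::seqlevels(qgr) <- lv
  GenomeInfoDb::seqlevels(rgr) <- lv
  m <- matrix(NA_real_, 2, 2,
              dimnames = list(labelSet(reference), labelSet(query)))
  for (r in labelSet(reference)) {
    rsub <- rgr[mcols(rgr)$label == r]
    tot <- sum(width(rsub))
    for (q in labelSet(query)) {
      qsub <- qgr[mcols(qgr)$label == q]
      ov <- sum(width(GenomicRanges::intersect(rsub, qsub,
                                               ignore.strand = TRUE)))
      m[r, q] <- if (tot > 0) ov / tot else NA_real_
    }
  }
  m
}

#' List borders between adjacent opposite-label domains
#'
#' A border is the shared boundary where a domain of `orientation[1]` is
#' immediately followed (left to right along the genome) by a domain of
#' `orientation[2]` on the same chromosome. Chromosome ends and gap-split
#' junctions (domains that do not touch) are not borders.
#'
#' @param ds a [DomainSet-class].
#' @param orientation character(2): the left label then the right label,
#'   e.g. `c("Lo", "Ti")`.
#' @return data.frame with columns `chrom` and `pos` (0-based boundary
#'   coordinate), with attribute `orientation`.
#' @export
listBorders <- function(ds, orientation = labelSet(ds)) {
  gr <- domainRanges(ds)
  out <- data.frame(chrom = character(0), pos = numeric(0))
  if (length(gr) >= 2L) {
    i <- seq_len(length(gr) - 1L)
    sameChrom <- as.character(seqnames(gr))[i] ==
      as.character(seqnames(gr))[i + 1L]
    touching <- start(gr)[i + 1L] == end(gr)[i] + 1L
    lab <- mcols(gr)$label
    match12 <- lab[i] == orientation[1L] & lab[i + 1L] == orientation[2L]
    sel <- which(sameChrom & touching & match12)
    out <- data.frame(chrom = as.character(seqnames(gr))[sel],
                      pos = as.numeric(end(gr)[sel]))
  }
  attr(out, "orientation") <- orientation
  out
}

#' Track values around domain borders
#'
#' For each border, extracts track values in `[border - flankBp,
#' border + flankBp)`; columns read upstream to downstream, i.e. always
#' first-label to second-label for borders from [listBorders()]. Windows
#' running past a chromosome end are NA-padded.
#'
#' @param track a [SignalTrack-class].
#' @param borders data.frame from [listBorders()] (columns chrom, pos).
#' @param flankBp flank width (bp); must be a multiple of the bin size.
#' @return a [BorderProfile-class]; `profileMean()` gives the column-wise
#'   mean ignoring missing values.
#' @export
borderProfile <- function(track, borders, flankBp) {
  if (nrow(borders) == 0L) stop("zero borders")
  layout <- genomeLayout(track)
  B <- binSize(layout)
  if (flankBp %% B != 0) stop("flankBp must be a multiple of the bin size")
  f <- as.integer(flankBp %/% B)
  off <- .chromBinOffsets(layout)
  nb <- .nBinsPerChrom(layout)
  v <- trackValues(track)
  m <- matrix(NA_real_, nrow(borders), 2L * f)
  for (i in seq_len(nrow(borders))) {
    ch <- borders$chrom[i]
    k <- borders$pos[i] %/% B            # bins upstream of the border
    loc <- (k - f + 1L):(k + f)          # chromosome-local bin numbers
    ok <- loc >= 1L & loc <= nb[[ch]]
    m[i, ok] <- v[off[[ch]] + loc[ok]]
  }
  colnames(m) <- as.character(seq_len(2L * f) * B - f * B - B)
  orient <- attr(borders, "orientation")
  new("BorderProfile", matrix = m, flankBp = flankBp, binBp = B,
      borderType = if (is.null(orient)) "" else
        paste(orient, collapse = "->"))
}

#' @rdname BorderProfile-class
#' @export
setMethod("profileMatrix", "BorderProfile", function(x) x@matrix)

#' @rdname BorderProfile-class
#' @export
setMethod("profileMean", "BorderProfile",
          function(x) colMeans(x@matrix, na.rm = TRUE))

setMethod("show", "BorderProfile", function(object) {
  cat("BorderProfile:", nrow(object@matrix), "borders",
      if (nzchar(object@borderType)) paste0("(", object@borderType, ")") else "",
      ",", ncol(object@matrix), "flank bins of", object@binBp, "bp\n")
})

#' Per-region track profile matrix
#'
#' `"anchored"` mode centres each row on the region's start (TSS) or end
#' (TTS) with a fixed flank of `flankBp`; the anchor bin is the first
#' downstream column. `"scaled"` mode rescales each region body to
#' `nBodyBins` columns (mean of track bins overlapping each column's
#' sub-interval). Minus-strand regions are reversed so columns always read
#' in the direction of transcription. Regions on chromosomes absent from the
#' track are skipped with a warning.
#'
#' @param track a [SignalTrack-class].
#' @param regions a [GenomicRanges::GRanges] (strand used; `*` treated as `+`).
#' @param mode `"anchored"` or `"scaled"`.
#' @param flankBp anchored mode: flank (bp) either side of the anchor;
#'   multiple of the bin size.
#' @param anchor anchored mode: `"start"` (TSS) or `"end"` (TTS).
#' @param nBodyBins scaled mode: number of body columns.
#' @param orderBy optional per-region score; rows are sorted by it in
#'   descending order.
#' @return a numeric matrix, one row per (kept) region.
#' @export
regionProfile <- function(track, regions, mode = c("anchored", "scaled"),
                          flankBp = 2000, anchor = c("start", "end"),
                          nBodyBins = 100, orderBy = NULL) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  layout <- genomeLayout(track)
  B <- binSize(layout)
  off <- .chromBinOffsets(layout)
  nb <- .nBinsPerChrom(layout)
  v <- trackValues(track)
  known <- as.character(seqnames(regions)) %in% layout@chromNames
  if (any(!known))
    warning(sum(!known), " region(s) on unknown chromosomes skipped")
  regions <- regions[known]
  if (!is.null(orderBy)) orderBy <- orderBy[known]
  n <- length(regions)
  if (n == 0L) stop("no usable regions")
  minus <- as.character(strand(regions)) == "-"
  if (mode == "anchored") {
    if (flankBp %% B != 0) stop("flankBp must be a multiple of the bin size")
    f <- as.integer(flankBp %/% B)
    m <- matrix(NA_real_, n, 2L * f)
    for (i in seq_len(n)) {
      ch <- as.character(seqnames(regions))[i]
      s0 <- start(regions)[i] - 1; e0 <- end(regions)[i]
      a0 <- if (!minus[i]) (if (anchor == "start") s0 else e0) else
        (if (anchor == "start") e0 else s0)
      j <- a0 %/% B                       # 0-based local bin holding anchor
      loc <- (j - f + 1L):(j + f)         # 1-based local bins
      ok <- loc >= 1L & loc <= nb[[ch]]
      row <- rep(NA_real_, 2L * f)
      row[ok] <- v[off[[ch]] + loc[ok]]
      if (minus[i]) row <- rev(row)
      m[i, ] <- row
    }
  } else {
    if (any(width(regions) < B))
      stop("scaled mode requires track bin size <= region length")
    m <- matrix(NA_real_, n, nBodyBins)
    for (i in seq_len(n)) {
      ch <- as.character(seqnames(regions))[i]
      s0 <- start(regions)[i] - 1; e0 <- end(regions)[i]
      L <- e0 - s0
      edges <- s0 + L * (0:nBodyBins) / nBodyBins
      row <- vapply(seq_len(nBodyBins), function(j) {
        lo <- edges[j]; hi <- edges[j + 1L]
        b1 <- floor(lo / B) + 1L
        b2 <- ceiling(hi / B)
        b2 <- min(b2, nb[[ch]])
        vals <- v[off[[ch]] + (b1:b2)]
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      }, 0)
      if (minus[i]) row <- rev(row)
      m[i, ] <- row
    }
  }
  if (!is.null(orderBy)) m <- m[order(orderBy, decreasing = TRUE), , drop = FALSE]
  m
}
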