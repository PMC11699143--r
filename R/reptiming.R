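#' Construct RTFractionCounts
#'
#' Per-bin fragment counts for the four FACS-sorted S-phase fractions
#' (S1 earliest to S4 latest), either from four [FragmentSet-class] objects
#' (counted per bin in overlap mode) or from a ready-made counts matrix.
#'
#' @param s1,s2,s3,s4 [FragmentSet-class] objects, one per fraction
#'   (ignored when `counts` is given).
#' @param layout the common [GenomeLayout-class] (50 Kb bins are customary).
#' @param counts optional bins x 4 matrix (columns S1..S4).
#' @param libraryTotals total fragments per fraction; defaults to the
#'   fragment counts of the supplied sets, or column sums of `counts`.
#' @return an [RTFractionCounts-class].
#' @export
rtFractionCounts <- function(s1, s2, s3, s4, layout, counts = NULL,
                             libraryTotals = NULL) {
  if (is.null(counts)) {
    sets <- list(s1, s2, s3, s4)
    one <- LengthGroupScheme(c(1, .Machine$integer.max))  # count everything
    counts <- vapply(sets, function(fs)
      as.numeric(assay(countFragments(fs, layout, one), "counts")[, 1L]),
      numeric(nBins(layout)))
    if (is.null(libraryTotals))
      libraryTotals <- vapply(sets, length, 0L)
  } else if (is.null(libraryTotals)) {
    libraryTotals <- colSums(counts)
  }
  colnames(counts) <- c("S1", "S2", "S3", "S4")
  new("RTFractionCounts", layout = layout, counts = as.matrix(counts),
      libraryTotals = as.numeric(libraryTotals))
}

#' @rdname RTFractionCounts-class
#' @export
setMethod("genomeLayout", "RTFractionCounts", function(x) x@layout)

setMethod("show", "RTFractionCounts", function(object) {
  cat("RTFractionCounts:", nrow(object@counts), "bins x 4 fractions;",
      "library totals", paste(format(object@libraryTotals, big.mark = ","),
                              collapse = ", "), "\n")
})

#' Replication-timing score
#'
#' Each fraction's bin counts are scaled to a library size of 1 million,
#' then per bin `RT = log2((S1' + S2') / (S3' + S4'))`: positive = early
#' replicating, negative = late. Bins where the numerator or denominator is
#' zero are missing (no pseudocount).
#'
#' @param rc an [RTFractionCounts-class]; all library totals must be > 0.
#' @return a [SignalTrack-class] of RT values.
#' @export
rtScore <- function(rc) {
  if (any(rc@libraryTotals <= 0))
    stop("every fraction needs a positive library total")
  sc <- sweep(rc@counts, 2L, 1e6 / rc@libraryTotals, `*`)
  num <- sc[, 1L] + sc[, 2L]
  den <- sc[, 3L] + sc[, 4L]
  vals <- ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
  SignalTrack(vals, rc@layout)
}

#' Quantile-normalize a track to a target distribution
#'
#' Non-missing values are replaced by target quantiles at their rank: the
#' value of rank r among n maps to the target's empirical quantile at
#' probability (r - 0.5)/n, by linear interpolation of the target's
#' quantile function (plotting positions (j - 0.5)/m); tied input values
#' receive the mean of their mapped values. The transform is monotone
#' (rank-preserving); missing stays missing.
#'
#' @param track a [SignalTrack-class] with >= 2 non-missing values.
#' @param target numeric vector of target values (sorted internally).
#' @return a [SignalTrack-class].
#' @export
quantileNormalize <- function(track, target) {
  if (!length(target)) stop("target must be non-empty")
  target <- sort(as.numeric(target))
  v <- trackValues(track)
  obs <- which(!is.na(v))
  n <- length(obs)
  if (n < 2L) stop("need >= 2 non-missing values to quantile-normalize")
  x <- v[obs]
  o <- order(x)
  mapped <- stats::quantile(target, probs = (seq_len(n) - 0.5) / n,
                            type = 5, names = FALSE)
  out <- numeric(n)
  out[o] <- mapped
  out <- stats::ave(out, x)     # tie groups -> mean of their mapped values
  v[obs] <- out
  SignalTrack(v, genomeLayout(track))
}

#' Replication-timing domains
#'
#' Delegates to [callDomains()] with labels early (RT > 0) / late (RT < 0).
#'
#' @param rt an RT [SignalTrack-class].
#' @param minSizeBp minimum domain span in bp.
#' @param smoothSpan loess window in bins (0 = already smoothed).
#' @return a [DomainSet-class] with labels `early` / `late`.
#' @export
rtDomains <- function(rt, minSizeBp = 3 * binSize(genomeLayout(rt)),
                      smoothSpan = 10) {
  callDomains(rt, minSizeBp = minSizeBp, smoothSpan = smoothSpan,
              labels = c("early", "late"), provenance = "replication timing")
}
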