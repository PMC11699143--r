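#' Nucleosome wrapping score (NRS)
#'
#' Per bin, with fragment counts split at the break point X,
#' `NRS(X) = (a - b) / (a + b)` where `a` is the number of fragments of
#' length >= X (groups covering `[X, max)`) and `b` the number of length
#' < X (groups covering `[min, X)`). Larger NRS means tighter wrapping:
#' nucleosomes protected more of their DNA from MNase. Bins with
#' `a + b < minTotal` are missing.
#'
#' @param counts a [BinCountMatrix-class].
#' @param breakpoint break point X in bp; must coincide with a boundary of
#'   the counting scheme (NRS from grouped counts is only exact there).
#' @param minTotal minimum `a + b` for a defined value (default 1: only
#'   empty bins are missing).
#' @return a [SignalTrack-class] of NRS values in `[-1, 1]`.
#' @export
nrs <- function(counts, breakpoint = 140, minTotal = 1) {
  scheme <- lengthScheme(counts)
  b <- boundaries(scheme)
  if (!breakpoint %in% b)
    stop("breakpoint ", breakpoint, " is not a boundary of the scheme; ",
         "valid boundaries: ", paste(b, collapse = ", "))
  lower <- b[-length(b)]
  m <- assay(counts, "counts")
  aCols <- which(lower >= breakpoint)
  bCols <- which(lower < breakpoint)
  av <- if (length(aCols)) rowSums(m[, aCols, drop = FALSE]) else
    numeric(nrow(m))
  bv <- if (length(bCols)) rowSums(m[, bCols, drop = FALSE]) else
    numeric(nrow(m))
  tot <- av + bv
  vals <- ifelse(tot >= minTotal & tot > 0, (av - bv) / tot, NA_real_)
  SignalTrack(vals, genomeLayout(counts))
}

#' Nucleosome wrapping index (NRI)
#'
#' The genome-wide z-score of the NRS track: `Z(i) = (X(i) - mu) / sigma`
#' with mu and sigma the mean and population standard deviation (divisor n)
#' of NRS over all non-missing bins, all chromosomes pooled. The z-score
#' removes the systematic NRS shift introduced by the break-point choice and
#' by MNase digestion extent, leaving the relative ordering of bins.
#'
#' @param track an NRS [SignalTrack-class] (>= 2 non-missing bins).
#' @return a [SignalTrack-class]; missing bins stay missing; the non-missing
#'   values have mean 0 and population SD 1.
#' @export
nri <- function(track) {
  v <- trackValues(track)
  obs <- v[!is.na(v)]
  if (length(obs) < 2L) stop("need >= 2 non-missing bins to compute NRI")
  mu <- mean(obs)
  sigma <- sqrt(mean((obs - mu)^2))
  if (sigma == 0)
    stop("degenerate track: NRS is constant (sigma = 0), NRI undefined")
  SignalTrack((v - mu) / sigma, genomeLayout(track))
}

#' Loess-smooth a track per chromosome
#'
#' Local linear regression (degree 1, tricube weights) over a window of
#' `spanBins` non-missing neighbouring bins, applied independently per
#' chromosome (never across chromosome ends). Missing input bins remain
#' missing. A chromosome with fewer than `spanBins` non-missing bins passes
#' through unsmoothed, with a warning.
#'
#' @param track a [SignalTrack-class].
#' @param spanBins window width in bins (>= 2); default 10.
#' @return a smoothed [SignalTrack-class] of the same length.
#' @export
loessSmooth <- function(track, spanBins = 10) {
  if (spanBins < 2) stop("spanBins must be >= 2")
  layout <- genomeLayout(track)
  out <- trackValues(track)
  off <- .chromBinOffsets(layout)
  nb <- .nBinsPerChrom(layout)
  for (ch in layout@chromNames) {
    idx <- (off[[ch]] + 1L):(off[[ch]] + nb[[ch]])
    v <- out[idx]
    obs <- which(!is.na(v))
    if (length(obs) == 0L) next
    if (length(obs) < spanBins) {
      warning("chromosome ", ch, " has ", length(obs), " < ", spanBins,
              " non-missing bins; passed through unsmoothed")
      next
    }
    fit <- stats::loess(y ~ x,
                        data = data.frame(x = as.numeric(obs), y = v[obs]),
                        span = spanBins / length(obs), degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    v[obs] <- stats::predict(fit, newdata = data.frame(x = as.numeric(obs)))
    out[idx] <- v
  }
  SignalTrack(out, layout)
}

#' Pearson correlation between two tracks
#'
#' Computed over bins non-missing in both tracks.
#'
#' @param x,y [SignalTrack-class] objects on the same layout.
#' @return list with `r` (Pearson coefficient) and `n` (bins used).
#' @export
correlateTracks <- function(x, y) {
  .stopIfLayoutMismatch(genomeLayout(x), genomeLayout(y))
  vx <- trackValues(x); vy <- trackValues(y)
  ok <- !is.na(vx) & !is.na(vy)
  if (sum(ok) < 3L) stop("need >= 3 bins non-missing in both tracks")
  if (stats::var(vx[ok]) == 0 || stats::var(vy[ok]) == 0)
    stop("zero variance in one of the tracks; correlation undefined")
  list(r = stats::cor(vx[ok], vy[ok]), n = sum(ok))
}

#' Normalize one track by another
#'
#' Per-bin ratio `(track + pseudocount) / (denom + pseudocount)`; used e.g.
#' to express histone-modification signal relative to total histone signal
#' so that nucleosome-density variation cancels. Bins where the denominator
#' is missing, or zero with `pseudocount = 0`, are missing.
#'
#' @param track,denom [SignalTrack-class] objects on the same layout.
#' @param pseudocount added to both numerator and denominator (default 0).
#' @return a [SignalTrack-class].
#' @export
normalizeBy <- function(track, denom, pseudocount = 0) {
  .stopIfLayoutMismatch(genomeLayout(track), genomeLayout(denom))
  num <- trackValues(track) + pseudocount
  den <- trackValues(denom) + pseudocount
  vals <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  vals[is.na(trackValues(track))] <- NA_real_
  SignalTrack(vals, genomeLayout(track))
}
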