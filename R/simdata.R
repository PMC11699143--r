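#' Construct a SimulationSpec
#'
#' Defines a synthetic genome of alternating domains with known per-domain
#' tightness theta. Fragment lengths are drawn from a two-component
#' truncated-normal mixture: a "long" nucleosomal-scale component
#' (mean 167 bp, sd 15, truncated to \[50, 250\]) sampled with probability
#' theta, and a "short" sub-nucleosomal component (mean 110 bp, sd 25,
#' truncated) with probability 1 - theta. `digestionShift` subtracts a
#' constant from theta genome-wide, emulating longer MNase digestion.
#'
#' @param layout a [GenomeLayout-class].
#' @param domainLengthBp length of each alternating domain (bp); must divide
#'   every chromosome length. Ignored when `domainPlan` is given.
#' @param thetaHigh,thetaLow tightness of the alternating domains (defaults
#'   0.8 / 0.2: clearly tight vs clearly loose, noise-separated at the
#'   default depth).
#' @param domainPlan optional explicit data.frame(chrom, length, theta);
#'   lengths must tile each chromosome exactly.
#' @param depth expected fragments per bin (Poisson mean), default 200.
#' @param digestionShift delta in \[0, 1\], default 0.
#' @param seed integer master seed.
#' @param longMean,longSd,shortMean,shortSd,minLen,maxLen mixture parameters.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(layout, domainLengthBp = NULL, thetaHigh = 0.8,
                           thetaLow = 0.2, domainPlan = NULL, depth = 200,
                           digestionShift = 0, seed = 1L,
                           longMean = 167, longSd = 15,
                           shortMean = 110, shortSd = 25,
                           minLen = 50, maxLen = 250) {
  if (is.null(domainPlan)) {
    if (is.null(domainLengthBp))
      stop("supply domainLengthBp or an explicit domainPlan")
    plans <- lapply(seq_along(layout@chromNames), function(ci) {
      L <- layout@chromLengths[ci]
      if (L %% domainLengthBp != 0)
        stop("domainLengthBp must divide the length of ",
             layout@chromNames[ci])
      k <- L %/% domainLengthBp
      data.frame(chrom = layout@chromNames[ci],
                 length = rep(domainLengthBp, k),
                 theta = rep(c(thetaHigh, thetaLow), length.out = k))
    })
    domainPlan <- do.call(rbind, plans)
  }
  new("SimulationSpec", layout = layout, domainPlan = domainPlan,
      depth = depth, digestionShift = digestionShift,
      seed = as.integer(seed),
      lengthModel = list(longMean = longMean, longSd = longSd,
                         shortMean = shortMean, shortSd = shortSd,
                         minLen = minLen, maxLen = maxLen))
}

#' @rdname SimulationSpec-class
#' @export
setMethod("genomeLayout", "SimulationSpec", function(x) x@layout)

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", nrow(object@domainPlan), "domains, depth",
      object@depth, ", digestionShift", object@digestionShift,
      ", seed", object@seed, "\n")
})

# deterministic sub-seed per (chromosome, bin, condition); < 2^31
.subSeed <- function(seed, chromIdx, bin, condCode) {
  as.integer((as.numeric(seed) * 1000003 + chromIdx * 699053 +
                bin * 101 + condCode * 7777) %% 2147483647)
}

# inverse-CDF truncated-normal sampler
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Per-bin ground-truth tightness of a SimulationSpec
#'
#' @param spec a [SimulationSpec-class].
#' @return numeric vector, theta per bin (a bin inherits the theta of the
#'   domain containing its start).
#' @export
simTheta <- function(spec) {
  layout <- spec@layout
  nb <- .nBinsPerChrom(layout)
  out <- numeric(0)
  for (ch in layout@chromNames) {
    dp <- spec@domainPlan[spec@domainPlan$chrom == ch, , drop = FALSE]
    dEnd <- cumsum(dp$length)
    binStart0 <- (seq_len(nb[[ch]]) - 1L) * layout@binSize
    out <- c(out, dp$theta[findInterval(binStart0, c(0, dEnd),
                                        rightmost.closed = FALSE)])
  }
  out
}

#' Generate the genome side of a simulation
#'
#' Returns the layout, the ground-truth [DomainSet-class] (theta > 0.5 ->
#' Ti, theta < 0.5 -> Lo; domains with theta exactly 0.5 are omitted and
#' flagged), and optionally an i.i.d.-uniform random FASTA genome for
#' sequence-feature tests. Deterministic given `spec@seed`.
#'
#' @param spec a [SimulationSpec-class].
#' @param withFasta also generate a random genome sequence.
#' @return list with `layout`, `truth` (DomainSet), `nUndefined` (number of
#'   theta = 0.5 domains omitted), and `genome` (DNAStringSet or NULL).
#' @export
simulateGenome <- function(spec, withFasta = FALSE) {
  layout <- spec@layout
  dp <- spec@domainPlan
  starts <- unlist(lapply(split(dp$length, factor(dp$chrom,
                                                  levels = layout@chromNames)),
                          function(l) cumsum(c(0, l[-length(l)]))),
                   use.names = FALSE)
  ord <- order(factor(dp$chrom, levels = layout@chromNames))
  dp <- dp[ord, , drop = FALSE]
  defined <- dp$theta != 0.5
  gr <- GRanges(dp$chrom[defined],
                IRanges(start = starts[defined] + 1,
                        width = dp$length[defined]),
                seqinfo = Seqinfo(layout@chromNames, layout@chromLengths))
  mcols(gr)$label <- ifelse(dp$theta[defined] > 0.5, "Ti", "Lo")
  mcols(gr)$score <- dp$theta[defined]
  truth <- DomainSet(gr, labelSet = c("Ti", "Lo"), provenance = "simulated truth")
  genome <- NULL
  if (withFasta) {
    genome <- Biostrings::DNAStringSet(vapply(
      seq_along(layout@chromNames), function(ci) {
        set.seed(.subSeed(spec@seed, ci, 0L, 99L))
        paste(sample(c("A", "C", "G", "T"), layout@chromLengths[ci],
                     replace = TRUE), collapse = "")
      }, ""))
    names(genome) <- layout@chromNames
  }
  list(layout = layout, truth = truth, nUndefined = sum(!defined),
       genome = genome)
}

#' Simulate a FragmentSet with known ground truth
#'
#' Per bin, the fragment count is Poisson(`depth`); each fragment's length
#' is drawn from the two-component mixture at effective tightness
#' `clamp(theta_condition - digestionShift, 0, 1)`, where theta_condition is
#' theta (parental), theta - nascentDelta (nascent, just-deposited
#' nucleosomes wrap looser) or theta + chaseDelta (chase, maturation
#' tightens wrapping). Start positions are uniform within the bin.
#' Reproducible: every (chromosome, bin, condition) derives its own
#' sub-seed from `spec@seed`.
#'
#' @param spec a [SimulationSpec-class].
#' @param condition `"parental"`, `"nascent"` or `"chase"`.
#' @param nascentDelta theta reduction for nascent chromatin (default 0.15).
#' @param chaseDelta theta gain after chase maturation (default 0.1).
#' @return a [FragmentSet-class].
#' @export
simulateFragments <- function(spec,
                              condition = c("parental", "nascent", "chase"),
                              nascentDelta = 0.15, chaseDelta = 0.1) {
  condition <- match.arg(condition)
  condCode <- match(condition, c("parental", "nascent", "chase"))
  layout <- spec@layout
  lm <- spec@lengthModel
  theta <- simTheta(spec)
  theta <- switch(condition,
                  parental = theta,
                  nascent = theta - nascentDelta,
                  chase = theta + chaseDelta)
  theta <- pmin(pmax(theta - spec@digestionShift, 0), 1)
  nb <- .nBinsPerChrom(layout)
  chromL <- list(); startL <- list(); endL <- list()
  g <- 0L
  for (ci in seq_along(layout@chromNames)) {
    ch <- layout@chromNames[ci]
    clen <- layout@chromLengths[ci]
    for (b in seq_len(nb[[ci]])) {
      g <- g + 1L
      set.seed(.subSeed(spec@seed, ci, b, condCode))
      n <- rpois(1L, spec@depth)
      if (n == 0L) next
      isLong <- runif(n) < theta[g]
      len <- numeric(n)
      if (any(isLong))
        len[isLong] <- .rtruncnorm(sum(isLong), lm$longMean, lm$longSd,
                                   lm$minLen, lm$maxLen)
      if (any(!isLong))
        len[!isLong] <- .rtruncnorm(sum(!isLong), lm$shortMean, lm$shortSd,
                                    lm$minLen, lm$maxLen)
      len <- pmin(pmax(round(len), lm$minLen), lm$maxLen)
      binStart0 <- (b - 1L) * layout@binSize
      binEnd0 <- min(binStart0 + layout@binSize, clen)
      s0 <- floor(runif(n, binStart0, binEnd0))
      s0 <- pmin(s0, clen - len)        # keep fragments inside the contig
      s0 <- pmax(s0, 0)
      chromL[[g]] <- rep(ch, n)
      startL[[g]] <- s0
      endL[[g]] <- s0 + len
    }
  }
  chrom <- unlist(chromL, use.names = FALSE)
  if (is.null(chrom)) chrom <- character(0)
  gr <- GRanges(chrom,
                IRanges(start = unlist(startL, use.names = FALSE) + 1,
                        end = unlist(endL, use.names = FALSE)),
                seqinfo = Seqinfo(layout@chromNames, layout@chromLengths))
  FragmentSet(gr, provenance = paste0("simulated:", condition,
                                      ":seed", spec@seed))
}
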