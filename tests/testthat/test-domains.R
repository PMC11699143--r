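test_that("sign runs become domains; short runs are absorbed", {
  # [+,+,+,-,-], min size 1 bin -> Ti(0-2), Lo(3-4)
  ds <- callDomains(signTrack(c(1, 1, 1, -1, -1)), minSizeBp = 100,
                    smoothSpan = 0)
  gr <- domainRanges(ds)
  expect_equal(length(gr), 2L)
  expect_equal(S4Vectors::mcols(gr)$label, c("Ti", "Lo"))
  expect_equal(GenomicRanges::start(gr) - 1, c(0, 300))
  expect_equal(GenomicRanges::end(gr), c(300, 500))

  # all-positive chromosome -> single Ti domain spanning it
  ds2 <- callDomains(signTrack(c(2, 1, 3, 1)), minSizeBp = 100,
                     smoothSpan = 0)
  expect_equal(length(ds2), 1L)
  expect_equal(S4Vectors::mcols(domainRanges(ds2))$label, "Ti")
  expect_equal(GenomicRanges::width(domainRanges(ds2)), 400)

  # [+,+,-,+,+] with min size 2 bins: 1-bin negative run absorbed
  ds3 <- callDomains(signTrack(c(1, 1, -1, 1, 1)), minSizeBp = 200,
                     smoothSpan = 0)
  expect_equal(length(ds3), 1L)
  expect_equal(S4Vectors::mcols(domainRanges(ds3))$label, "Ti")
})

test_that("zero bins take the sign of the nearest non-zero neighbour, ties left", {
  # zero equidistant between - (left) and + (right): left wins
  ds <- callDomains(signTrack(c(-1, -1, 0, 1, 1)), minSizeBp = 100,
                    smoothSpan = 0)
  gr <- domainRanges(ds)
  expect_equal(S4Vectors::mcols(gr)$label, c("Lo", "Ti"))
  expect_equal(GenomicRanges::end(gr)[1], 300)      # zero bin joined Lo
})

test_that("missing gaps of one bin are bridged; larger gaps split domains", {
  ds <- callDomains(signTrack(c(1, 1, NA, 1, 1)), minSizeBp = 100,
                    smoothSpan = 0)
  expect_equal(length(ds), 1L)                      # bridged, one Ti domain
  expect_equal(GenomicRanges::width(domainRanges(ds)), 500)
  ds2 <- callDomains(signTrack(c(1, 1, NA, NA, 1, 1)), minSizeBp = 100,
                     smoothSpan = 0)
  expect_equal(length(ds2), 2L)                     # split at the 2-bin gap
  expect_equal(GenomicRanges::width(domainRanges(ds2)), c(200, 200))
  # and gap-split junctions are not borders
  expect_equal(nrow(listBorders(ds2, c("Ti", "Lo"))), 0L)
})

test_that("segmentation equals the exhaustive absorption oracle (length <= 7)", {
  for (n in 1:7) {
    combos <- expand.grid(rep(list(c(-1, 1)), n))
    for (minBins in 1:3) {
      for (i in seq_len(nrow(combos))) {
        signs <- as.numeric(combos[i, ])
        got <- callDomains(signTrack(signs), minSizeBp = minBins * 100,
                           smoothSpan = 0)
        gr <- domainRanges(got)
        gotLab <- rep(S4Vectors::mcols(gr)$label,
                      GenomicRanges::width(gr) / 100)
        want <- ifelse(oracleSegment(signs, minBins) > 0, "Ti", "Lo")
        expect_identical(gotLab, want)
      }
    }
  }
})

test_that("domain calling is idempotent on its own label indicator track", {
  set.seed(21)
  signs <- sign(rnorm(60))
  ds <- callDomains(signTrack(signs), minSizeBp = 300, smoothSpan = 0)
  gr <- domainRanges(ds)
  indicator <- rep(ifelse(S4Vectors::mcols(gr)$label == "Ti", 1, -1),
                   GenomicRanges::width(gr) / 100)
  ds2 <- callDomains(signTrack(indicator), minSizeBp = 300, smoothSpan = 0)
  expect_equal(GenomicRanges::start(domainRanges(ds2)),
               GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(domainRanges(ds2)),
               GenomicRanges::end(gr))
  expect_equal(S4Vectors::mcols(domainRanges(ds2))$label,
               S4Vectors::mcols(gr)$label)
})

test_that("Ti bp + Lo bp equals covered bp (complementarity)", {
  set.seed(22)
  v <- rnorm(80)
  v[c(10, 11, 12, 40)] <- NA                       # one real gap, one bridged
  ds <- callDomains(signTrack(v), minSizeBp = 200, smoothSpan = 0)
  gr <- domainRanges(ds)
  covered <- sum(GenomicRanges::width(gr))
  # segments: bins 1-9 and 13-80 (gap 10-12 >= 2 bins; bin 40 bridged)
  expect_equal(covered, (9 + 68) * 100)
})

test_that("overlapFraction matches the example and the self-overlap identity", {
  mk <- function(df, labels) {
    gr <- GenomicRanges::GRanges(df$chrom,
      IRanges::IRanges(start = df$start + 1, end = df$end))
    S4Vectors::mcols(gr)$label <- df$label
    DomainSet(gr, labelSet = labels)
  }
  q <- mk(data.frame(chrom = "c1", start = c(0, 1000), end = c(1000, 2000),
                     label = c("Ti", "Lo")), c("Ti", "Lo"))
  r <- mk(data.frame(chrom = "c1", start = c(500, 1500), end = c(1500, 2000),
                     label = c("A", "B")), c("A", "B"))
  m <- overlapFraction(q, r)
  expect_equal(m["A", "Ti"], 0.5)                 # half of A overlapped by Ti
  expect_equal(m["A", "Lo"], 0.5)
  expect_equal(m["B", "Lo"], 1.0)
  self <- overlapFraction(q, q)
  expect_equal(unname(diag(self)), c(1, 1))
  expect_equal(self["Ti", "Lo"], 0)
  expect_true(all(rowSums(m) <= 1 + 1e-12))
  expect_error(overlapFraction(q, DomainSet(GenomicRanges::GRanges(),
                                            labelSet = c("A", "B"))),
               "empty")
})

test_that("overlapFraction matches the per-base bitmap oracle on random genomes", {
  set.seed(31)
  sizes <- c(c1 = 2000, c2 = 1500)
  for (rep in 1:10) {
    mkRandom <- function(labels) {
      grs <- lapply(names(sizes), function(ch) {
        cuts <- sort(sample(1:(sizes[[ch]] - 1), 3))
        bounds <- c(0, cuts, sizes[[ch]])
        keep <- sort(sample(seq_len(length(bounds) - 1L), 3))
        GenomicRanges::GRanges(ch, IRanges::IRanges(
          start = bounds[keep] + 1, end = bounds[keep + 1L]))
      })
      gr <- suppressWarnings(do.call(c, grs))
      # both labels always present so every overlap fraction is defined
      S4Vectors::mcols(gr)$label <-
        sample(c(labels, sample(labels, length(gr) - 2L, replace = TRUE)))
      DomainSet(gr, labelSet = labels)
    }
    q <- mkRandom(c("Ti", "Lo"))
    r <- mkRandom(c("A", "B"))
    expect_equal(overlapFraction(q, r), oracleOverlapFraction(q, r, sizes))
  }
})

test_that("borders are directional, counted once, absent at chromosome ends", {
  ds <- callDomains(signTrack(c(1, 1, -1, -1, 1, 1)), minSizeBp = 100,
                    smoothSpan = 0)
  tl <- listBorders(ds, c("Ti", "Lo"))
  lt <- listBorders(ds, c("Lo", "Ti"))
  expect_equal(nrow(tl), 1L)
  expect_equal(nrow(lt), 1L)
  expect_equal(tl$pos, 200)
  expect_equal(lt$pos, 400)
  single <- callDomains(signTrack(rep(1, 4)), minSizeBp = 100, smoothSpan = 0)
  expect_equal(nrow(listBorders(single, c("Ti", "Lo"))), 0L)
})

test_that("border counts on a multi-domain genome match hand enumeration", {
  set.seed(44)
  layout <- GenomeLayout(c(c1 = 5e3, c2 = 5e3), 100)
  signs <- rep(rep(c(1, -1), 10), each = 5)        # 20 alternating domains
  ds <- callDomains(SignalTrack(signs, layout), minSizeBp = 100,
                    smoothSpan = 0)
  # per chromosome: 10 domains alternating Ti-first -> 5 Ti->Lo, 4 Lo->Ti
  expect_equal(nrow(listBorders(ds, c("Ti", "Lo"))), 10L)
  expect_equal(nrow(listBorders(ds, c("Lo", "Ti"))), 8L)
})

test_that("border profiles read first-label to second-label with NA padding", {
  layout <- GenomeLayout(c(c1 = 1e3), 100)
  v <- c(rep(-1, 5), rep(1, 5))
  ds <- callDomains(SignalTrack(v, layout), minSizeBp = 100, smoothSpan = 0)
  b <- listBorders(ds, c("Lo", "Ti"))
  bp <- borderProfile(SignalTrack(v, layout), b, flankBp = 300)
  expect_equal(unname(profileMean(bp)), c(-1, -1, -1, 1, 1, 1))
  # border 2 bins from the chromosome start: first column NA for that row
  v2 <- c(-1, -1, 1, 1, 1, 1, 1, 1, 1, 1)
  ds2 <- callDomains(SignalTrack(v2, layout), minSizeBp = 100, smoothSpan = 0)
  b2 <- listBorders(ds2, c("Lo", "Ti"))
  bp2 <- borderProfile(SignalTrack(v2, layout), b2, flankBp = 300)
  expect_true(is.na(profileMatrix(bp2)[1, 1]))
  expect_false(anyNA(profileMatrix(bp2)[1, -1]))
  expect_error(borderProfile(SignalTrack(v, layout),
                             b[0, , drop = FALSE], 300), "zero")
})

test_that("mean border profile recovers a noisy step within 3 SEM", {
  set.seed(55)
  nb <- 40; f <- 3; sd0 <- 0.5
  layout <- GenomeLayout(c(c1 = nb * 100), 100)
  rows <- t(vapply(seq_len(50), function(i)
    rep(c(-1, 1), each = f) + rnorm(2 * f, 0, sd0), numeric(2 * f)))
  # place each replicate's step at bin 20 of its own track and profile it
  got <- matrix(NA_real_, 50, 2 * f)
  for (i in seq_len(50)) {
    v <- rep(NA_real_, nb)
    v[(20 - f + 1):(20 + f)] <- rows[i, ]
    bdf <- data.frame(chrom = "c1", pos = 20 * 100)
    got[i, ] <- profileMatrix(borderProfile(SignalTrack(v, layout), bdf,
                                            f * 100))
  }
  sem <- sd0 / sqrt(50)
  expect_true(all(abs(colMeans(got) - rep(c(-1, 1), each = f)) <= 3 * sem))
})

test_that("region profiles honour strand, anchoring and scaling", {
  layout <- GenomeLayout(c(c1 = 1e4), 100)
  v <- seq_len(100)
  tr <- SignalTrack(v, layout)
  # constant track -> constant matrix in both modes
  cst <- SignalTrack(rep(2, 100), layout)
  reg <- GenomicRanges::GRanges("c1", IRanges::IRanges(2001, 4000),
                                strand = "+")
  expect_true(all(regionProfile(cst, reg, "anchored", flankBp = 500) == 2))
  expect_true(all(regionProfile(cst, reg, "scaled", nBodyBins = 10) == 2))
  # identical plus and minus regions give mirror-image rows
  regs <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(2001, 2001),
                                                        c(4000, 4000)),
                                 strand = c("+", "-"))
  m <- regionProfile(tr, regs, "scaled", nBodyBins = 20)
  expect_equal(m[1, ], rev(m[2, ]))
  # anchored: minus strand anchors at the region end and reads leftward
  m2 <- regionProfile(tr, regs, "anchored", flankBp = 500, anchor = "start")
  expect_equal(m2[1, ], as.numeric(16:25))        # bins around the + TSS
  expect_equal(m2[2, ], as.numeric(45:36))        # reversed around the - TSS
  # unknown chromosome skipped with warning
  regs2 <- GenomicRanges::GRanges(c("c1", "cX"),
                                  IRanges::IRanges(c(2001, 1), c(4000, 2000)))
  expect_warning(m3 <- regionProfile(tr, regs2, "scaled", nBodyBins = 5),
                 "skipped")
  expect_equal(nrow(m3), 1L)
})

test_that("an anchored peak lands in the first downstream column", {
  layout <- GenomeLayout(c(c1 = 1e5), 100)
  set.seed(66)
  tssBins <- sample(20:980, 100)
  v <- rep(0, 1000)
  for (b in tssBins) v[b] <- v[b] + 1             # +1 peak in the anchor bin
  tss0 <- (tssBins - 1) * 100
  regs <- GenomicRanges::GRanges("c1", IRanges::IRanges(tss0 + 1, tss0 + 500),
                                 strand = "+")
  m <- regionProfile(SignalTrack(v, layout), regs, "anchored", flankBp = 500)
  prof <- colMeans(m, na.rm = TRUE)
  expect_equal(which.max(prof), 6L)               # flank = 5 bins; anchor next
})
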