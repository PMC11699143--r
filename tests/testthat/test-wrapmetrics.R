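test_that("fragment counting handles single- and cross-bin fragments", {
  layout <- GenomeLayout(c(chrA = 5e3), 1e3)
  scheme <- LengthGroupScheme(c(50, 140, 250))
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(
    start = c(101, 951), end = c(250, 1150)))       # [100,250), [950,1150)
  fs <- FragmentSet(gr)
  m <- SummarizedExperiment::assay(countFragments(fs, layout, scheme),
                                   "counts")
  expect_equal(unname(m[1, 2]), 2L)         # both overlap bin 0 (150, 200 bp)
  expect_equal(unname(m[2, 2]), 1L)         # the cross-bin one also in bin 1
  expect_equal(sum(m), 3L)                  # (fragment, bin) pairs
})

test_that("midpoint mode assigns each fragment to exactly one bin", {
  layout <- GenomeLayout(c(chrA = 5e3), 1e3)
  scheme <- LengthGroupScheme(c(50, 140, 250))
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(
    start = c(101, 951), end = c(250, 1150)))
  fs <- FragmentSet(gr)
  m <- SummarizedExperiment::assay(
    countFragments(fs, layout, scheme, mode = "midpoint"), "counts")
  expect_equal(sum(m), 2L)
  expect_equal(unname(m[2, 2]), 1L)         # midpoint of [950,1150) is 1050
})

test_that("counting matches the O(N*B) brute-force oracle", {
  layout <- GenomeLayout(c(chrA = 8e3, chrB = 4e3), 1e3)
  fs <- randomFragments(layout, 400, seed = 9)
  scheme <- defaultLengthGroups()
  m <- SummarizedExperiment::assay(countFragments(fs, layout, scheme),
                                   "counts")
  expect_equal(unname(m), oracleCountMatrix(fs, layout, scheme))
})

test_that("NRS formula, range and missing-bin rules hold", {
  layout <- GenomeLayout(c(chrA = 4e3), 1e3)
  scheme <- LengthGroupScheme(c(50, 140, 250))
  counts <- matrix(c(10, 0, 20, 0,          # b column (50-140)
                     10, 20, 0, 0), ncol = 2)  # a column (140-250)
  cm <- BinCountMatrix(counts, layout, scheme)
  v <- trackValues(nrs(cm, 140))
  expect_equal(v, c(0, 1, -1, NA))
  expect_error(nrs(cm, 100), "boundar")
  # a=30, b=10 -> 0.5
  cm2 <- BinCountMatrix(matrix(c(10, 0, 0, 0, 30, 0, 0, 0), ncol = 2),
                        layout, scheme)
  expect_equal(trackValues(nrs(cm2, 140))[1], 0.5)
})

test_that("swapping the a and b column blocks negates NRS exactly", {
  layout <- GenomeLayout(c(chrA = 1e4), 1e3)
  scheme <- LengthGroupScheme(c(50, 140, 250))
  set.seed(5)
  counts <- matrix(rpois(20, 8), ncol = 2)
  v1 <- trackValues(nrs(BinCountMatrix(counts, layout, scheme), 140))
  v2 <- trackValues(nrs(BinCountMatrix(counts[, 2:1], layout, scheme), 140))
  expect_equal(v2, -v1)
})

test_that("NRI is the genome-wide population z-score", {
  layout <- GenomeLayout(c(chrA = 300), 100)
  z <- trackValues(nri(SignalTrack(c(-1, 0, 1), layout)))
  # mu = 0, population sigma = sqrt(2/3); frozen from the direct computation
  expect_equal(z, c(-1.22474487139159, 0, 1.22474487139159), tolerance = 1e-12)
  # mean 0, population SD 1 over non-missing bins
  layout2 <- GenomeLayout(c(chrA = 1e4), 100)
  set.seed(2)
  vals <- ifelse(runif(100) < 0.1, NA, rnorm(100))
  z2 <- trackValues(nri(SignalTrack(vals, layout2)))
  expect_equal(mean(z2, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z2^2, na.rm = TRUE)), 1, tolerance = 1e-9)
  expect_equal(is.na(z2), is.na(vals))
})

test_that("NRI is invariant under positive affine transforms of NRS", {
  layout <- GenomeLayout(c(chrA = 5e3), 100)
  set.seed(3)
  v <- rnorm(50)
  z1 <- trackValues(nri(SignalTrack(v, layout)))
  z2 <- trackValues(nri(SignalTrack(2 * v + 3, layout)))
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("constant NRS tracks are rejected as degenerate", {
  layout <- GenomeLayout(c(chrA = 500), 100)
  expect_error(nri(SignalTrack(rep(0.4, 5), layout)), "constant|degenerate")
})

test_that("loess smoothing reproduces constants and straight lines", {
  layout <- GenomeLayout(c(chrA = 1e4), 100)
  cst <- trackValues(loessSmooth(SignalTrack(rep(0.7, 100), layout), 10))
  expect_equal(cst, rep(0.7, 100), tolerance = 1e-9)
  ramp <- seq(-1, 1, length.out = 100)
  sm <- trackValues(loessSmooth(SignalTrack(ramp, layout), 10))
  expect_equal(sm, ramp, tolerance = 1e-9)
})

test_that("loess smoothing of a step matches the reference local regression", {
  layout <- GenomeLayout(c(chrA = 1e4), 100)
  step <- rep(c(0, 1), each = 50)
  sm <- trackValues(loessSmooth(SignalTrack(step, layout), 10))
  expect_true(all(diff(sm) >= -1e-9))              # monotone non-decreasing
  expect_true(all(sm >= -1e-6 & sm <= 1 + 1e-6))
  ref <- oracleLocalLinear(1:100, step, k = 10)
  expect_equal(sm, ref, tolerance = 1e-6)
})

test_that("smoothing keeps missing bins missing and respects chromosome ends", {
  layout <- GenomeLayout(c(chrA = 3e3, chrB = 3e3), 100)
  v <- c(seq(0, 1, length.out = 30), rep(5, 30))
  v[10] <- NA
  sm <- trackValues(loessSmooth(SignalTrack(v, layout), 10))
  expect_true(is.na(sm[10]))
  expect_equal(sm[31:60], rep(5, 30), tolerance = 1e-9)  # no bleed across chroms
})

test_that("a chromosome with too few bins passes through with a warning", {
  layout <- GenomeLayout(c(chrA = 300), 100)
  expect_warning(sm <- loessSmooth(SignalTrack(c(1, 2, 3), layout), 10),
                 "unsmoothed")
  expect_equal(trackValues(sm), c(1, 2, 3))
})

test_that("track correlation returns r and n over jointly observed bins", {
  layout <- GenomeLayout(c(chrA = 1e3), 100)
  x <- SignalTrack(c(1, 2, 3, 4, 5, NA, 7, 8, 9, 10), layout)
  y <- SignalTrack(c(1, 2, 3, 4, 5, 6, 7, 8, NA, 10), layout)
  res <- correlateTracks(x, y)
  expect_equal(res$r, 1)
  expect_equal(res$n, 8L)
  yneg <- SignalTrack(-trackValues(x), layout)
  expect_equal(correlateTracks(x, yneg)$r, -1)
  expect_error(correlateTracks(x, SignalTrack(rep(1, 10), layout)),
               "variance")
})

test_that("independent white-noise tracks are uncorrelated under the null", {
  layout <- GenomeLayout(c(chrA = 1e6), 100)    # 10,000 bins
  set.seed(99)
  hits <- vapply(seq_len(200), function(i) {
    r <- cor(rnorm(10000), rnorm(10000))
    abs(r) < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.99)
  # spot-check through the track interface with one replicate
  set.seed(100)
  r <- correlateTracks(SignalTrack(rnorm(10000), layout),
                       SignalTrack(rnorm(10000), layout))
  expect_lt(abs(r$r), 0.05)
})

test_that("normalizeBy computes elementwise ratios with missing propagation", {
  layout <- GenomeLayout(c(chrA = 500), 100)
  x <- SignalTrack(c(2, 4, 6, NA, 10), layout)
  d <- SignalTrack(c(2, 0, 3, 2, NA), layout)
  v <- trackValues(normalizeBy(x, d))
  expect_equal(v, c(1, NA, 2, NA, NA))
  set.seed(8)
  a <- runif(5) + 1; b <- runif(5) + 1
  v2 <- trackValues(normalizeBy(SignalTrack(a, layout),
                                SignalTrack(b, layout), pseudocount = 0.5))
  expect_equal(v2, (a + 0.5) / (b + 0.5))
})
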