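# wrapseq

Genome-wide quantification of **nucleosome wrapping states** from
paired-end MNase (or MNase-ChIP) fragment lengths, for chromatin biologists
analyzing "wrapping-seq"-style data: how tightly is nucleosomal DNA held
onto the histone core, where, and how does that organize into domains that
line up with Hi-C compartments and replication timing?

## The idea

MNase chews back any DNA the histone octamer does not protect, so the
*length* of a sequenced fragment reports how much of its nucleosome was
wrapped. Within each genomic bin, fragments retained in the 50–250 bp
window are split at a break point *X* (default 140 bp) into *a* fragments
of length ≥ *X* and *b* shorter ones, giving the **nucleosome wrapping
score**

    NRS(X) = (a − b) / (a + b)   ∈ [−1, +1]

(+1 = all nucleosome-scale fragments, tight wrapping; −1 = all
sub-nucleosomal, loose). Because NRS drifts wholesale with digestion time
and break-point choice, the genome-wide z-score

    Z(i) = (X(i) − μ) / σ

— the **nucleosome wrapping index (NRI)** — captures the *relative*
ordering of bins and is robust to both. Maximal runs of constant NRI sign
are **nucleosome wrapping domains**: TiNRD (tight, NRI > 0) and LoNRD
(loose, NRI < 0).

The package covers the full analysis path: fragment I/O (BED/BAM) and
length classification; binned counting; NRS/NRI and loess smoothing; domain
segmentation with overlap-fraction matrices and border/TSS profile
matrices; replication timing from four S-phase fractions
(log2((S1+S2)/(S3+S4)) with quantile normalization); MNase cut-site
sequence diagnostics; parental-vs-nascent NRS comparison; and a
synthetic-data generator with known ground truth that makes every stage
testable without external data.

## Worked example

Simulate a 1 Mb genome (1 kb bins) of alternating tight/loose 20 kb domains
and recover them:

```r
library(wrapseq)

layout <- GenomeLayout(c(chr1 = 1e6), binSize = 1e3)
spec   <- simulationSpec(layout, domainLengthBp = 2e4, depth = 200, seed = 7)
frags  <- simulateFragments(spec)
frags
#> FragmentSet: 199882 fragments (simulated:parental:seed7)
#>   length range: 50 - 231 bp

counts <- countFragments(frags, layout, defaultLengthGroups())
wrap   <- nrs(counts, breakpoint = 140)
index  <- nri(wrap)
round(head(trackValues(wrap)), 3)
#> [1] 0.543 0.539 0.622 0.671 0.549 0.624

nrds <- callDomains(index, minSizeBp = 3e3, smoothSpan = 10)
nrds
#> DomainSet: 50 domains ( Ti=25, Lo=25 )
#>   median length: 20,000 bp

truth <- simulateGenome(spec)$truth
round(overlapFraction(nrds, truth), 3)
#>       Ti    Lo
#> Ti 1.000 0.000
#> Lo 0.002 0.998

correlateTracks(index, SignalTrack(simTheta(spec), layout))$r
#> [1] 0.9926915
```

The first bins sit in a tight domain, so their NRS is strongly positive.
All 50 planted domains are recovered; the overlap-fraction matrix (rows =
truth labels, entries = fraction of truth bp overlapped by each called
label) is essentially the identity, and the NRI track correlates at
r ≈ 0.99 with the latent per-bin tightness that generated the data.

On real data the entry point is `loadFragments()` (BED3+ or
coordinate-sorted indexed BAM; proper-pair template intervals, 50–250 bp
closed filter), and tracks/domains round-trip through bedGraph and BED4
via `writeBedGraph()` / `writeDomainsBed()` and friends. A thin CLI over
the same functions ships in `inst/scripts/wrapseq.R`
(`fragments`, `nrs`, `nri`, `smooth`, `domains`, `overlap`, `borders`,
`rt`, `simulate`, `cutsites`, `compare`).

See the vignette (`vignettes/wrapping-seq-methods.Rmd`) for the model,
parameter defaults, numerical conventions, and what the simulator does and
does not emulate.

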