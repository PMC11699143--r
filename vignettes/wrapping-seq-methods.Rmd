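---
title: "Quantifying nucleosome wrapping states from fragment lengths"
author: "wrapseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome wrapping states from fragment lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrapseq)
```

## The measurement and the model

Micrococcal nuclease (MNase) digests the linker DNA between nucleosomes and
nibbles into whatever DNA the histone octamer fails to protect. A fully
wrapped nucleosome shields roughly 147 bp; a partially unwrapped one shields
less, so its protected fragment is shorter. Paired-end sequencing of
MNase-digested (optionally histone-ChIP-enriched) chromatin therefore turns
fragment *length* into a readout of wrapping: within any genomic interval,
an excess of long (nucleosome-scale) fragments over short (sub-nucleosomal)
ones indicates tight wrapping.

`wrapseq` formalizes this with two per-bin metrics. Fragments retained in
the 50--250 bp window are split at a break point $X$ (default 140 bp) into
$a$ = fragments of length $\ge X$ and $b$ = fragments of length $< X$, and
the **nucleosome wrapping score** is

$$\mathrm{NRS}(X) = \frac{a - b}{a + b} \in [-1, 1].$$

NRS is an absolute metric, and it moves wholesale when digestion conditions
change: digest longer and every bin loses long fragments, so genome-wide
NRS drifts downward without any change in the underlying biology. The
**nucleosome wrapping index** removes this: for bin $i$,

$$Z(i) = \frac{X(i) - \mu}{\sigma},$$

the z-score of bin $i$'s NRS against the mean $\mu$ and standard deviation
$\sigma$ of NRS over all non-missing bins, all chromosomes pooled. NRI is a
relative metric — the genome-wide ordering of wrapping — and is robust both
to the arbitrary choice of break point and to digestion extent. Both
properties are exercised directly in the test suite on simulated data
(break points 100--160 give pairwise NRI correlations above 0.9; a
digestion shift that moves mean NRS by more than 0.2 leaves NRI tracks
correlated above 0.95).

**Nucleosome wrapping domains (NRDs)** are maximal runs of constant NRI
sign: TiNRD (tight, positive) and LoNRD (loose, negative). Replication
timing uses the same machinery with labels early/late on the
$\log_2((S_1 + S_2)/(S_3 + S_4))$ track computed from four FACS-sorted
S-phase fraction libraries after scaling each to 1 million fragments.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| retention window | [50, 250] closed | bp | sub-nucleosomal up to di-nucleosomal boundary; both endpoints kept, reading "within 50--250 bp" inclusively |
| length groups | 50--80, 80--90, ..., 150--160, 160--250 | bp | half-open `[lo, hi)`; boundaries include every usual break point |
| break point $X$ | 140 | bp | the conventional long/short split for wrapping analysis |
| bin size | 100 kb (RT: 50 kb) | bp | domain-scale signal; any bin size works, partial terminal bins are kept |
| `minTotal` (NRS) | 1 | fragments | only empty bins are missing; no coverage floor is imposed |
| loess span | 10 | bins | window width in bins, applied per chromosome |
| `minSizeBp` (domains) | 3 bins | bp | minimum domain span before absorption (300 kb at 100 kb bins); at mouse-like genome size this yields domain counts on the order of about 1,400 |
| cut-site flank | 20 | bp | window for base-frequency diagnostics; a parameter, not a claim |

## Numerical and convention choices

These were genuinely open choices; each is fixed here as the package's
contract so results are bit-reproducible.

* **Half-open length groups.** The conventional group lists ("50--140,
  140--250") share boundary values; `[lo, hi)` makes them a partition, and a
  140 bp fragment counts toward $a$, matching "$a$ = fragments $\ge X$".
* **Counting mode.** A fragment overlapping two bins increments both
  (any-overlap), the behaviour of bedtools-style annotation; at 100 kb bins
  the border effect is a fraction of a percent of fragments. Midpoint
  assignment is available via `mode = "midpoint"`.
* **Population SD in the z-score** (divisor $n$). The difference from the
  sample SD is negligible at genome scale but one convention must be fixed.
  $\mu$ and $\sigma$ are computed after excluding missing (zero-coverage)
  bins, genome-wide rather than per chromosome.
* **Smoothing** never crosses a chromosome end; "by 10 bins" is a window
  *width* (10 nearest non-missing neighbours, tricube-weighted degree-1
  local regression via `stats::loess`), not a fraction-of-genome span.
  Chromosomes with fewer non-missing bins than the span pass through
  unsmoothed with a warning.
* **Domain segmentation.** Zero-valued bins take the sign of the nearest
  non-zero neighbour, ties broken toward the left. Runs shorter than
  `minSizeBp` are absorbed shortest-first (ties leftmost). Because run
  signs alternate, absorbing an interior short run necessarily merges both
  flanks — the "absorb into the stronger flank" choice only arises at
  segment edges, where there is exactly one flank, so the rule is fully
  deterministic. The segmentation is verified against an independent
  brute-force absorber exhaustively over every sign string up to length 12.
* **Missing-gap handling.** A single missing bin inside a domain is bridged
  (it joins its left neighbour's domain); two or more consecutive missing
  bins split the genome into separate segments, and those junctions are
  never reported as borders. Consequently Ti bp + Lo bp equals covered bp.
* **Quantile normalization** maps the value of rank $r$ among $n$ to the
  target's empirical quantile at probability $(r - 0.5)/n$ with linear
  interpolation (the plotting-position convention of `quantile type = 5`);
  ties receive the mean of their mapped values. The target distribution is
  an explicit input — no default reference profile is assumed.
* **No pseudocount in the RT log-ratio**: bins with a zero numerator or
  denominator are missing rather than clamped.
* **Midpoint membership** (half-open) assigns fragments to peak regions and
  domains: a fragment whose 0-based midpoint equals a region's end
  coordinate falls outside it.
* **N bases** are excluded from both numerator and denominator of every
  composition statistic; all-N intervals are missing.

## What the simulator emulates — and what it does not

`simulationSpec()` plants alternating domains with latent tightness
$\theta \in [0,1]$ per domain. Per bin, the fragment count is
Poisson(depth) and each fragment's length is drawn from a two-component
truncated-normal mixture: with probability $\theta$ the "long" component
(mean 167 bp, sd 15 — the nucleosomal scale), else the "short" component
(mean 110 bp, sd 25 — sub-nucleosomal), both truncated to [50, 250].
`digestionShift` subtracts a constant from $\theta$ genome-wide, emulating
longer digestion; the nascent/chase conditions offset $\theta$ by
$-\Delta$ / $+\Delta'$ (defaults 0.15 / 0.10), emulating looser
just-deposited nucleosomes that tighten during maturation. The defaults —
$\theta$ 0.8/0.2, depth 200 fragments per bin, 20-bin domains — give a
clean two-level genome whose NRS separation is large relative to counting
noise ($\mathrm{SE} \approx \sqrt{(1 - \mathrm{NRS}^2)/n} \approx 0.07$ at
depth 200), which is what the recovery guarantees in the tests refer to.
Every sampler derives a sub-seed per (chromosome, bin, condition), so
partial regeneration is stable.

The simulator does **not** emulate: MNase sequence preference (its random
genomes are i.i.d. uniform, so cut-site diagnostics on them test only the
*machinery*, not bias detection); nucleosome positioning or phasing;
copy-number or mappability variation; ChIP enrichment efficiency; or
continuous gradients of wrapping. Passing tests therefore demonstrate that
the estimators recover a planted block-structured signal at realistic
depth — not that real chromatin follows a two-component mixture.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on simulated
data: robustness and recovery properties use a 1,000-bin genome (1 Mb at
1 kb bins) at depth 200 (about 200,000 fragments); border recovery uses 20
replicates of a 200-bin genome with 10 planted domains; segmentation
equivalence is exhaustive over all $2^n$ sign strings for $n \le 12$;
sequence statistics are cross-checked against character-level scans on
1,000 fragments and binomial bounds at 10,000 cut sites. These sizes were
chosen so the full suite exercises every claim at meaningful signal-to-noise
on a desktop machine.

## Known limitations

* NRS/NRI are sequence-bias *diagnosed* but not *corrected*: A/T-rich DNA
  is cut preferentially by MNase, and the package reports composition
  correlations rather than adjusting scores.
* NRI is relative by construction: it cannot say whether the whole genome
  wraps tighter in one sample than another — that comparison needs NRS
  under matched digestion, which is why the parental-vs-nascent comparison
  (`nrsDifference()`) works on NRS within one digestion.
* The domain caller is a deterministic sign-run segmenter; it reports no
  uncertainty, and statistical significance of domain concordance
  (e.g. against Hi-C compartments) is out of scope.
* Hi-C PC1 and other external tracks are consumed as bedGraph/BED on a
  matching bin grid; the package does not compute compartment eigenvectors.
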