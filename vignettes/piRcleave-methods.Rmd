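---
title: "Scoring cleavage-site preference at piRNA 5' ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cleavage-site preference at piRNA 5' ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(piRcleave))
```

## The problem

PIWI-interacting RNAs (piRNAs) made through Zucchini/PLD6-dependent phased
biogenesis arise from successive endonucleolytic cuts of a long precursor:
each cut simultaneously creates the 3' end of one pre-piRNA and the 5' end
of the next, so fragments are laid down tail-to-head. The hallmark of this
pathway is a uridine at piRNA position 1 (the 1U bias). On top of the 1U
bias, mammalian piRNA 5' ends are enriched for the three stop-codon
trinucleotides UAA, UAG and UGA relative to the thirteen other
U-starting (Unn) trinucleotides. piRcleave implements the statistics
needed to detect, quantify and stress-test this kind of 5' end sequence
preference, together with a generator of synthetic phased reads whose
cleavage preferences are known exactly, so every statistic can be checked
for parameter recovery without any external data.

## The 5' end definition score

Raw 5' end counts confound two things: how often a position is cleaved,
and how abundant piRNAs are in its neighbourhood. The 5' end definition
score removes the abundance term by scoring each position against its own
local window. For a transcript position $x$, with $f(x)$ the number of
read 5' ends mapping exactly at $x$,

$$ s(x) \;=\; \frac{f(x)}{\sum_{i=x-10}^{x+20} f(i)} $$

where the window runs 10 nt toward the transcript 5' end and 20 nt toward
the 3' end, inclusive of $x$ itself (31 positions). $s(x)$ is the
fraction of local cleavage events that chose exactly $x$: 0 for a
position never used, 1 for a position that wins every local competition.
Two reading conventions are fixed here deliberately:

* the denominator includes $x$ (the summation bounds are inclusive), and
* the coverage gate (`minLocalReads`, default 100 reads) applies to the
  window total, not to $f(x)$, so confidently-zero positions are retained
  as informative observations.

Windows are truncated at region edges and those positions flagged; with
`end = "downstream_of_three_prime"` the same machinery scores the
position immediately past each read's 3' end, the expected next 5' end
under phased processing.

Covered positions are partitioned into bins: bin 0 holds positions with
score exactly 0, and the positive-score positions are sorted and split
into `nBins` (default 20) contiguous groups whose sizes differ by at most
one, ordered from least to most preferred. Score ties at bin boundaries
are broken by (contig, position) after the score, a stable rule chosen so
binning is a pure function of the input set: equal bin sizes take
precedence over keeping tied scores together, and permuting the input
order cannot change any assignment.

## The stop-codon ratio and its tests

For a library, the 64-cell table of trinucleotides starting at read 5'
ends is summarised by the stop-codon ratio: the mean frequency of UAA,
UAG and UGA divided by the mean frequency of the 13 other Unn
trinucleotides. The ratio is invariant to count rescaling and to changes
confined to non-U cells, so it does not depend on whether frequencies are
taken over all 64 cells or renormalised within Unn. Replicate ratios are
tested against 1 with a two-sided one-sample t test on the natural scale
(the default; a log-scale option is provided because ratios are
right-skewed, but the natural scale is the primary interface so that
reported means stay on the familiar fold-change scale).

Cross-species work adds three layers:

* **robustness classes** per library: *robust* when every stop codon is
  strictly more frequent than every non-stop trinucleotide (ties demote:
  a tie with a non-stop cell defeats the claim of strict preference), and
  *near-robust* when all three stop codons sit in the top five cells,
  with ties taking the worst rank of their tie group;
* **composition normalization**: the observed 5' end distribution divided
  by the sliding-window 3-mer distribution of the expressed cluster
  sequences, which removes the inflation an AT-rich cluster produces even
  under unbiased cleavage;
* **group statistics** with each (species, tissue) pair entering as one
  equal-weight point, so heavily sequenced species do not dominate, and a
  two-sided Fisher exact test comparing robust-library counts between
  taxonomic groups.

Under a null in which any of the 16 Unn trinucleotides is equally likely
to occupy any abundance rank, the probability that the three stop codons
top the ranking is $1/\binom{16}{3} = 1/560 \approx 0.18\%$; the package
exposes this closed form (`nullRobustFraction`) and the tests cross-check
it by permutation enumeration.

## ORF analysis

Stop codons are located on the sense strand in any frame, overlaps
allowed. A stop closes an upstream ORF when an in-frame ATG occurs before
any in-frame stop; ORF length counts codons from the ATG up to but
excluding the stop (so `ATG AAA CCC TAA` is a 3-aa ORF — the bounds
3–100 aa are inclusive). Score comparisons between ORF classes use the
two-sided Wilcoxon rank-sum test; the three size strata (3–8, 9–19,
20–100 aa) double as the matching rule for the empirical test, in which
each of 10,000 resamples draws one size-matched control per confirmed
site and the p-value is the fraction of resampled control means at or
below the observed mean. That directionality (a one-sided test of whether
the observed mean is *low*) is fixed here because it is the reading under
which an observed mean below the control average can still yield a
non-significant p.

## Conservation joins

Per-base conservation values (e.g. phyloP) are inner-joined to binned
positions by coordinate. Per-bin summaries are the mean with a t-based
95% confidence interval; acceleration calls use a strict threshold of
−1.30103 (phyloP's −log10 0.05 convention, so "below threshold" means
significant acceleration / positive selection); each bin's accelerated
fraction is compared against the pooled remaining bins (the bin itself
excluded, so the comparison is not diluted by its own signal) with a
two-sided two-proportion Z test. Because A/U positions are more conserved
than C/G positions genome-wide, subsetting to U positions, or to U in
stop-codon context, is supported before any summary.

## What the generator emulates — and what it does not

`generateCluster` draws sequence from a first-order chain: independent
base probabilities (default A/C/G/T = 0.30/0.20/0.20/0.30, the AT-rich
regime typical of piRNA clusters) except that the C→G transition is
multiplied by a depletion factor (default 0.25) and renormalised,
emulating genomic CpG depletion. The implied stationary CpG frequency has
a closed form (`expectedCpGFrequency`) used as the oracle in tests.

`simulatePhasedReads` runs cleavage chains: every candidate cut 20–50 nt
downstream of the current 5' end is weighted by

* the trinucleotide starting at the candidate (the next 5' end) — the
  default weights are 1 for Unn, 4 for UAA/UAG/UGA/UAC, and 0.05 for
  non-U trinucleotides, reproducing a strong-but-leaky 1U bias with a
  4-fold preference for the four empirically preferred sequences;
* a −1G penalty (default 0.25) when the base immediately upstream of the
  cut is G; and
* an upstream-GC bonus, `upstreamGC^gcFraction` over the window 10–20 nt
  upstream of the cut (default base 1.5). The exact offsets of this
  window are a free simulator choice recorded with the simulation truth.

The 20 nt lower bound prevents degenerate fragments; the 50 nt upper
bound matches the longest pre-piRNAs. Initiation sites are drawn from the
same positional weight distribution, since an initiating 5' end is itself
an upstream cleavage product. Trimming mode shortens each fragment from
its 3' end to 26–27 nt — the 5' end is never touched, as 3'→5' trimming
leaves it intact — which severs the tail-to-head adjacency exactly as
trimming does in vivo; untrimmed mode leaves raw 20–50 nt fragments whose
downstream flank is the next fragment's 5' end.

The generator does **not** emulate ping-pong amplification (and therefore
no 10A signature — `excludeTenA` is exercised on constructed fixtures),
RNA secondary structure, sequencing error, non-templated tailing, or
multimapping ambiguity. Passing tests on simulated data therefore
demonstrate correctness of the statistics under phased biogenesis with a
known preference, not robustness to those real-data complications.

### A competition effect worth knowing about

Even with *uniform* Unn weights the raw stop-codon ratio of simulated
reads settles slightly above 1 (about 1.09 at large sample sizes). This
is not a defect: a trinucleotide containing a second or third U (UUA,
UAU, UUU, ...) carries guaranteed competitor cut sites within the local
window wherever it occurs, so multi-U sequences systematically lose the
local competition and single-U sequences — the three stop codons among
them — win by default. The same neighbouring-U competition is visible in
real data as multi-U sequences peaking in lower score bins. The unbiased
zero point for "no stop-specific preference" is therefore the comparison
of stops against the six other single-U Unn trinucleotides (UAC, UCA,
UCC, UCG, UGC, UGG), which calibrates to 1 in the simulator; the
acceptance checks assert both this calibration and that the
conventional ratio's replicate confidence interval covers 1 at the
small-library sizes where replicate variance dominates.

## Numerical and design choices

* Coordinates are BED 0-based half-open on disk and GRanges 1-based
  closed in memory; the 5'-most base of a minus-strand read is its `end`.
* The internal alphabet is DNA; every user-facing table renders T as U
  through one conversion point (`renderRNA`), so stop codons print as
  UAA/UAG/UGA.
* Reads whose interrogated window contains N or leaves the sequence are
  excluded from that statistic only, never globally.
* Duplicate capping keys on the full coordinate tuple (contig, start,
  end, strand) and caps the summed multiplicity; since capped copies are
  interchangeable, aggregation-then-cap is deterministic and needs no
  random tie-break.
* The motif-enrichment background defaults to all covered positions and
  is exposed as a parameter, since different backgrounds answer different
  questions (composition of preferred sites vs preference relative to
  scored sequence space).
* All stochastic functions take a `seed` and restore the caller's RNG
  state; pipeline stages derive per-stage seeds from one global seed so
  stages rerun identically alone or together.

## Problem sizes

The bundled checks run on deliberately modest simulations chosen to give
each statistic enough events to be decisive: a 10 kb cluster with 250
initiation chains (roughly 37,000 fragments) for parameter recovery and
the trimming contrast; ten replicate 8 kb clusters with 60 chains each
for the null calibration; and fixtures of a few hundred positions for the
exact window-sum oracle, which is quadratic and kept small on purpose.
At these sizes nearly every cluster position passes the 100-read coverage
gate, mirroring the deeply sequenced libraries the score is designed for.

## Limitations

The score treats positions within a window as competing for a fixed
local budget of cleavage events; it cannot separate a preference acting
at cleavage from one acting at loading or stabilisation (in real data
that separation needs the trimming-deficient contrast). ORF
classification considers only ATG starts and the three canonical stops
on the sense strand. The conservation module consumes whatever per-base
track it is given and knows nothing about alignment quality. The
cross-species layer takes taxonomic class labels as supplied and does not
resolve taxonomy itself.
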