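---
title: "Denoising amplicon reads into sub-OTUs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising amplicon reads into sub-OTUs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subotu)
```

## The problem

Illumina 16S rRNA amplicon sequencing misreads roughly 1 nucleotide in
1,000. In a study of millions of reads, most true sequences are therefore
shadowed by a cloud of error-derived neighbours one or two substitutions
away, which inflates diversity estimates and defeats analyses that care
about single-nucleotide differences between closely related taxa.
Similarity-threshold OTU clustering hides the errors but also destroys the
resolution, and de novo cluster centroids differ between sequencing runs,
so OTU tables from different runs cannot be merged.

`subotu` takes the opposite approach: it infers the *exact* sequences
(sub-OTUs, sOTUs) that were presented to the sequencer, one sample at a
time, by subtracting the reads each candidate sequence is predicted to
have spawned as errors. Because the output features are literal sequences
and no cross-sample state exists, tables from different runs — even
different instruments and years — merge by plain string identity.

## The greedy subtraction model

After trimming to a fixed length $L$ and dereplication (singletons
removed), a sample is a list of unique sequences $s_i$ with observed
counts $c_i$. Two ingredients drive the denoiser:

* an **upper-bound error profile** $E[h]$, $h = 0, 1, \dots, H$: the
  maximal expected number of reads a true sequence emits at Hamming
  distance $h$, expressed as a fraction of the number of reads it
  presented to the sequencer. $E[0] = 1$ by convention and $E[h]$ is
  non-increasing for $h \ge 1$; distances beyond $H$ reuse $E[H]$.
* the **mod factor** $M = (1 - \epsilon)^L$, the probability that a read
  of length $L$ with mean per-nucleotide error rate $\epsilon$ is
  error-free. Dividing an observed count by $M$ estimates the sequenced
  abundance that the profile's bounds apply to.

Sequences are visited once, in fixed order of descending observed count
(ties broken lexicographically). When sequence $i$ with current residual
$r_i > 0$ acts as a source, every other sequence $j$ at aligned
substitution distance $h_{ij}$ and with $g_{ij}$ indel columns receives
the subtraction

$$ r_j \leftarrow r_j \; - \; \frac{r_i \, E[\min(h_{ij}, H)]}{M}
   \times \begin{cases} 1 & g_{ij} = 0 \\ p_{\text{indel}} & 1 \le g_{ij}
   \le g_{\max} \\ \text{(skipped)} & g_{ij} > g_{\max} \end{cases} $$

A sequence whose residual drops to zero or below is removed immediately
and never acts as a source. At the end, residuals are rounded half-up;
sequences rounding to zero are dropped. Only subtraction ever happens, so
no output count can exceed its observed count and no new sequence can be
invented — the two safety properties the test suite checks on every run.

Three modelling choices deserve comment:

* **Sources project from their residual, not their observed count.** A
  sequence partially explained as someone else's error should project
  proportionally fewer errors of its own.
* **The visiting order is frozen up front** from the observed counts
  rather than re-sorted as residuals shrink. This makes the pass a single
  deterministic sweep; re-sorting would let early subtractions reorder
  later ones and would make results depend on floating-point tie detail.
* **"Drops to 0" is read as $\le 0$**: a residual exactly zero is as
  explained-away as a negative one.

A consequence of removal-feedback worth knowing: the output is *not*
globally monotone in the profile. Raising some $E[h]$ can remove a
mid-abundance sequence earlier, which then stops projecting errors, so a
third sequence can end up with a *higher* count. The per-pair
subtraction is monotone (and tested as such on cascade-free instances);
the global cascade is not, by construction.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `trim_length` | 150 nt | prefix kept from every read; shorter reads are discarded |
| `mean_error` | 0.005 | mean per-nucleotide read error rate (0.5%), used only through $M$ |
| `indel_prob` | 0.01 | maximal probability of an indel-bearing error read; applied **once** per neighbour with $g \ge 1$, not per indel column |
| `indel_max` | 3 | neighbours with more indel columns are not subtracted from |
| `error_profile` | see below | $E[1..12]$ = 0.06, 0.02, 0.02, 0.01, 0.005, 0.005, 0.005, 0.001, 0.001, 0.001, 0.0005, 0.0005 |
| `min_reads` | 10 | features with fewer total counts are dropped from the final table |
| `abundance_skew` | 2.0 | chimera parents must be at least twice as abundant as the query |

The shipped profile is a configuration default for Illumina-style data;
platform-specific profiles load from a plain text file
(`load_error_profile()`), and all acceptance-style computations in the
package pass the profile explicitly. The indel treatment (single
multiplication by `indel_prob`, hard cap at `indel_max`) is the simplest
contract consistent with "a maximal probability for indels"; per-column
exponentiation was deliberately not used, and both knobs are exposed.

## Alignment for indel detection

Indels are rare in Illumina amplicons but must be recognised, or a
frame-shifted error read looks like a distant substitution neighbour.
Each sample is aligned with a center-star strategy: every sequence is
globally aligned (Needleman–Wunsch, match $+1$, mismatch $-1.5$, gap
$-3$, deterministic traceback preferring diagonal, then up, then left) to
the most abundant sequence, and the pairwise alignments are merged under
"once a gap, always a gap" with inserted residues left-justified.

One rule was added after measurement rather than taken for granted: a
gapped alignment to the center is **accepted only if its residual
substitutions plus indel columns are at most half the ungapped Hamming
distance** of the pair. Unrelated same-length 150-mers are ~75%
divergent, and an optimal aligner will happily buy back a few mismatches
with opportunistic gaps; merging such alignments makes the star
inconsistent, and true one-substitution neighbours then appear to differ
by indels and escape subtraction (pipeline precision drops from 1.0 to
roughly 0.35 on simulated communities). A genuine frame shift passes the
half-distance test by an order of magnitude; opportunistic gaps never
pass it. Terminal gaps count like internal ones (reads are fixed-length
prefixes, so terminal gaps are real length variation), and a run of $g$
one-sided gap columns counts as $g$ indel positions.

The aligner and its scores are plumbing, not the contribution; an
externally computed alignment can be imported with
`read_aligned_fasta()` for parity experiments.

## Chimera removal

PCR chimeras survive denoising because they are real molecules. The de
novo check uses an explicit two-parent, single-crossover model: a query
is flagged when a prefix of one sufficiently more abundant sequence
(count $\ge$ `abundance_skew` × query) concatenated with a suffix of
another reconstructs the query within `max_model_diffs` (default 0 —
exact), while each parent alone differs from the query by at least
`min_parent_diffs` (default 3) inside the segment the *other* parent
contributes. Queries are processed from least to most abundant, first
qualifying combination wins (parents in descending abundance, leftmost
crossover), and flagged sequences leave the parent pool so chimeras
cannot parent other chimeras. This is a fully specified, exhaustively
testable stand-in for heuristic h-score voting; it makes no attempt to
reproduce any particular external tool's scores.

## Feature tables

The feature identifier *is* the sequence. That single decision makes
merging across runs associative, order-independent and trivial: identical
sequences collapse; nothing else ever does. `merge_tables()` optionally
truncates all features to the shortest feature length first (for runs
trimmed differently), summing counts of prefixes that become identical.
The `min_reads` filter is strictly "fewer than". Rarefaction draws
without replacement (multivariate hypergeometric), drops samples below
the target depth rather than padding them, and is seeded. BIOM 1.0 JSON
output carries a fixed date stamp so identical runs produce
byte-identical files.

## What the simulator emulates — and what it does not

`make_truth_community()` draws $k$ unique sequences whose pairwise
Hamming distances all stay at or above a chosen radius. To make the
radius mean something, every second sequence is *derived* from an earlier
one at exactly that distance; purely random 150-mers sit ~112 apart, so
without derivation a "radius 1" community would contain no close pairs
at all and resolution limits could never be probed. Abundances are
uniform or lognormal (meanlog 0, sdlog 1 — a typical skew for stool-like
communities, leaving the rarest of 20 members a few hundred reads in
10,000).

`simulate_reads()` applies position-independent substitutions (default
0.001 per nucleotide — the error rate the method is designed around) and
rare indels (5e-05 each per nucleotide), drawing each read's source from
the community's abundances. It does not emulate quality-score
trajectories, motif- or position-dependent error hotspots, PCR chimeras,
or abundance biases. Passing tests on these simulations therefore
demonstrates the algorithm's arithmetic and its behaviour under the
stated error model — not robustness to every artifact of real
instruments. The artifact screen (k-mer containment, $k = 16$, fraction
0.5, both strands) is likewise a deterministic self-contained substitute
for aligner-based filtering, with no claim of parity.

## Numerical and degenerate-input choices

* Counts are rounded half away from zero; `round_half_up(0.5) = 1`.
* Alignment scores are halves, exactly representable in doubles, so
  traceback equality tests are exact.
* Dereplication, processing order, UPGMA tie-breaks and merged-tree child
  order are all resolved lexicographically — byte-identical outputs
  across platforms and batch compositions are a tested contract.
* Empty inputs flow through: an empty sample yields an all-zero table
  row; a sample failing mid-pipeline is skipped with a warning while the
  batch proceeds.
* UniFrac for two samples observing no branches at all is defined as 0.
* Reads shorter than the trim length are discarded, not padded; the
  discard count is reported. Sequences containing `N` are dropped just
  before alignment, since the Hamming error model is defined over
  unambiguous bases.

## Problem sizes used by the test suite

The suite exercises the greedy core against a brute-force oracle on 200
random 30-sequence instances, recovers 20-sequence communities (10,000
reads, 10 seeds) exactly, traces the observed/actual ratio over
similarity radii {1, 2, 4, 8, 16} × 10 seeds at 5,000 reads, and checks
run-integration metrics on two 4-sample runs of 8,000 reads rarefied to
5,000. These sizes were chosen so that every statistical check has
comfortable resolution while a full run stays in the minutes range on a
laptop core; all of them are parameters, not limits.

## Known limitations

* The error profile is an input, not an inference: no attempt is made to
  derive upper bounds from the data at hand.
* Center-star alignment is adequate for same-length amplicons with rare
  indels; it is not a general MSA and would mis-serve long-indel data.
* The chimera model considers single crossovers of two parents only.
* Quality scores are carried through but never consulted.
* Weighted UniFrac and ordination are out of scope; the package produces
  the distance matrices that downstream tools consume.
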