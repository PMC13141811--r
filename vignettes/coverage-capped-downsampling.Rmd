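---
title: "Coverage-capped downsampling with covcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-capped downsampling with covcap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput sequencing runs routinely produce wildly uneven depth:
PCR duplication, GC bias and abundance differences leave some loci at
thousands-fold coverage while others sit near the mean. Subsampling a fixed
*fraction* of reads (as `samtools view -s` does) rescales that landscape but
preserves its peaks and troughs. Capped-depth downsampling instead enforces
that **no reference position retains more than N reads**, flattening the
profile to a uniform ceiling — useful for benchmarking variant callers,
emulating lower-yield runs, or normalising inputs to depth-sensitive models.

covcap implements this cap with a sweep-line algorithm over coordinate-sorted
SAM/BAM input, with selection that is random (not greedy) yet exactly
reproducible from a seed.

## The algorithm

Every primary mapped record becomes a half-open reference interval
`[start, start + reference span)`, where the span sums the
reference-consuming CIGAR operations (M, D, N, =, X). As the file streams in
coordinate order, each participating record is assigned a 64-bit random
**priority** drawn sequentially from a seeded generator; lower is better.
The sweep maintains an **active set** — the retained reads overlapping the
current position:

1. *Evict*: reads whose interval ends at or before the incoming start no
   longer cover the frontier and leave the set (half-open convention: a read
   ending at `p` does not cover `p`).
2. *Keep*: if the live size is below the cap `N`, the incoming read is
   retained.
3. *Swap*: otherwise the incoming priority is compared with the worst
   (highest) priority in the set. A strictly better incoming read replaces
   the worst member **only if** their start positions are within
   `swap_distance` (default 5 bp, inclusive). The distance check stops a
   late arrival from reopening a coverage gap far behind the frontier.
4. Otherwise the read is discarded; the set is unchanged.

At any position whose covering reads all started within `swap_distance` of
one another, the survivors are exactly the `min(depth, N)` covering reads
with the lowest priorities — an unbiased random sample of the input reads at
that position. Ties in priority (about one in 2^53 comparisons) resolve to
the earlier record, so the whole procedure is a deterministic function of
(file order, seed, cap, swap distance). The active set is reset at each
reference boundary.

### Priorities

Priorities come from splitmix64, keyed so that the k-th draw is a pure
function of `(seed, k)`. R's doubles cannot hold all 64-bit integers
exactly, so each output is truncated to its high 53 bits and stored as an
exactly-representable double — comparisons remain exact and the stream is
identical across platforms. The generator's name is recorded in the output
`@PG` header line; one draw is consumed per participating record, in file
order, so the selection is independent of non-participating records.

### Record policy

Only primary mapped records (FLAG without 0x4/0x100/0x800) compete in the
sweep and count toward depth. Secondary alignments are dropped from output;
supplementary alignments are emitted iff their template was selected but do
not count toward depth (counting split alignments would double-count
templates). Duplicate-flagged records are treated as ordinary primaries —
pre-filter them if that is not wanted. Primary records whose CIGAR consumes
no reference cover no position; they are dropped with a warning.

## Processing modes

**Single-end / long reads.** One sweep over the file; the kept records are
then written in input order. Because a keep decision is revocable only
within `swap_distance` of the read's start, nothing is written that a later
swap could revoke; in this implementation the whole selection completes
before the output pass, which satisfies that contract trivially. The output
depth provably never exceeds `N`, and an input whose depth never exceeds
`N` passes through record-identical.

**Paired-end.** Template integrity requires two passes. Pass 1 sweeps the
primary records and builds the set of selected template names. A template's
fate is decided at its first-encountered mate, using that mate's priority;
the second mate never competes — if the template is selected it is
*force-inserted* into the active set (even when full), and if the template
was rejected it is silently discarded. A swap that evicts any member of a
template removes the whole template (including its other active mate) from
both the set and the selection — safe, because nothing is emitted until
Pass 2. Pass 2 re-reads the file and writes every non-secondary record whose
name is selected, recovering unmapped mates and mates that are physically
distant in the file. Forced insertions are why paired output can exceed the
cap slightly at mate loci; so can unmapped mates (which occupy a slot's
template without contributing coverage at the expected mate locus) and
insert-size variation, which makes it impossible to optimise the cap at both
mate loci simultaneously. The overshoot is reported, not hidden:
`cap_report()` gives the fraction of positions above the cap.

**Batched fetching.** An index-based alternative (`strategy = "fetch"`):
each reference is tiled into contiguous windows (default 10 kbp), reads are
fetched per window through the `.bai` index, shuffled with draws from the
same seeded stream (consumed in window order), and accepted greedily iff
adding them keeps every covered position at or below the cap against a
running depth that carries accepted spans into later windows. A read is
owned by the window containing its start, so it gets exactly one decision.
This strategy is strictly cap-respecting by construction for single-end
data, for any window size; paired inputs reuse the first-mate-decides
policy and the name-set retrieval pass. Single-end fetch retrieval matches
records by name, so it assumes unique single-end QNAMEs (the sweep strategy
tracks exact record ordinals instead and makes no such assumption).

## Verification instruments

`compute_depth()` recomputes per-position retained coverage from the
package's own interval model (deletion- and skip-spanned positions count;
insertions and clips cannot; secondary/supplementary records do not), and
`cap_report()` summarises compliance. The test suite cross-checks
`compute_depth()` against `samtools depth -a -J -G 0x904` — the flag
combination with the same conventions — and against a naive per-position
loop. The sweep itself is checked against a literal list-based replay of the
selection rules on hundreds of randomized instances, and retention
frequencies on an identical-reads fixture are checked for uniformity with a
chi-square goodness-of-fit test across 2000 seeds.

## The simulator

`simulate_reference()` and `simulate_alignments()` generate the test
conditions: a uniform-composition reference, and either single-end long
reads (lognormal lengths, default mean 5 kbp, log-sd 0.5, uniform starts,
fully-matched CIGARs) or proper 2×150 bp pairs (Normal insert, default
300 ± 50 bp) in which a configurable fraction of second mates is emitted
unmapped-at-the-mate's-position. Read counts are chosen so expected mean
depth equals the target; the default verification scenario is a 100 kbp
reference at ~300× long-read depth capped to 50×, a desk-scale version of
the multi-thousand-fold bacterial datasets this class of tool is aimed at.
The simulator emulates depth structure only: there is no error model, no
soft-clipping, no secondary/supplementary records and no duplicate marking,
so passing tests say nothing about how upstream aligner quirks interact
with the record policy — only about the capping contract itself. Identical
specs (including seed) reproduce byte-identical files.

## Parameters that matter

* `coverage_cap` (`-c`): the ceiling, in reads per position. ≥ 1.
* `seed` (`-s`): any integer below 2^53. Absent, one is drawn from the
  session RNG and logged; re-running with the logged seed reproduces the
  selection exactly.
* `swap_distance` (default 5 bp): larger values let better-priority reads
  displace earlier picks across a wider margin (closer to an ideal random
  sample) at the cost of deeper transient dips behind the frontier; 0
  disables swapping entirely (first-come reservoir behaviour).
* `window_size` (fetch only, default 10 kbp): a pure I/O-granularity
  knob — the cap guarantee holds for any value ≥ 1.

## Numerical and degenerate-input choices

Eviction uses `end <= position` and the swap check `new - old <=
swap_distance` (inclusive), both consequences of the half-open convention.
Header-only inputs produce a valid header-only output. Inputs must declare
`SO:coordinate` and be truly non-decreasing per reference; violations are
fatal, named by record. Depth summaries use known reference lengths as
denominators. Problem sizes in the tests (references of 5–100 kbp, depths
of tens to hundreds) were chosen as the smallest scales at which the
law-of-large-numbers checks (mean depth, unmapped-mate rate, uniformity)
are stable.

## Known limitations

* The sweep is sequential by contract; no multi-threading.
* CRAM is not supported (BAM/SAM only).
* Paired-end output is near-capped, not strictly capped (see above) — use
  `cap_report()` to quantify the overshoot for your data.
* Bit-compatibility with other implementations of the same scheme is not a
  goal; determinism is guaranteed only within this package, holding the
  generator (recorded in the `@PG` line) fixed.
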