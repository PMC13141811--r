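# covcap — coverage-capped downsampling of alignments

Sequencing depth is rarely uniform: PCR duplication, GC bias and abundance
variation leave coordinate-sorted BAMs with extreme peaks. Subsampling a
fixed fraction of reads preserves those peaks; **capped-depth** downsampling
instead guarantees that *no reference position retains more than N reads*.
covcap enforces such a cap with a single-pass **sweep-line algorithm**: each
primary mapped read becomes a half-open interval `[start, start+span)` and
is assigned a seeded random 64-bit **priority** (lower = better) in file
order. The sweep keeps an *active set* of retained reads overlapping the
current position — reads ending at or before the frontier are evicted, a
read is kept while the set holds fewer than `N`, and a full set admits a
better-priority newcomer only by swapping out the worst member when their
starts lie within `swap_distance` (default 5 bp), so no gap opens behind
the frontier. Where covering reads start close together the survivors are
exactly the `min(depth, N)` lowest-priority covering reads: an unbiased,
seed-reproducible random sample at every position.

Three execution paths share this core:

* **single-end / long-read**: one sweep, output streamed in input order;
* **paired-end**: two passes — the sweep selects template names, then the
  file is re-read and every record of a selected template is written, so
  mate pairs survive intact even when unmapped or distant;
* **batched fetch** (`--strategy fetch`): an index-based alternative that
  samples reads window-by-window (default 10 kbp) under the same seed.

The package is intended for anyone normalising high-depth data — variant
calling benchmarks, assembly subsampling experiments, training-set
construction — who needs the result to be both flat and reproducible.

## Worked example

```r
library(covcap)

ref <- simulate_reference(1e5, seed = 42)                  # 100 kbp reference
bam <- simulate_alignments(ref, "deep.bam",                # ~300x long reads
                           mode = "long_single_end",
                           target_depth = 300, read_length_mean = 5000,
                           seed = 42)
run <- downsample_alignments(bam, "capped.bam", coverage_cap = 50, seed = 2109)
#> covcap: cap 50, seed 2109, sweep/single: 6000 records in, 1020 written (6 swaps)

rep <- cap_report(compute_depth("capped.bam"), cap = 50)
c(max = rep$max_depth, mean = round(rep$mean_depth_covered, 2),
  above = rep$fraction_above_cap)
#>   max  mean above
#> 50.00 49.01  0.00
```

6000 input reads (~300× depth) are cut to 1020; the retained profile never
exceeds the 50× cap (`max = 50`, `above = 0`) and averages 49.01× over
covered positions — a flat line at the requested ceiling. Re-running with
the same seed reproduces the identical read selection; changing the seed
draws a different (equally flat) sample.

The same engine is available from a shell:

```sh
exec/covcap aln -s 2109 -c 50 deep.bam -o capped.bam
exec/covcap depth capped.bam -o capped.depth.tsv   # samtools-depth-shaped TSV
```

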