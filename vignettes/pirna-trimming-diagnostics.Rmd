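---
title: "Detecting piRNA 3' trimming defects from small RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting piRNA 3' trimming defects from small RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitrimseq)
```

## Background and model

piRNA biogenesis fixes the 5′ end of each piRNA first (with a strong
uridine preference at position 1, the "1U bias") and then shortens the 3′
end exonucleolytically to mature length. A trimming-deficient animal
therefore accumulates **pre-piRNA intermediates**: RNAs that share a mature
piRNA's 5′ end but carry extra genome-templated 3′ nucleotides. In
sequencing data this state is invisible to most summary statistics — the
reads still map to piRNA clusters, still start with U — and is diagnosed by
the *joint* behavior of read ends relative to a set of wild-type anchors:

* the **5′–5′ end-distance profile** of the mutant against wild-type
  reference piRNAs keeps a single peak at offset 0 (shared 5′ ends), while
* the **3′–3′ profile** moves its mass strictly downstream (extended, never
  shortened, 3′ ends).

Formally, let each reference piRNA r define anchor positions a₅(r), a₃(r)
on its cluster and strand. For every perfect-match placement of a query read
q on the same cluster and strand, with end positions e₅(q), e₃(q), the
signed offset d = σ(r)·(e(q) − a(r)) is recorded, where σ(r) = +1 on the
plus strand and −1 on the minus strand, so "downstream of the reference's
3′ end" is positive regardless of genomic strand. Offsets with |d| ≤ 30 are
accumulated count-weighted over **all** (reference, placement) pairs, and
frequencies are normalized over in-window events.

## Pipeline stages and parameters

| stage | parameter | default | why |
|---|---|---|---|
| adapter clip | `min_overlap` | 6 nt | shortest adapter prefix accepted at the 3′ end |
| length filter | `min_len`–`max_len` | 24–48 nt | mature piRNAs (24–32) plus room for intermediates |
| annotation | `max_mismatch` | 1 | tolerant mode for category assignment |
| annotation | order | clusters, coding, non-coding, repeats, intron | fixed priority; first hit wins, leftovers are `other` |
| length profile | miRNA proxy | 21–23 nt reads | depth normalization denominator; scale 10⁶ (reads per million proxy reads) |
| distance | `max_mismatch` | 0 | anchors must be positionally exact |
| distance | `top_n` | 10000 | abundance-ranked reference piRNAs |
| distance | `half_window` | 30 nt | profile spans −30…+30 |

Reads whose adapter is not found are **kept**: a 46–48 nt insert leaves too
little adapter on the read end to identify, and dropping such reads would
selectively deplete the longest intermediates — the very signal of interest.
The run report counts them separately.

"Top-N distinctively mapped" is interpreted as **uniquely mapped**: a
sequence with exactly one perfect-match placement across the cluster set
(both strands). This is the only reading that gives unambiguous position-0
anchors; a `unique_only = FALSE` mode keeps multi-mapping sequences with all
their placements as anchors for users who prefer the looser reading.

Two further conventions are deliberate choices rather than field facts, and
are exposed as configuration:

* **Multi-mapping queries** contribute every placement at full count
  (`multimapper = "fractional"` divides the count across placements).
* **Profile normalization** is over in-window events only, so the window
  sums to 1 and profiles of libraries with different depths are comparable.

## What the simulator emulates

`simulation_config()` describes matched immunoprecipitated piRNA libraries:

* **piRNA clusters**: 4 synthetic clusters of 20 kb (40% GC), each with 250
  planted loci, one per 80 nt slot, strand chosen uniformly. Slotting keeps
  neighboring anchors more than the 30 nt window apart on the same strand,
  so a library profiled against its own references concentrates all mass at
  offset 0 and any off-zero signal is real.
* **mature lengths** 24–31 nt peaked at 26–27 nt, the size range of
  MILI-bound piRNAs.
* **1U bias**: each locus 5′ base is forced to T with probability
  `u_bias = 0.9`, matching the strong uridine start of primary piRNAs.
* **abundance**: Zipf (exponent 1) over a single global rank list, the
  heavy-tailed shape of real piRNA libraries; this makes "top N by count"
  selection meaningful.
* **mutant mode**: every piRNA read is extended 3′ by +1…+18 nt drawn from
  a geometric(p = 0.5) truncated at +18, copying downstream genomic
  sequence — intermediates are genome-templated, which is what lets the
  distance analysis and the per-cluster pileup read them as extensions. No
  quantitative extension-length distribution is established for
  trimming-deficient animals (gels show a smear), so the distribution is a
  free parameter with the truncated geometric as default.
* **spike-ins and decoys**: 5% of reads are 21–23 nt miRNA spike-ins (the
  normalization proxy); 10% are drawn from coding/non-coding/repeat/intron
  decoy references that are rejection-sampled to share no 24-mer with the
  clusters (or each other), so category truth is unambiguous.
* **adapter read-through**: every read carries the full 3′ adapter
  (Illumina small-RNA adapter by default); quality strings are constant
  because no stage uses them.

What it does **not** emulate: sequencing errors, PCR duplicates, ping-pong
biogenesis signatures, partial trimming mixtures in the mutant, cluster
sequence homology (real clusters contain repeats; here multi-mapping is
rare by construction). Passing tests therefore demonstrate correctness of
the *computation* under clean conditions, not robustness to every artifact
of real libraries — on real data the profiles will show background mass
away from 0, and thresholds on profile masses (`flag_5p_peak`,
`flag_3p_positive`) exist precisely because the clean-data values (1.0 and
1.0) degrade.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; BED6 is the only
  coordinate-bearing output.
* The aligner is ungapped, substitution-only, `max_mismatch` ∈ {0, 1},
  implemented as an exact 12-mer seed index with the pigeonhole guarantee
  (two disjoint 12-mer seeds cover one mismatch for reads ≥ 24 nt);
  correctness is defined by equivalence to a brute-force Hamming scan,
  which ships in the package as `brute_force_align()` and is enforced in
  the tests.
* `report = "any"` returns the deterministic minimum placement under
  (reference, start, strand) ordering; ties in reference selection break by
  (count desc, sequence); alignment output is ordered by (reference, start,
  strand, read).
* Zero in-window distance events return an all-zero profile with `total =
  0` and a warning; normalization with no 21–23 nt reads, an empty
  reference list, or duplicate annotation priorities are explicit errors.
* N-containing reads survive I/O and are dropped (and counted) only at
  alignment, keeping stages orthogonal.

## Scale of the shipped checks

The test suite and the acceptance script run the full analysis on 50,000
reads over 1,000 loci (4 × 20 kb clusters) — large enough that the Zipf
tail, multinomial sampling noise, and the geometric extension distribution
are all exercised — plus a 50 kb aligner-oracle instance and smaller
constructed fixtures (2 × 4 kb clusters, 8,000 reads) for the per-module
contracts. The 1U recovery check estimates the per-locus 5′-U probability
from distinct piRNA-annotated sequences (each locus once): read-weighted
fractions are dominated by the few most abundant loci under a Zipf law, so
the distinct-sequence estimator is the one with a clean binomial reference
distribution.

## Known limitations

* The aligner indexes the full reference on every call; it is sized for
  cluster-scale references (10⁴–10⁶ nt), not genomes.
* `clip_adapter` with `max_mismatch_per_overlap > 0` falls back to a scalar
  scan and is noticeably slower than the exact-match path.
* The phenotype flag is a two-threshold rule on profile masses, not a
  calibrated test; on real data the thresholds should be set against a
  WT-vs-WT split-half null, which `compare_libraries()` makes easy to
  compute.
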