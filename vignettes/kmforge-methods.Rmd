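---
title: "kmforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kmforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kmforge builds, from a collection of short-read sequencing samples, either a
joint k-mer count matrix or one Bloom filter per sample. This vignette
explains the procedure, the parameters that matter, what the bundled
synthetic-community generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## The construction procedure

**Canonical k-mers.** Read strands are unknown, so every k-mer is
represented by its canonical form: the lexicographic minimum (A < C < G < T)
of the k-mer and its reverse complement. The 2-bit base encoding A=0, C=1,
G=2, T=3 makes numeric order on packed k-mers identical to lexicographic
order on the strings, so sorted binary count files and sorted text output
agree.

**Minimizer partitioning.** The minimizer of a k-mer is the smallest m-mer
(m < k) occurring in the k-mer or its reverse complement; computing it over
both strands makes it strand-symmetric, so every occurrence of a canonical
k-mer carries the same minimizer and lands in the same partition. Reads are
decomposed into super-k-mers — maximal stretches whose consecutive k-mers
share one minimizer — which are spilled to per-partition files without
repeating the overlap between adjacent k-mers. The map from the 4^m possible
minimizers to the P partitions is built once per run: per-minimizer k-mer
mass is estimated from the first `subsample` reads of each sample (default
10^4) and minimizers are packed greedily, largest estimated mass first, into
the currently lightest partition; minimizers absent from the subsample are
spread round-robin by their numeric rank so the map is total. Greedy
largest-first packing is a simple deterministic 4/3-approximation to the
balancing problem, which is all that per-partition load balancing needs.
Plain lexicographic minimizer order was chosen over a hashed order for
transparency and testability; its known skew toward A-rich m-mers is
absorbed by the mass-balanced map.

**Hash counting into partitioned filters.** A Bloom filter of `bits` bits
with a single hash function is split into P sub-filters with exclusive,
consecutive ranges: partition p owns indices `[p*s, p*s + s - 1]` with
`s = ceiling(bits/P)` rounded up to a multiple of 8 (byte alignment makes
concatenation of sub-filters a plain byte concatenation). Within partition
p, a canonical k-mer maps to `p*s + H(kmer, seed) mod s`, where H is a
64-bit avalanche hash (the MurmurHash3 finalizer) of the 2-bit packed k-mer
with an explicit seed. The seed and the partition-map digest travel in every
output file header so artifacts from different runs cannot be silently
mixed. In hash mode the k-mer sequence is discarded as soon as it is hashed:
only (hash, count) pairs are stored, which is exactly the information a
Bloom filter construction needs. Distinct k-mers may collide on one hash
index, in which case the index carries the sum of their counts; the run
report's per-sample `distinct_keys` therefore counts distinct hash values in
hash mode and distinct canonical k-mers in k-mer mode.

**Counting, merging, rescue, transposition.** Each sample x partition is
counted independently: keys are tallied, de-duplicated, sorted, and keys
with abundance below the sample's hard-min are dropped (such k-mers can
never be rescued later — this is the stage that defines what "reaches" the
collection-wide filter). Equivalent partitions across the C samples are then
combined by an n-way merge over the sorted streams, giving one count row per
key present anywhere. The rescue rule is applied per row and per sample i:

* abundance >= soft-min_i: the k-mer is *solid* in sample i and is kept;
* hard-min_i <= abundance < soft-min_i: kept iff the row is solid in at
  least share-min *other* samples;
* everything else becomes 0.

The rescuable band is half-open at the top because a count equal to soft-min
is already solid; a closed upper end would be redundant. "Other samples" is
strict (j != i): a k-mer does not support its own rescue. Rows are then
binarized into a dense s x C hash-major bit sub-matrix in which hash values
are implicit row positions (absent hashes are all-zero rows and no keys are
stored), the sub-matrix is bit-transposed to sample-major orientation, and
the per-sample rows of the P transposed sub-matrices are concatenated into
one partitioned Bloom filter per sample. When rescue is disabled in hash
mode no cross-sample information is needed, so the merge and transpose
stages are skipped and each partition bit-vector is emitted directly from
the sample's counted hashes; the two routes are bit-identical by
construction and tested as such.

**Query.** Because the hash function depends on the partition, a query
k-mer is canonicalized, its minimizer recomputed, the partition looked up in
the run's partition map, and a single bit probed. Inserted k-mers always
query true; never-inserted k-mers query true with probability roughly equal
to the occupancy of the probed sub-filter. Sequence-level queries report,
per sample, the fraction of the sequence's valid k-mers present (k-mers
spanning non-ACGT characters are excluded from both numerator and
denominator); thresholding that fraction is left to the caller, since a
sensible threshold depends on query length and expected divergence.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 20 | k-mer length (bases). Standard for short-read indexing; limited to 26 so packed k-mers stay exact in the 8-byte keys of the count-file format. |
| `m` | 10 | minimizer length (bases), `m < k`, `m <= 12` (the map stores all 4^m minimizers). Smaller m gives longer super-k-mers but coarser balancing units. |
| `P` | 16 | partition count. More partitions shrink per-partition memory and increase stage-level parallelism opportunities. |
| `bits` | 2^26 | requested total Bloom filter size in bits; per-partition size s is derived from it. Choose so that expected occupancy stays near or below ~0.3 for useful false positive rates (single-hash filter: FPR = occupancy). |
| `hard_min` | 1 (rescue) / 2 (no rescue) | abundance below which a k-mer is dropped at counting. With rescue on, 1 lets the whole abundance spectrum reach the collection-wide filter; without rescue, 2 is the classical "drop k-mers seen once". |
| `soft_min` | auto (0.1%) | per-sample solidity threshold. The automatic rule picks the smallest abundance t whose histogram bin holds fewer than 0.1% of the sample's distinct k-mers; "total number of k-mers" is read as *distinct* k-mers because the bin it is compared against counts distinct keys. |
| `share_min` | 1 | number of *other* samples in which a sub-soft k-mer must be solid to be rescued. 0 disables soft filtering entirely; values above C-1 make rescue impossible. |
| `seed` | 0 | hash seed; recorded in all headers. Changing it changes every hash index. |
| `threads` | 1 | accepted for interface compatibility. Partitions are processed sequentially in a fixed order, so outputs never depend on this value; any parallel scheduling that preserves per-partition determinism would produce the same bytes. |

## The synthetic-community generator

`simulate_collection()` draws fixed-length reads uniformly from circular
genomes (i.i.d. uniform ACGT, or user-supplied), flips each read to the
reverse strand with probability 1/2 to exercise canonicalization, and
applies i.i.d. substitutions at a per-base rate e (a substituted base always
changes, so the error count per read is exact). Ground truth — the genomes'
canonical k-mer sets, each sample's error-free k-mer abundances, and the set
of erroneous read k-mers (those absent from every genome) — is computed from
the pre-error reads, which a substitution-only model makes exact. The
default study condition used by the tests and the acceptance script is five
samples sharing one 10 kb genome at coverages (1, 1, 4, 4, 4) with e =
0.5%, read length 100 and k = 20: a desk-scale cartoon of a metagenome
collection in which the same low-abundance organism is better covered in
some samples than in others. Genome size and read counts are deliberately
small so that every test recomputes truth exhaustively.

What the generator does **not** emulate: indels and technology-specific
error profiles (substitution-only errors keep truth exact; the filtering
question only needs *erroneous* k-mers to exist), GC or coverage bias,
paired-end structure, and real inter-sample genome overlap structure.
Passing tests therefore demonstrate the correctness of counting, merging,
rescue and filter construction — not that any particular threshold setting
is well calibrated for a real metagenome.

## Numerical and format choices

* Hash indices and packed k-mers are carried in R as doubles holding exact
  integers below 2^53; all modular arithmetic happens in C++ on `uint64_t`.
  Reduction to the partition range is by modulo s; the bias is negligible
  for s far below 2^64.
* Bit order is LSB-first within each byte in every format, so sub-filter
  concatenation and matrix transposition are pure byte operations; s is
  always a multiple of 8 for the same reason.
* Counts are unsaturated 32-bit integers; k-mer keys in binary count files
  are 8-byte little-endian (hash index, or 2-bit packed k-mer).
* Ties: equal-mass minimizers are packed in numeric-rank order; the lightest
  partition with the lowest index wins; all iteration orders are fixed, so a
  run is a pure function of (inputs, config, seed).
* Degenerate inputs: reads are split at any non-ACGT character and fragments
  shorter than k are ignored; empty samples produce empty count sets, empty
  histograms resolve soft-min to 1 with a warning, and an empty balancing
  subsample falls back to a round-robin map with a warning.
* The automatic soft-min scan covers abundances 1 to max+1; abundances
  absent from the histogram's support count zero k-mers and therefore
  qualify, which also gives the boundary value max+1 when no supported
  abundance does.

## Known limitations

* The rescue rule helps when rescuable k-mers have enough *other* samples
  in which they are solid. In small collections where share-min is close to
  the number of well-covered samples, the rescue condition is nearly a
  conjunction over all of them and fails for a large fraction of true
  low-abundance k-mers — while soft-min simultaneously filters k-mers the
  plain hard-min baseline would keep. `rescue_benchmark()` makes this
  regime measurable: on the default five-sample study condition the rescue
  configuration (hard 1 / soft 3 / share 3) filters *more* true k-mers than
  the hard-min-2 baseline. The mechanism pays off as the number of samples
  grows relative to share-min; the package reports both ratios rather than
  assuming the favourable regime.
* Everything is desk-scale: partitions are assumed to fit in memory, and the
  external-memory layout (per-partition spill files, sorted binary count
  files, stage-wise resumability) reproduces the structure, not the
  scalability, of terabase-scale pipelines.
* k <= 26 and m <= 12; multiple hash functions per filter and invertible
  k-mer encodings are out of scope, as is file-format compatibility with
  other Bloom-filter toolchains (headers here are self-describing instead).
* Query correctness requires the run's partition map; filters refuse to
  load against a map with a different digest.
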