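---
title: "Match-point graphs and LPF-based reference compression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Match-point graphs and LPF-based reference compression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpf)
```

## The LCS model

For strings $S_1$ (length $n$) and $S_2$ (length $m$), the longest
common subsequence is the longest sequence of position pairs
$(u_1, v_1), \ldots, (u_M, v_M)$ with $S_1[u_h] = S_2[v_h]$ and both
coordinates strictly increasing. The classical dynamic program fills
an $(n+1) \times (m+1)$ table in $O(nm)$ time; `lcs_dp()` implements
it and serves as the independent oracle throughout the test suite.

`lcs()` takes a different route through *match points*: the individual
position pairs with equal symbols.

1. **Enumeration** (`enumerate_matches`). Occurrence lists are
   bucketed per symbol and crossed, which is exactly what a
   generalized suffix tree's depth-1 nodes would yield; a full tree
   buys nothing for length-1 matches, so none is built. Ids are
   assigned in (symbol, p1, p2) order so downstream structures are
   reproducible. Sentinels S = (0, 0) (id 1) and E = (n+1, m+1)
   (id $\eta$+2) bracket the $\eta$ real matches; both sentinel
   coordinates participate in the rank maps so every node is reachable
   from S.

2. **Max tables** (`build_prev`). Distinct p1 values are renamed to
   consecutive ranks (likewise p2), and two dense tables over rank
   space answer nearest-dominated-predecessor queries: `tbl1[i, j]` is
   the match with maximal p1 among ranks $\le (i, j)$, ties broken
   towards the rightmost p2; `tbl2` maximises p2 first. Seeding each
   cell, propagating down columns, then sweeping rows left-to-right
   with a single comparison per cell builds both tables in
   $\Theta(|p1| \cdot |p2|)$ work.

3. **Parent sets** (`get_dprnt`, `get_prnts`). The *direct parents* of
   a match at ranks $(i, j)$ are `tbl1[i-1, j-1]` and
   `tbl2[i-1, j-1]`. Three cases produce the full parent set: no
   direct parent means S is the only parent; equal direct parents are
   the unique parent; otherwise both are kept and the open rectangle
   strictly between their coordinates is probed. The probe walks the
   *floor ranks* of the open p1 gap $(i_1, i_2)$ — rows
   $r(i_1) \ldots r(i_2)-1$ — because a hypothetical match with any p1
   value in the gap sees, as its direct parents, the table entries at
   the floor rank of that value; the p2 gap is handled symmetrically.
   Probed candidates are kept only when strictly inside the rectangle,
   and the set is finally pruned to an antichain: whenever two members
   are in series (one dominates the other in both coordinates), the
   dominated one — the one farther from the child — is deleted. The
   pairwise filter is used directly rather than a shortcut through
   direct-parent lookups, since the antichain property is the actual
   contract and the sets involved are tiny.

4. **DAG and longest path** (`construct_dag`, `longest_path_lcs`).
   Each node receives edges from its parents; every edge strictly
   increases both coordinates, so sorting nodes by (p1, p2) is a valid
   topological order and the longest S-to-E path falls out of one
   relaxation sweep (the mirror image of the shortest-path view in
   which every edge has weight −1). LCS length is the path's edge
   count minus one. Ties between equal-length paths keep the first
   predecessor found in processing order: deterministic output, and
   any optimal path is acceptable — the validity check is that the
   returned string is a common subsequence of both inputs of the DP
   oracle's length.

Matches that are never selected as anyone's parent become sinks
without a path to E. This is harmless for the longest path — any such
match is dominated by a selected one — and the engine makes no claim
that *every* maximal chain survives as an S-to-E path.

The dense tables make this engine quadratic in rank space, so inputs
are capped at $5 \times 10^7$ table cells with a clear error. That is
deliberate: the engine is for desk-scale strings, and genome-scale
work belongs to the codec, which never builds these tables.

## The codec

Let $Z = R \circ T$. For every position $i$, $\mathrm{LPF}[i]$ is the
length of the longest factor starting at $i$ that also starts at some
$h < i$, and $\mathrm{POS}[i]$ is such an $h$. Self-overlap
($h + \mathrm{LPF}[i] - 1 \ge i$) is allowed, matching LZ convention —
a run compresses to one triple against its own first symbol. Where
several $h$ attain the maximum, the *leftmost* is reported. Any valid
$h$ decompresses correctly; fixing the leftmost makes output
deterministic and gives the brute-force oracle a well-defined answer.

`compress` scans the target region of the arrays left to right
starting at $i = |R|+1$: a factor shorter than the threshold $k$ costs
one literal byte; otherwise a triple
$(p_T, p_Z, \ell) = (i - |R|, \mathrm{POS}[i], \mathrm{LPF}[i])$ costs
12 bytes (three 4-byte words) and the scan jumps by $\ell$. Because
$\mathrm{LPF}[i+1] \ge \mathrm{LPF}[i] - 1$, declining a factor
forfeits at most one unit of factor length per literal emitted, which
is why a threshold well above 12 can pay off: short factors are
cheaper as literals, and the factors that remain are long enough to
amortize their triples. The default $k = 31$ is the fixed operating
point used for the published genome experiments; `sweep_k()` re-scans
one LPF pass at many thresholds to expose the interior-band minimum on
any input pair.

Decompression is a single left-to-right replay and needs no index
structures: literal positions (the complement of the triple extents)
are filled first, then each triple copies from the reference when the
source index is $\le |R|$ and from already-reconstructed target
otherwise, byte by byte when a factor overlaps its own output.
Malformed containers (overlapping or out-of-range extents, stream
length mismatches, truncation, bad magic) raise corrupt-archive
errors.

### Construction strategy and numerical choices

* The suffix array uses prefix doubling ($O(n \log^2 n)$) in C++;
  linear-time construction exists but is unnecessary at the scales
  this package targets, and the simpler algorithm is easy to verify.
* LPF/POS come from the suffix array plus Kasai's LCP array: visiting
  text positions in decreasing order while deleting them from a
  doubly-linked list threaded through rank order makes the list
  neighbours of rank$(i)$ the lexicographically nearest suffixes
  starting before $i$; an RMQ over LCP gives the factor length, and a
  range-minimum over SA inside the widened lcp-interval gives the
  leftmost occurrence. A vectorized quadratic scan (`lpf_bruteforce`)
  is the independent oracle.
* Positions in the container are 1-based, words little-endian; these
  are arbitrary but must be fixed for interoperability. 4-byte words
  cap $|Z|$ at $2^{32}-1$; longer inputs are rejected rather than
  silently widened.
* The case bitstring is packed LSB-first within each byte
  (`packBits()` order).

### Decomposition mode

`lpf_compress_decomposed` folds both sequences to upper case and runs
two codec passes: the folded target against the folded reference, and
the target's packed case bitstring against the reference's packed
case bitstring. Halving the alphabet exposes redundancy that
mixed-case text (soft-masked genomes) hides from exact factor
matching. Using the reference's bitstring as the dictionary for the
target's is this package's choice of dictionary for the second pass;
shared masking structure then compresses to a handful of triples.
Symbols without case (N digits, `-`) carry bit 0 and round-trip
unchanged, which is the governing contract — `recompose(decompose(x))`
is byte-identical for arbitrary input.

### Post-compression and the container

The spec of the two raw streams deliberately leaves them byte-aligned
and further compressible. The `builtin` post-compressor (DEFLATE via
`memCompress`) is applied per stream at serialization time and
recorded in the header flags, so decompression never has to guess;
`none` keeps the streams verbatim. When a stream is post-compressed,
an 8-byte stored-length word precedes it in the container, since
12 × count no longer gives its size. Multi-record FASTA targets are
compressed record-by-record against the concatenation of all
reference records (the per-chromosome versus whole-genome-reference
layout), headers stored verbatim.

## The simulator

`generate_reference` draws i.i.d. uniform symbols;
`mutate_sequence` applies per-position substitutions (always to a
different symbol), deletions, and post-position insertions, then
toggles the case of a configurable number of geometric-length blocks.
One integer seed makes every fixture bit-reproducible. The defaults —
1% substitutions, no indels, no case blocks — model a low-divergence
resequencing release, the regime in which reference-based compression
is the right tool.

What the simulator does *not* model: repeat families, segmental
duplications, transition/transversion bias, structural rearrangements,
or the heavy-tailed block structure of real assembly updates. Passing
tests on simulated pairs therefore demonstrate correctness (lossless
round trips, oracle agreement) and qualitative behaviour (threshold
response, scaling of stream sizes with divergence), not the absolute
byte counts achievable on real genomes.

## Problem sizes used by the test suite

The randomized suites run at sizes chosen so the whole suite completes
in about a minute: 200 string pairs up to length 40 for the
LCS-versus-DP equivalence, 200 strings up to length 300 for the
LPF-versus-brute-force equivalence, a few hundred codec round trips up
to ~1 kb across thresholds {1, 12, 31, 100}, both archive modes, both
post settings, and one 100 kb pair at 1% divergence for the threshold
sweep's shape assertion. These scales exercise every code path
(including self-overlapping factors, disjoint alphabets, and
single-symbol runs) while staying far from the engine's guard rails.

## Known limitations

* The LCS engine's dense tables make near-identical long strings its
  worst case (that regime is the codec's job, and the engine says so
  in its error message).
* One optimal LCS is returned, not all of them.
* The container stores positions in 4-byte words: inputs with
  $|R| + |T| \ge 2^{32}$ are rejected.
* FASTA I/O reads whole records into memory; streaming decompression
  is not attempted.
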