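---
title: "Mining gapped motifs with counting matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gapped motifs with counting matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmine)
```

## The model

A sequence database `D` is an ordered list of `N` sequences over an
alphabet of `A` single-character items (4 for DNA, 20 for protein; custom
alphabets are allowed and out-of-alphabet symbols can be kept as ordinary
items). Positions are 1-based everywhere. A gapped pattern
`p = p_1 * p_2 * ... * p_m` occurs in a sequence `s` when there are
positions `q_1 < q_2 < ... < q_m` with `s[q_i] = p_i` and every adjacent
pair strictly inside the gap window:

    q_i < q_{i+1} < q_i + G.

The *support* of `p` is the number of sequences with at least one
occurrence; a pattern is reported when its support is at least the minimum
support. The mining problem is to report **every** pattern of every length
meeting that threshold — no maximal/closed condensation, no rigid-gap
(`<L,W>`-style) constraints, no wildcard-segment pattern trees; those are
different problem statements.

### Assumptions worth stating

* The gap bound is **strict** (`q < p + G`), applied independently to each
  adjacent item pair. Consequences users should internalise: `G = 1` admits
  no extension at all, and `G = 2` means adjacency, so mining at `G = 2` is
  exactly frequent-contiguous-substring mining. The test suite pins both
  limits against independent oracles.
* One global `G` for the whole pattern; per-pair gap vectors are out of
  scope.
* A sequence contributes at most one support count however many occurrences
  it contains. Counting occurrences instead of sequences would inflate
  supports and change the reported set.
* Fractional minimum support `S` resolves to `ceiling(S * N)` — "at least
  a fraction S" — and qualification is `support >= threshold`. Floor would
  be the only other defensible reading; ceiling is chosen and used
  consistently.

## The miner

Two structures carry all state. The **position index** maps every (item,
sequence) pair to the sorted vector of occurrence positions; it is built in
one pass and never mutated. The per-candidate **counting matrix** `C_l`
holds, for each sequence, every position at which an occurrence of the
candidate can end.

Extension of a candidate `α` by item `e` computes, per sequence, the set

    { q in positions(e) : exists p in row(α) with p < q < p + G }

by two binary searches per occurrence position (`findInterval` against the
sorted parent row). Support is the number of non-empty rows. The miner
spells candidates depth-first in fixed alphabet order, reports a candidate
when its support meets the threshold, and recurses only then:
anti-monotonicity (an extension's row positions are always a subset of
later positions reachable from the parent's rows) guarantees a pruned
candidate can never be revived, and also guarantees termination — each
extension strictly increases the minimum end position of every non-empty
row, so depth is bounded by the longest sequence even with no length cap.

### Why every qualifying position is retained

Keeping only the earliest in-window successor of each parent position looks
like a harmless economy but is incomplete. On the single sequence `ACCGT`
with `G = 3`: from `A` at 1, the in-window `C` positions are 2 and 3.
Min-only retention keeps just 2; from 2, `T` at 5 is outside the window
`(2, 5)`, and `A*C*T` is lost. Full retention keeps 3, from which `T` at 5
is reachable. The deliberately crippled rule survives in the code base
(`extend_matrix(..., retain = "min-only")`) purely so the regression test
can keep demonstrating this failure mode:

```{r}
db <- seq_db("ACCGT", alphabet = "dna")
idx <- build_index(db)
mA <- initial_matrix(idx, "A")
extend_matrix(idx, mA, "C", G = 3)[[1]]
extend_matrix(idx, mA, "C", G = 3, retain = "min-only")[[1]]
```

The narrative of the original worked example speaks of taking "minimum
positions"; its printed matrices happen not to distinguish the two rules
(they coincide there), while the formal definition of the counting matrix
and the stated rationale — later occurrences may be the only ones able to
reach the next item — both require full retention. We follow the
definition.

A second typographical wrinkle in the same narrative: the window-bound
arithmetic it prints ("(6) is less than (9)") corresponds to no single
consistent formula (the bounds printed equal parent position + G + 2). We
verified that the printed counting matrices themselves are reproduced by
the strict window and implement exactly that.

## The baselines

`brute_force_mine()` enumerates candidate strings depth-first over the
alphabet and counts support with an independent containment test — a
left-to-right scan that carries *all* live end positions (the same
completeness argument as above, in oracle form). It descends below a
candidate only when its support is nonzero; that cutoff uses nothing but
the containment definition itself, so the oracle shares no machinery with
the counting-matrix miner. It refuses `A^max_len > 1e6`.

`genprefixspan_mine()` is a projected-database pattern-growth miner
reconstructed from its published narrative, faithful to this package's
comparison needs rather than to any other description of it. A projection
stores one (sequence, suffix start) pseudo-projection entry per occurrence
of the pattern's last item — strings are never copied. Candidate items for
extension are counted over **whole suffixes** (this is the step the
published example prints: after projecting the lowercase example on `a`,
the frequent items at λ = 3 are `{a, c, g}` — a fact that only whole-suffix
counting reproduces; windowed counting gives `{c, g}`). Each candidate's
support is then verified from the gap-valid occurrences reachable from the
entries before anything is emitted. Whole-suffix counting is a superset
filter of gap-valid counting, so the final (pattern, support) set is
provably identical to the depth-first miner's — the cross-miner identity
the test suite asserts on hundreds of random databases.

## The synthetic generator

`generate_db(A, L, N, seed)` draws `N` sequences of exact length `L`,
each residue i.i.d. uniform over the first `A` alphabet letters. This is
the stated world of the benchmark settings the package emulates (DNA grids
around `A = 4, L = 25..50, N = 1000..9000`, protein at
`A = 20, L = 100, N = 500`); the original benchmark data's generator is not
parameterised beyond `A`, `L`, `N`, so uniform i.i.d. is the documented
substitute realising exactly those parameters. Each sequence draws from a
substream derived from the master seed by an LCG mix, so enlarging `N`
appends sequences without reshuffling earlier ones.

What the generator does *not* emulate: planted motifs, compositional bias,
repeats, phylogenetic correlation. A green test on synthetic data therefore
establishes algorithmic correctness and scalability of the miner, not
biological sensitivity or specificity; under i.i.d. uniformity the motifs
found are exactly the statistically expected ones (e.g. every single letter
has expected support fraction `1 - ((A-1)/A)^L ≈ 0.9998` for `A = 4,
L = 30`, which the suite checks in closed form).

## Numerical and design choices

* **Tie-breaks and order.** Extensions are tried in fixed alphabet order;
  output is DFS preorder, each pattern exactly once; `sort = TRUE` re-sorts
  lexicographically with descending support as tie-break. Runs are
  deterministic byte for byte.
* **Degenerate inputs.** Empty sequences are legal, contribute no index
  positions and never support anything. `G = 1` yields only length-1
  motifs. A threshold above `N` warns and returns an empty set.
  `min_length` only suppresses reporting, never recursion.
* **Unknown symbols.** Default policy keeps them as ordinary items
  (completeness-preserving: they simply fail to reach support in
  practice); `error` and `drop-sequence` are available. Alignment gaps
  `-` are rejected outright — input sequences are unaligned by problem
  statement.
* **Thresholds in tests.** Exact fixtures are asserted exactly; stochastic
  checks use conservative bounds (5σ binomial bands) so seed changes do
  not flip them.
* **Timings.** The benchmark harness reports wall time but no test asserts
  any timing: relative speeds of the miners are hardware-bound claims and
  outside this package's acceptance surface.

## Known limitations

* The pattern-growth baseline follows one published narrative of that
  algorithm; other descriptions may differ in candidate counting. Its role
  here is comparability, and its output set is verified identical to the
  main miner's.
* `brute_force_mine()` is an oracle, not a tool: exponential in pattern
  length by design.
* Memory for `report_positions = TRUE` grows with motif count times `N`;
  leave it off for large grids.
* Gapped mining at very large `G` over low-complexity input can report
  exponentially many motifs — that is the problem statement, not a bug;
  use `max_length` or higher support to contain it.
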