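# gapmine

Gapped sequential pattern mining for biological sequences.

## The problem

Biologically meaningful motifs rarely sit at fixed distances: functionally
coupled residues are separated by stretches of sequence that evolution
inserts into and deletes from. A *gapped sequential pattern* models this: an
ordered list of residues `p_1 * p_2 * ... * p_m` occurs in a sequence when
matching positions `q_1 < q_2 < ... < q_m` exist with each consecutive pair
inside a user-set window, `q_{i+1} < q_i + G`. The *gap constraint* `G`
bounds how far apart adjacent matches may drift (`G = 2` forces contiguous
substrings; large `G` recovers plain subsequence mining). A pattern's
*support* is the number of database sequences containing it at least once —
a sequence contributes one count no matter how many occurrences it holds —
and a pattern whose support reaches the minimum support (an absolute count
λ, or a fraction `S` of `N` resolved as `ceiling(S * N)`) is reported as a
motif.

The package is for anyone mining frequent gapped motifs from unaligned DNA
(4-letter) or protein (20-letter) sequence collections: FASTA or plain
line-per-sequence input, tab-separated output.

## The algorithm

The miner spells candidates depth-first, one residue at a time, and never
builds projected databases. Two structures carry all state:

* a **position index** built in one pass: for every (item, sequence) pair
  the sorted list of 1-based occurrence positions;
* per candidate, a **counting matrix**: for each sequence, the set of
  positions at which an occurrence of the candidate can *end*. Extending a
  candidate by item `e` replaces each row with all positions `q` of `e`
  such that some parent end position `p` satisfies `p < q < p + G` —
  located by binary search in the index. All qualifying positions are kept:
  retaining only the earliest successor is provably incomplete (see the
  vignette). Support = number of non-empty rows.

Support never grows under extension (anti-monotonicity), so any candidate
below threshold is pruned together with its whole subtree; this bounds the
search and guarantees termination without a length cap.

Two reference miners act as independent oracles and baselines: exhaustive
enumeration with a gapped-containment test (`brute_force_mine()`), and a
projected-database pattern-growth miner (`genprefixspan_mine()`). All three
return identical (pattern, support) sets; they differ only in work done.

## Worked example

The canonical three-sequence database, mined at λ = 3, G = 3:

```r
library(gapmine)
db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
idx <- build_index(db)

initial_matrix(idx, "C")               # (4), (3,5), (4,6)
m <- extend_matrix(idx, initial_matrix(idx, "C"), "A", G = 3)
m                                      # (6), (4,7), (7)
support_of(m)                          # 3 -> "C*A" is a motif

res <- mine(db, mining_params(gap = 3, min_support = 3))
subset(res$motifs, pattern == "C*A")
#   pattern length support support_fraction
# 8     C*A      2       3                1
```

The counting matrix of `C` holds every occurrence position of `C` per
sequence. Extending by `A` keeps the `A` positions reachable within the gap
window: all three rows stay non-empty, so `C*A` has support 3 of 3 and is
reported. The candidate `A*T` ends with matrix `(2,7), (2), (-)` — support
2 — so it is rejected and nothing beneath it is explored.

The same database ships as a FASTA fixture:

```r
fa <- system.file("extdata", "worked_example.fasta", package = "gapmine")
mine(load_sequences(fa), mining_params(gap = 3, min_support = 3))
```

## Command line

```sh
Rscript inst/cli/gapmine mine --input seqs.fa --gap 3 --min-support 3 --out motifs.tsv
Rscript inst/cli/gapmine synth --A 4 --L 30 --N 3000 --seed 7 --out synth.fa
Rscript inst/cli/gapmine bench --grid grid.cfg --algorithms dfsg,genprefixspan --out bench.tsv
```

`mine` writes a TSV with columns `pattern`, `length`, `support`,
`support_fraction`; `--algorithm dfsg|genprefixspan|bruteforce` selects the
miner, `--report-positions` adds a per-sequence end-position table, and
exit codes follow the usual contract (0 ok, 1 data error, 2 usage error).
`synth` generates seeded uniform i.i.d. sequences (DNA for `--A 4`, protein
for `--A 20`). `bench` expands a `key=value` grid over `A, L, N, G, S`,
mines each cell with every requested algorithm and tabulates wall time,
pattern count and whether outputs agree; timings are informational only.

Real nucleotide test sets of a fixed length can be assembled from public
repositories (e.g. querying a nucleotide database for records of length 35
and taking the first 1000 hits); no test here depends on such data — the
seeded generator stands in for it.

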