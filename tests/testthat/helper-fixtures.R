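# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

# The canonical three-sequence worked example.
worked_example_db <- function() {
  seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
}

# Random database over the first A DNA letters, variable lengths.
random_db <- function(seed, A = NULL, N = NULL, Lmax = 12L) {
  set.seed(seed)
  if (is.null(A)) A <- sample(2:4, 1)
  if (is.null(N)) N <- sample(2:10, 1)
  ab <- c("A", "C", "G", "T")[seq_len(A)]
  L <- sample(seq_len(Lmax), N, replace = TRUE)
  seqs <- vapply(L, function(l)
    paste(sample(ab, l, replace = TRUE), collapse = ""), "")
  seq_db(seqs, alphabet = ab)
}

# (pattern, support) set as a sorted "pattern support" character vector, for
# order-free miner comparisons.
support_set <- function(x) {
  if (inherits(x, "motif_set")) x <- x$motifs
  sort(paste(x$pattern, x$support))
}

# Oracle: frequent contiguous substrings by direct substring extraction
# (the G = 2 limit of gapped mining). Counts each sequence once per
# distinct substring.
substring_oracle <- function(db, threshold, max_len) {
  per_seq <- lapply(db$sequences, function(s) {
    n <- nchar(s)
    subs <- character(0)
    for (len in seq_len(min(max_len, n)))
      subs <- c(subs, substring(s, seq_len(n - len + 1L),
                                seq_len(n - len + 1L) + len - 1L))
    unique(subs)
  })
  tab <- table(unlist(per_seq))
  tab <- tab[tab >= threshold]
  data.frame(pattern = vapply(strsplit(names(tab), ""), paste, "",
                              collapse = "*"),
             support = as.integer(tab), stringsAsFactors = FALSE)
}

# Oracle: frequent plain (gap-free) subsequences, by per-sequence
# enumeration of all distinct subsequence strings up to max_len (the
# unconstrained limit G > max sequence length). Exponential — tiny inputs.
subsequence_oracle <- function(db, threshold, max_len) {
  per_seq <- lapply(db$sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    seen <- character(0)
    for (c1 in ch) {
      prev <- seen[nchar(seen) < 2L * max_len - 1L]
      grown <- if (length(prev)) paste0(prev, "*", c1) else character(0)
      seen <- unique(c(seen, c1, grown))
    }
    seen
  })
  tab <- table(unlist(per_seq))
  tab <- tab[tab >= threshold]
  data.frame(pattern = names(tab), support = as.integer(tab),
             stringsAsFactors = FALSE)
}
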