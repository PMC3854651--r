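#' Generate a synthetic sequence database
#'
#' Draws `N` sequences of exact length `L`, each residue independently and
#' uniformly from the first `A` letters of the chosen alphabet — the i.i.d.
#' uniform model that standard mining benchmarks over DNA (`A = 4`) and
#' protein (`A = 20`) alphabets assume. Generation is deterministic under
#' `seed`, and each sequence draws from its own substream derived from the
#' master seed, so enlarging `N` extends the database without reshuffling
#' the sequences already generated.
#'
#' @param A Alphabet size (1..26). `A = 4` uses the DNA alphabet, `A = 20`
#'   the protein alphabet, anything else the first `A` Latin letters.
#' @param L Sequence length (`>= 0`).
#' @param N Number of sequences (`>= 0`; 0 gives an empty database).
#' @param seed Master seed (integer).
#' @param alphabet Override the alphabet choice: `"auto"` (default, rule
#'   above), `"dna"`, `"protein"`, or an [alphabet()] with at least `A`
#'   symbols.
#' @return A [seq_db()] with ids `"S000001"`, `"S000002"`, ...
#' @examples
#' db <- generate_db(A = 4, L = 30, N = 5, seed = 7)
#' db$sequences[1]
#' @export
generate_db <- function(A, L, N, seed, alphabet = "auto") {
  stopifnot(A >= 1, A <= 26, L >= 0, N >= 0)
  ab <- if (is_alphabet(alphabet)) alphabet
        else switch(alphabet,
                    auto = if (A == 4) dna_alphabet()
                           else if (A == 20) protein_alphabet()
                           else new_alphabet(LETTERS[seq_len(A)]),
                    dna = dna_alphabet(),
                    protein = protein_alphabet(),
                    stop("unknown alphabet choice", call. = FALSE))
  if (ab$size < A)
    stop(sprintf("alphabet has %d symbols but A = %d requested", ab$size, A),
         call. = FALSE)
  letters_used <- ab$items[seq_len(A)]

  seqs <- vapply(seq_len(N), function(i) {
    set.seed(derive_seed(seed, i))
    if (L == 0L) return("")
    paste(sample(letters_used, L, replace = TRUE), collapse = "")
  }, character(1))

  seq_db(as.character(seqs), ids = sprintf("S%06d", seq_len(N)),
         alphabet = ab)
}

# Per-sequence substream seed: one LCG step over a mix of master seed and
# sequence number, kept inside the positive 32-bit integer range.
derive_seed <- function(seed, i) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + i * 16807
  as.integer(x %% m)
}
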