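#' Sequence databases
#'
#' A sequence database is an ordered collection of sequences over a declared
#' alphabet. Positions are 1-based throughout the package: residue `i` of a
#' sequence occupies position `i`. The order of sequences is stable — row `j`
#' of every counting matrix and position-index slice refers to the `j`-th
#' sequence here.
#'
#' @param sequences Character vector of residue strings (one per sequence);
#'   lowercase residues are uppercased. Empty strings are legal sequences of
#'   length 0.
#' @param ids Character vector of unique sequence identifiers; defaults to
#'   `"S000001"`, `"S000002"`, ...
#' @param alphabet An [alphabet()], or one of `"auto"`, `"dna"`, `"protein"`,
#'   or a character vector of symbols. With `"auto"` the alphabet is DNA when
#'   all residues fall in `{A,C,G,T,N}` and protein otherwise.
#' @param unknown_policy What to do with residues outside the alphabet:
#'   `"keep-as-item"` (default) appends them to a custom alphabet, `"error"`
#'   fails naming the offending sequence and position, `"drop-sequence"`
#'   silently removes sequences containing them.
#' @return An object of class `"seq_db"`: list with `alphabet`, `ids`,
#'   `sequences` (uppercase strings) and `N`.
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' db$N
#' @export
seq_db <- function(sequences, ids = NULL, alphabet = "auto",
                   unknown_policy = c("keep-as-item", "error",
                                      "drop-sequence")) {
  unknown_policy <- match.arg(unknown_policy)
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- sprintf("S%06d", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences))
    stop("ids and sequences differ in length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("sequence ids must be unique", call. = FALSE)
  if (any(grepl("-", sequences, fixed = TRUE)))
    stop("gap characters '-' are not allowed: sequences must be unaligned",
         call. = FALSE)

  ab <- resolve_alphabet(alphabet, sequences)

  # apply the unknown-symbol policy against the resolved base alphabet
  chars <- strsplit(sequences, "", fixed = TRUE)
  bad <- lapply(chars, function(ch) which(!(ch %in% ab$items)))
  has_bad <- lengths(bad) > 0L
  if (any(has_bad)) {
    if (unknown_policy == "error") {
      j <- which(has_bad)[1L]
      p <- bad[[j]][1L]
      stop(sprintf("unknown symbol '%s' in sequence '%s' at position %d",
                   chars[[j]][p], ids[j], p), call. = FALSE)
    } else if (unknown_policy == "drop-sequence") {
      sequences <- sequences[!has_bad]
      ids <- ids[!has_bad]
    } else {  # keep-as-item
      ab <- extend_alphabet(ab, unlist(lapply(chars[has_bad], unique)))
    }
  }

  structure(list(alphabet = ab, ids = ids, sequences = sequences,
                 N = length(sequences)),
            class = "seq_db")
}

resolve_alphabet <- function(alphabet, sequences) {
  if (is_alphabet(alphabet)) return(alphabet)
  if (is.character(alphabet) && length(alphabet) == 1L) {
    if (alphabet == "dna") return(dna_alphabet())
    if (alphabet == "protein") return(protein_alphabet())
    if (alphabet == "auto") {
      letters_seen <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
      if (all(letters_seen %in% c("A", "C", "G", "T", "N")))
        return(dna_alphabet())
      return(protein_alphabet())
    }
  }
  new_alphabet(alphabet)
}

#' @export
print.seq_db <- function(x, ...) {
  cat(sprintf("<seq_db: %d sequences over %s alphabet (%d symbols)>\n",
              x$N, x$alphabet$name, x$alphabet$size))
  n_show <- min(x$N, 6L)
  for (j in seq_len(n_show)) {
    s <- x$sequences[j]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %s  %s (%d)\n", x$ids[j], s, nchar(x$sequences[j])))
  }
  if (x$N > n_show) cat(sprintf("  ... and %d more\n", x$N - n_show))
  invisible(x)
}

seq_lengths <- function(db) nchar(db$sequences)

#' Read a sequence database from disk
#'
#' Supports standard FASTA (multi-line record bodies allowed; the id is the
#' header up to the first whitespace) and a line-oriented text format with
#' one sequence per line and an optional leading `id<TAB>` field. Residues
#' are uppercased on load. Both LF and CRLF line endings are accepted.
#'
#' @param path File to read.
#' @param format `"fasta"` or `"lines"`.
#' @inheritParams seq_db
#' @return A [seq_db()].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("ATACGAT", "ATCACGA", "TAACGCA"), f)
#' db <- load_sequences(f, format = "lines")
#' db$alphabet$name
#' @export
load_sequences <- function(path, format = c("fasta", "lines"),
                           alphabet = "auto",
                           unknown_policy = c("keep-as-item", "error",
                                              "drop-sequence")) {
  format <- match.arg(format)
  unknown_policy <- match.arg(unknown_policy)
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)

  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
      stop(sprintf("empty FASTA file '%s'", path), call. = FALSE)
    ids <- sub("[[:space:]].*$", "", names(set))
    seqs <- as.character(set)
  } else {
    ln <- readLines(path, warn = FALSE)
    ln <- sub("\r$", "", ln)
    ln <- ln[nzchar(ln)]
    if (length(ln) == 0L)
      stop(sprintf("empty sequence file '%s'", path), call. = FALSE)
    has_id <- grepl("\t", ln, fixed = TRUE)
    ids <- ifelse(has_id, sub("\t.*$", "", ln), sprintf("S%06d", seq_along(ln)))
    seqs <- ifelse(has_id, sub("^[^\t]*\t", "", ln), ln)
  }
  db <- seq_db(seqs, ids = ids, alphabet = alphabet,
               unknown_policy = unknown_policy)
  if (db$N == 0L)
    stop(sprintf("empty sequence database after loading '%s'", path),
         call. = FALSE)
  db
}

#' Write a sequence database to disk
#'
#' Round-trip property: `load_sequences(write_sequences(db, f), f)` restores
#' ids, residues and sequence order exactly, for both formats.
#'
#' @param db A [seq_db()].
#' @param path Output file.
#' @param format `"fasta"` or `"lines"` (lines always carries `id<TAB>seq`).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(db, path, format = c("fasta", "lines")) {
  format <- match.arg(format)
  stopifnot(inherits(db, "seq_db"))
  if (format == "fasta") {
    set <- Biostrings::BStringSet(db$sequences)
    names(set) <- db$ids
    Biostrings::writeXStringSet(set, path)
  } else {
    writeLines(paste(db$ids, db$sequences, sep = "\t"), path)
  }
  invisible(path)
}
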