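#' Residue alphabets
#'
#' An alphabet is an ordered set of single-character residue symbols. The
#' iteration order over `items` is fixed: it determines the order in which
#' candidate patterns are spelled during depth-first mining, so two runs over
#' the same alphabet always enumerate candidates identically.
#'
#' @param items Character vector of unique, single, non-whitespace characters.
#'   Lowercase input is uppercased.
#' @param name Label for the alphabet (`"dna"`, `"protein"`, `"custom"`, ...).
#' @return An object of class `"alphabet"`: a list with elements `name`,
#'   `items` and `size`.
#' @examples
#' alphabet(c("A", "C", "G", "T"), name = "dna")
#' dna_alphabet()
#' protein_alphabet()
#' @export
alphabet <- function(items, name = "custom") {
  items <- toupper(as.character(items))
  if (length(items) < 1L)
    stop("an alphabet needs at least one symbol", call. = FALSE)
  if (any(nchar(items) != 1L) || any(grepl("[[:space:]]", items)))
    stop("alphabet symbols must be single non-whitespace characters",
         call. = FALSE)
  if (anyDuplicated(items))
    stop("alphabet symbols must be unique", call. = FALSE)
  structure(list(name = name, items = items, size = length(items)),
            class = "alphabet")
}

#' @rdname alphabet
#' @export
dna_alphabet <- function() alphabet(c("A", "C", "G", "T"), name = "dna")

#' @rdname alphabet
#' @export
protein_alphabet <- function() {
  # the 20 standard amino acids, alphabetical one-letter codes
  alphabet(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], name = "protein")
}

#' @export
print.alphabet <- function(x, ...) {
  cat(sprintf("<alphabet '%s': %d symbols: %s>\n",
              x$name, x$size, paste(x$items, collapse = "")))
  invisible(x)
}

is_alphabet <- function(x) inherits(x, "alphabet")

# constructor alias for use inside functions whose `alphabet` argument
# shadows the constructor
new_alphabet <- alphabet

#' Extend an alphabet with extra symbols
#'
#' Used by the keep-as-item unknown-symbol policy: out-of-alphabet residues
#' become ordinary items appended after the base symbols, in sorted order.
#'
#' @param ab An [alphabet()].
#' @param extra Character vector of additional single-character symbols.
#' @return An `"alphabet"` with name `"custom"` when symbols were added,
#'   otherwise `ab` unchanged.
#' @keywords internal
extend_alphabet <- function(ab, extra) {
  extra <- setdiff(sort(unique(toupper(extra))), ab$items)
  if (length(extra) == 0L) return(ab)
  alphabet(c(ab$items, extra), name = "custom")
}
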