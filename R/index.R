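#' Inverted position index over a sequence database
#'
#' The index is the miner's only view of the data after construction: for
#' every (item, sequence) pair it stores the strictly increasing list of
#' 1-based positions where the item occurs. It is built in a single pass
#' over the database; every residue is indexed exactly once, so the union of
#' position lists within one sequence is `1..n_j`. Windowed successor
#' queries against the sorted lists are answered by binary search
#' ([successors_in_window()]).
#'
#' @param db A [seq_db()].
#' @return An object of class `"position_index"`: list with `pos` (a list
#'   indexed by item symbol, each element a list of `N` integer position
#'   vectors), `alphabet` and `N`.
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' idx <- build_index(db)
#' positions_of(idx, "C", 2)  # 3 5
#' @export
build_index <- function(db) {
  stopifnot(inherits(db, "seq_db"))
  items <- db$alphabet$items
  empty <- lapply(items, function(i) vector("list", db$N))
  names(empty) <- items
  pos <- empty
  chars <- strsplit(db$sequences, "", fixed = TRUE)
  for (j in seq_len(db$N)) {
    ch <- chars[[j]]
    by_item <- split(seq_along(ch), factor(ch, levels = items))
    for (it in items) pos[[it]][[j]] <- as.integer(by_item[[it]])
  }
  structure(list(pos = pos, alphabet = db$alphabet, N = db$N,
                 ids = db$ids),
            class = "position_index")
}

#' @export
print.position_index <- function(x, ...) {
  total <- sum(vapply(x$pos, function(p) sum(lengths(p)), numeric(1)))
  cat(sprintf(
    "<position_index: %d sequences x %d items, %d indexed positions>\n",
    x$N, x$alphabet$size, total))
  invisible(x)
}

check_index_item <- function(index, item) {
  if (!item %in% x_items(index))
    stop(sprintf("item '%s' is not in the alphabet", item), call. = FALSE)
}

x_items <- function(index) index$alphabet$items

check_index_seq <- function(index, seq) {
  if (length(seq) != 1L || is.na(seq) || seq < 1L || seq > index$N)
    stop(sprintf("sequence number must be in 1..%d", index$N), call. = FALSE)
}

#' Occurrence positions of an item in one sequence
#'
#' @param index A [build_index()] result.
#' @param item Single residue symbol.
#' @param seq Sequence number (1..N, database order).
#' @return Strictly increasing integer vector of 1-based positions (possibly
#'   empty).
#' @export
positions_of <- function(index, item, seq) {
  check_index_item(index, item)
  check_index_seq(index, seq)
  index$pos[[item]][[seq]]
}

#' Windowed successor query by binary search
#'
#' Returns every occurrence position `q` of `item` in sequence `seq` that
#' lies strictly inside the gap window after `p`: `p < q < p + G`. Under
#' this (strict) convention `G = 1` admits nothing and `G = 2` admits only
#' the adjacent position `q = p + 1`. The window bounds are located in the
#' sorted position list with [findInterval()], i.e. binary search.
#'
#' @inheritParams positions_of
#' @param p Reference position (`>= 1`).
#' @param G Gap constraint (`>= 1`).
#' @return Strictly increasing integer vector, empty when no occurrence
#'   falls in the window.
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' idx <- build_index(db)
#' successors_in_window(idx, "A", 1, p = 4, G = 3)  # 6
#' @export
successors_in_window <- function(index, item, seq, p, G) {
  stopifnot(G >= 1, p >= 1)
  pos <- positions_of(index, item, seq)
  if (length(pos) == 0L) return(pos)
  # q in (p, p + G) over integers means p + 1 <= q <= p + G - 1
  lo <- findInterval(p, pos)            # last index with pos <= p
  hi <- findInterval(p + G - 1L, pos)   # last index with pos <= p + G - 1
  if (hi <= lo) return(integer(0))
  pos[(lo + 1L):hi]
}

#' Dump a position index as a TSV for inspection
#'
#' @param index A [build_index()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dump_index <- function(index, path) {
  rows <- list()
  for (it in x_items(index)) {
    for (j in seq_len(index$N)) {
      p <- index$pos[[it]][[j]]
      if (length(p))
        rows[[length(rows) + 1L]] <-
          data.frame(item = it, sequence_id = index$ids[j], position = p)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
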