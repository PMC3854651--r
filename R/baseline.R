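# Reference miners: an exhaustive gapped-containment enumerator and a
# projected-database pattern-growth miner. Both exist to cross-check the
# depth-first counting-matrix miner: all three must return identical
# (pattern, support) sets — they differ in how they get there.

# Per-sequence occurrence lists: item -> sorted positions, for one sequence.
split_positions <- function(s, items) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  lapply(split(seq_along(ch), factor(ch, levels = items)), as.integer)
}

# Left-to-right dynamic scan: after item k, `live` holds every position at
# which a gap-valid occurrence of items[1..k] can end. Not greedy — all live
# end positions are carried, for the same reason the counting matrix keeps
# every qualifying position.
contains_gapped_pos <- function(plist, its, G) {
  live <- plist[[its[1L]]]
  if (is.null(live) || length(live) == 0L) return(FALSE)
  if (length(its) > 1L) {
    for (k in 2L:length(its)) {
      pos <- plist[[its[k]]]
      if (is.null(pos) || length(pos) == 0L) return(FALSE)
      keep <- findInterval(pos - 1L, live) > findInterval(pos - G, live)
      live <- pos[keep]
      if (length(live) == 0L) return(FALSE)
    }
  }
  TRUE
}

#' Does a sequence contain a gapped pattern?
#'
#' True iff positions `q_1 < q_2 < ... < q_m` exist with the residue at
#' `q_i` equal to the i-th pattern item and `q_{i+1} < q_i + G` for every
#' consecutive pair. Implemented as a left-to-right scan that carries every
#' live end position, never just the earliest one.
#'
#' @param sequence A residue string (or a single-sequence slice of a
#'   [seq_db()]'s `sequences`).
#' @param pattern Character vector of items, or a `"X*Y*Z"` pattern string.
#' @param G Gap constraint.
#' @return Logical scalar.
#' @examples
#' contains_gapped("ATACGAT", "C*A", G = 3)  # TRUE
#' contains_gapped("TAACGCA", "A*T", G = 3)  # FALSE
#' @export
contains_gapped <- function(sequence, pattern, G) {
  its <- if (length(pattern) == 1L && grepl("*", pattern, fixed = TRUE))
    strsplit(pattern, "*", fixed = TRUE)[[1]] else as.character(pattern)
  its <- toupper(its)
  s <- toupper(sequence)
  plist <- split_positions(s, unique(c(its, strsplit(s, "")[[1]])))
  contains_gapped_pos(plist, its, as.integer(G))
}

#' Exhaustive mining by gapped-containment counting
#'
#' Enumerates candidate item strings of length 1..`max_len` depth-first over
#' the alphabet and computes each candidate's support by testing
#' [contains_gapped()] against every sequence. A branch is abandoned only
#' when its support is zero (a sequence containing an extension necessarily
#' contains the prefix), so the enumeration stays independent of the
#' counting-matrix miner's threshold pruning. Guarded to desk scale:
#' `A^max_len <= 1e6`.
#'
#' @param db A [seq_db()].
#' @param params A [mining_params()] (its `max_length` is ignored in favour
#'   of `max_len`).
#' @param max_len Maximum pattern length to enumerate.
#' @return data.frame with columns `pattern`, `support`, sorted by pattern.
#' @export
brute_force_mine <- function(db, params, max_len) {
  stopifnot(inherits(db, "seq_db"), inherits(params, "mining_params"),
            max_len >= 1)
  A <- db$alphabet$size
  if (A^max_len > 1e6)
    stop(sprintf("A^max_len = %d^%d exceeds the desk-scale guard of 1e6",
                 A, max_len), call. = FALSE)
  thr <- resolve_threshold(params, db$N)
  G <- params$gap
  items <- db$alphabet$items
  plists <- lapply(db$sequences, split_positions, items = items)

  acc <- new.env(parent = emptyenv())
  acc$pattern <- character(0)
  acc$support <- integer(0)

  descend <- function(its) {
    supp <- sum(vapply(plists, contains_gapped_pos, logical(1),
                       its = its, G = G))
    if (supp >= thr) {
      k <- length(acc$pattern) + 1L
      acc$pattern[k] <- pattern_string(its)
      acc$support[k] <- supp
    }
    if (supp > 0L && length(its) < max_len)
      for (it in items) descend(c(its, it))
    invisible()
  }
  if (thr <= db$N) for (it in items) descend(it)

  out <- data.frame(pattern = acc$pattern, support = acc$support,
                    stringsAsFactors = FALSE)
  out[order(out$pattern), , drop = FALSE]
}

#' Project a database (or a projection) on an item
#'
#' A projected database holds one entry per occurrence of `item`: the pair
#' (sequence number, suffix start position), the suffix being everything
#' strictly after the occurrence. Entries whose suffix is empty are
#' dropped. Projecting an existing projection restricts occurrences to the
#' gap window after the occurrence that created each entry (`p < q < p + G`
#' with `p = suffix start - 1`), so successive projections track exactly the
#' occurrence chains the gap constraint admits.
#'
#' @param x A [seq_db()] or a `"projected_db"`.
#' @param item Residue symbol to project on.
#' @param G Gap constraint (used only when projecting a projection).
#' @return An object of class `"projected_db"`: list with `db`, `prefix`
#'   (items projected on so far), `seq` and `start` (parallel integer
#'   vectors: sequence number and suffix start position, database order).
#' @examples
#' db <- seq_db(c("ATACGAT", "ATCACGA", "TAACGCA"), ids = c("X", "Y", "Z"))
#' pr <- project(db, "A")
#' projection_suffixes(pr)
#' @export
project <- function(x, item, G = NULL) {
  if (inherits(x, "seq_db")) {
    item <- toupper(item)
    check_db_item(x, item)
    occ_list <- lapply(seq_len(x$N), function(j)
      which(strsplit(x$sequences[j], "")[[1]] == item))
    seqs <- rep(seq_len(x$N), lengths(occ_list))
    occ <- as.integer(unlist(occ_list))
    new_projection(x, item, seqs, occ)
  } else if (inherits(x, "projected_db")) {
    if (is.null(G)) stop("G is required when projecting a projection",
                         call. = FALSE)
    item <- toupper(item)
    check_db_item(x$db, item)
    occ <- project_entries(x, item, as.integer(G))
    new_projection(x$db, c(x$prefix, item), occ$seq, occ$pos)
  } else stop("x must be a seq_db or a projected_db", call. = FALSE)
}

check_db_item <- function(db, item) {
  if (!item %in% db$alphabet$items)
    stop(sprintf("item '%s' is not in the alphabet", item), call. = FALSE)
}

new_projection <- function(db, prefix, seqs, occ) {
  # drop empty suffixes; suffix starts right after the occurrence
  start <- occ + 1L
  keep <- start <= nchar(db$sequences)[seqs]
  structure(list(db = db, prefix = prefix,
                 seq = seqs[keep], start = start[keep]),
            class = "projected_db")
}

# All gap-valid occurrences of `item` reachable from a projection's entries:
# positions q with p < q < p + G for some entry occurrence p, deduplicated
# per sequence. Includes occurrences at a sequence's last position (they
# carry support even though their own suffix is empty).
project_entries <- function(proj, item, G) {
  db <- proj$db
  out_seq <- integer(0); out_pos <- integer(0)
  for (j in unique(proj$seq)) {
    par <- sort(unique(proj$start[proj$seq == j] - 1L))
    pos <- which(strsplit(db$sequences[j], "")[[1]] == item)
    if (length(pos) == 0L) next
    keep <- findInterval(pos - 1L, par) > findInterval(pos - G, par)
    q <- pos[keep]
    if (length(q)) {
      out_seq <- c(out_seq, rep(j, length(q)))
      out_pos <- c(out_pos, as.integer(q))
    }
  }
  list(seq = out_seq, pos = out_pos)
}

#' Suffix strings of a projection
#'
#' @param proj A `"projected_db"`.
#' @return Character vector of suffixes, in database order.
#' @export
projection_suffixes <- function(proj) {
  stopifnot(inherits(proj, "projected_db"))
  substring(proj$db$sequences[proj$seq], proj$start)
}

#' @export
print.projected_db <- function(x, ...) {
  cat(sprintf("<projected_db on '%s': %d entries over %d sequences>\n",
              pattern_string(x$prefix), length(x$seq), length(unique(x$seq))))
  invisible(x)
}

#' Frequent items within a projection
#'
#' Candidate generation the projected-database way: every suffix of the
#' projection is scanned in full and an item is frequent when it appears in
#' the suffixes of at least `threshold` distinct sequences. Note this scan
#' ignores the gap constraint — it is a candidate filter (a superset of the
#' gap-valid frequent items, since a gap-valid occurrence lies in some
#' suffix); supports are verified under the gap window before any pattern
#' is reported.
#'
#' @param proj A `"projected_db"`.
#' @param threshold Absolute support threshold.
#' @return Character vector of items, in alphabet order.
#' @export
projection_frequent_items <- function(proj, threshold) {
  stopifnot(inherits(proj, "projected_db"))
  db <- proj$db
  per_seq <- lapply(unique(proj$seq), function(j)
    unique(strsplit(substring(db$sequences[j],
                              min(proj$start[proj$seq == j])), "")[[1]]))
  counts <- table(factor(unlist(per_seq), levels = db$alphabet$items))
  db$alphabet$items[counts >= threshold]
}

#' Pattern-growth mining over projected databases
#'
#' The projected-database counterpart of [mine()]: scan the database for
#' frequent single items, project on each, then recursively (i) generate
#' candidate items by whole-suffix scanning of the projection
#' ([projection_frequent_items()]) and (ii) verify each candidate's support
#' from the gap-valid occurrences reachable from the projection's entries,
#' emitting and recursing only when the verified support meets the
#' threshold. Returns exactly the (pattern, support) set of [mine()];
#' the two differ in work done, not in output.
#'
#' @param db A [seq_db()].
#' @param params A [mining_params()] (`max_length` honoured).
#' @return data.frame with columns `pattern`, `support`, sorted by pattern.
#' @export
genprefixspan_mine <- function(db, params) {
  stopifnot(inherits(db, "seq_db"), inherits(params, "mining_params"))
  thr <- resolve_threshold(params, db$N)
  G <- params$gap
  items <- db$alphabet$items

  acc <- new.env(parent = emptyenv())
  acc$pattern <- character(0)
  acc$support <- integer(0)
  emit <- function(its, supp) {
    if (length(its) < params$min_length) return(invisible())
    k <- length(acc$pattern) + 1L
    acc$pattern[k] <- pattern_string(its)
    acc$support[k] <- supp
    invisible()
  }

  grow <- function(proj) {
    if (length(proj$prefix) >= params$max_length) return(invisible())
    if (length(proj$seq) == 0L) return(invisible())
    for (it in intersect(items, projection_frequent_items(proj, thr))) {
      occ <- project_entries(proj, it, G)
      supp <- length(unique(occ$seq))
      if (supp >= thr) {
        emit(c(proj$prefix, it), supp)
        grow(new_projection(proj$db, c(proj$prefix, it), occ$seq, occ$pos))
      }
    }
    invisible()
  }

  if (thr <= db$N) {
    for (it in items) {
      has <- grepl(it, db$sequences, fixed = TRUE)
      supp <- sum(has)
      if (supp >= thr) {
        emit(it, supp)
        grow(project(db, it))
      }
    }
  }

  out <- data.frame(pattern = acc$pattern, support = acc$support,
                    stringsAsFactors = FALSE)
  out[order(out$pattern), , drop = FALSE]
}
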